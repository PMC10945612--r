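#' Default construct-domain candidate sets
#'
#' The five preliminary construct domains and their candidate variables:
#' demographics & head-injury history; circular-pursuit eye-movement
#' parameters; cognitive assessments (ANAM SRT, TRAILS); symptoms common to
#' concussion (19 RPQ items); and psychological & mood symptoms. The psych
#' domain carries separate adult (BAI, CES-D, CAARS) and youth (BAI-Y,
#' BDI-Y, Conners 3) instrument strata, since each athlete receives exactly
#' one instrument per construct.
#'
#' @return A named list of domain specs; each has `name` and `candidates`
#'   (for the psych domain, `strata` with adult/youth candidate lists).
#' @export
default_domain_specs <- function() {
  rpq <- paste0("rpq_", c(
    "headaches", "dizziness", "nausea", "noise", "sleep", "fatigue",
    "irritable", "depressed", "frustrated", "forgetfulness",
    "concentration", "longer_to_think", "vision", "light", "double_vision",
    "restlessness", "balance", "mental_fogginess", "drowsiness"))
  list(
    demographics_history = list(
      name = "demographics_history",
      candidates = c("age", "prior_head_injury", "caucasian", "male",
                     "learning_disability")),
    pursuit = list(
      name = "pursuit",
      candidates = c("sd_radial", "sd_tangential", "mean_radial_error",
                     "phase_error_mean", "gain_h", "gain_v")),
    cognitive = list(
      name = "cognitive",
      candidates = c("srt_median_rt", "srt_rt_sd", "srt_throughput",
                     "trails_a_time", "trails_b_time", "trails_a_errors",
                     "trails_b_errors", "trails_a_ss", "trails_b_ss")),
    concussion_symptoms = list(
      name = "concussion_symptoms", candidates = rpq),
    psych_mood = list(
      name = "psych_mood",
      strata = list(
        adult = c("bai", "cesd", "caars_inattention", "caars_hyperactivity",
                  "caars_impulsivity", "caars_self_concept",
                  "caars_adhd_index"),
        youth = c("bai_y", "bdi_y", "conners3_inattention",
                  "conners3_hyperactive_impulsive",
                  "conners3_learning_problems",
                  "conners3_defiance_aggression",
                  "conners3_family_relations"))))
}

# map retained raw psych variables onto their harmonized summary-model columns
harmonized_name <- function(v) {
  map <- c(bai = "anxiety_z", bai_y = "anxiety_z",
           caars_inattention = "adhd_inattention_t",
           conners3_inattention = "adhd_inattention_t")
  ifelse(v %in% names(map), unname(map[v]), v)
}

#' Fit one preliminary construct-domain model
#'
#' Fits a multiple logistic regression of case status (significantly
#' symptomatic vs non-concussed) on the domain's candidate variables, using
#' domain-wise complete cases, and retains the candidates whose Wald
#' p-values fall strictly below the retention threshold. Psych-domain specs
#' with instrument strata are fitted per stratum and the retained lists
#' pooled.
#'
#' @param data the analysis-sample records (with a binary `case` column) or
#'   an `analysis_sample`.
#' @param spec one element of [default_domain_specs()].
#' @param retain_p retention threshold on the Wald p-value (strict).
#' @return A list with `domain`, `model` (or `models` per stratum),
#'   `retained` (candidate names with p < `retain_p`), `p_values`,
#'   `odds_ratios`, `n_used`, `dropped` (incomplete-row indices).
#' @export
run_domain_model <- function(data, spec, retain_p = 0.10) {
  d <- domain_data(data)
  if (!is.null(spec$strata)) {
    # complete cases over a stratum's instrument columns restrict the fit to
    # that stratum, since the other stratum's instruments are missing there
    fits <- lapply(names(spec$strata), function(s) {
      vars <- spec$strata[[s]]
      if (!any(stats::complete.cases(d[, vars, drop = FALSE]))) return(NULL)
      fit_domain(d, vars, retain_p)
    })
    names(fits) <- names(spec$strata)
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits))
      stop(sprintf("domain '%s': no complete cases in any stratum", spec$name))
    retained <- unlist(lapply(fits, `[[`, "retained"), use.names = FALSE)
    list(domain = spec$name, models = lapply(fits, `[[`, "model"),
         retained = retained,
         p_values = unlist(lapply(fits, `[[`, "p_values")),
         odds_ratios = unlist(lapply(fits, `[[`, "odds_ratios")),
         n_used = sum(vapply(fits, `[[`, numeric(1), "n_used")),
         dropped = setdiff(seq_len(nrow(d)),
                           unlist(lapply(fits, `[[`, "rows"))))
  } else {
    f <- fit_domain(d, spec$candidates, retain_p)
    list(domain = spec$name, model = f$model, retained = f$retained,
         p_values = f$p_values, odds_ratios = f$odds_ratios,
         n_used = f$n_used, dropped = setdiff(seq_len(nrow(d)), f$rows))
  }
}

domain_data <- function(data) {
  if (inherits(data, "analysis_sample")) data <- data$records
  stopifnot(is.data.frame(data))
  if (!"case" %in% names(data)) {
    if (!"group" %in% names(data))
      stop("data must carry a 'case' or 'group' column")
    data$case <- as.integer(data$group == "symptomatic")
  }
  data
}

fit_domain <- function(d, vars, retain_p) {
  dm <- build_design_matrix(d, vars, outcome = "case")
  if (length(dm$y) == 0 || sum(dm$y) == 0)
    stop(sprintf(
      "domain fit degenerate: %d complete cases, %d events (all candidate records may have been screened invalid)",
      length(dm$y), sum(dm$y)))
  model <- fit_logistic(dm)
  p <- model$p_value[vars]
  list(model = model, retained = vars[p < retain_p], p_values = p,
       odds_ratios = model$odds_ratio[vars], n_used = model$n,
       rows = dm$rows)
}

#' Sequential selection and summary model
#'
#' Runs all five preliminary construct-domain models with the p < 0.10
#' retention rule, maps retained psych variables onto their harmonized
#' columns (anxiety Z, ADHD inattention T), and fits the summary model on
#' complete cases over the union of retained variables. Retained variables
#' stay in the summary model regardless of their summary-model p-values.
#'
#' @param sample an `analysis_sample` (or its records with `group`/`case`).
#' @param specs domain specs, defaults to [default_domain_specs()].
#' @param retain_p retention threshold (strict inequality).
#' @return An object of class `selection_result`: `domain_results`,
#'   `retained_union` (harmonized names), `summary_model` (a
#'   `pursuit_logit`, or `NULL` when nothing was retained), `summary_rows`
#'   (record rows entering the summary model), `dropped_log`.
#' @export
run_selection <- function(sample, specs = default_domain_specs(),
                          retain_p = 0.10) {
  d <- domain_data(sample)
  if (!("anxiety_z" %in% names(d)) || !("adhd_inattention_t" %in% names(d)))
    d <- harmonize_scores(d)
  domain_results <- lapply(specs, function(sp) run_domain_model(d, sp, retain_p))
  retained_raw <- unlist(lapply(domain_results, `[[`, "retained"),
                         use.names = FALSE)
  retained <- unique(harmonized_name(retained_raw))
  dropped_log <- lapply(domain_results, `[[`, "dropped")

  if (!length(retained)) {
    return(structure(list(domain_results = domain_results,
                          retained_union = character(0),
                          summary_model = NULL, summary_rows = integer(0),
                          dropped_log = dropped_log,
                          note = "no variable met the retention threshold"),
                     class = "selection_result"))
  }
  note <- NULL
  dm <- build_design_matrix(d, retained, outcome = "case")
  degenerate <- function(dm)
    length(dm$y) == 0 || sum(dm$y) == 0 || sum(dm$y) == length(dm$y)
  if (degenerate(dm)) {
    # unharmonizable variables retained from both instrument strata have an
    # empty complete-case intersection; they cannot be pooled, so they are
    # dropped from the summary model with a note
    stratum_bound <- intersect(retained, unlist(lapply(specs, function(sp)
      if (!is.null(sp$strata)) unlist(sp$strata) else character(0))))
    poolable <- setdiff(retained, stratum_bound)
    if (length(poolable) && length(poolable) < length(retained)) {
      note <- sprintf(
        "stratum-bound variables dropped from the summary model (no pooled complete cases): %s",
        paste(stratum_bound, collapse = ", "))
      retained <- poolable
      dm <- build_design_matrix(d, retained, outcome = "case")
    }
  }
  if (degenerate(dm)) {
    return(structure(list(domain_results = domain_results,
                          retained_union = retained, summary_model = NULL,
                          summary_rows = integer(0),
                          dropped_log = dropped_log,
                          note = sprintf(
                            "summary model degenerate: %d complete cases, %d events over the retained union",
                            length(dm$y), sum(dm$y))),
                     class = "selection_result"))
  }
  summary_model <- fit_logistic(dm)
  structure(list(domain_results = domain_results, retained_union = retained,
                 summary_model = summary_model, summary_rows = dm$rows,
                 dropped_log = dropped_log, note = note),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  for (r in x$domain_results)
    cat(sprintf("Domain %-22s n = %5d, retained: %s\n", r$domain, r$n_used,
                if (length(r$retained)) paste(r$retained, collapse = ", ")
                else "(none)"))
  if (is.null(x$summary_model)) {
    cat("No summary model:", x$note, "\n")
  } else {
    cat("\nSummary model over", length(x$retained_union), "retained variables:\n")
    print(x$summary_model)
  }
  invisible(x)
}
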