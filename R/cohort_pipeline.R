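#' Classify a significant post-concussion symptom burden
#'
#' An athlete is classified as significantly symptomatic when the BISQ
#' attention-memory factor score (mean frequency, 0-3, over 28 common
#' post-concussion symptoms) is at or above the cutoff of 0.53.
#'
#' @param bisq_attention_memory score(s) in \[0, 3\].
#' @param cutoff classification cutoff (boundary inclusive).
#' @return Logical vector: `TRUE` = significantly symptomatic.
#' @export
classify_symptomatic <- function(bisq_attention_memory, cutoff = 0.53) {
  if (any(bisq_attention_memory < 0 | bisq_attention_memory > 3,
          na.rm = TRUE))
    stop("BISQ attention-memory score must lie in [0, 3]")
  bisq_attention_memory >= cutoff
}

#' Assemble the analysis sample from a cohort
#'
#' Applies the participant-flow rules: concussed athletes tested after the
#' post-injury window are excluded (`late_testing`); the remaining concussed
#' athletes are partitioned into significantly symptomatic and resolved by
#' [classify_symptomatic()]; resolved athletes are dropped from the final
#' analysis sample; non-concussed athletes are retained as controls.
#'
#' @param cohort a cohort data.frame ([simulate_cohort()] schema).
#' @param window_days post-injury testing window in days.
#' @param cutoff BISQ classification cutoff.
#' @return An object of class `analysis_sample`: a list with `records` (the
#'   final sample, with a `group` column of `"symptomatic"` /
#'   `"non_concussed"`), `excluded` (dropped rows with a `reason` column of
#'   `"late_testing"` / `"resolved"`), and `flow_counts`.
#' @export
assemble_analysis_sample <- function(cohort, window_days = 14,
                                     cutoff = 0.53) {
  stopifnot(is.data.frame(cohort), "concussed" %in% names(cohort))
  conc <- cohort$concussed == 1
  if (any(conc & (is.na(cohort$days_to_test) |
                  is.na(cohort$bisq_attention_memory))))
    stop("concussed record missing days_to_test or BISQ score")

  late <- conc & cohort$days_to_test > window_days
  evaluated <- conc & !late
  sympt <- evaluated &
    classify_symptomatic(cohort$bisq_attention_memory, cutoff) %in% TRUE
  resolved <- evaluated & !sympt

  records <- cohort[!conc | sympt, , drop = FALSE]
  records$group <- ifelse(records$concussed == 1, "symptomatic",
                          "non_concussed")
  excluded <- cohort[late | resolved, , drop = FALSE]
  excluded$reason <- ifelse(late[late | resolved], "late_testing", "resolved")

  flow <- list(baseline_total = nrow(cohort), concussed = sum(conc),
               excluded_late = sum(late), evaluated_in_window = sum(evaluated),
               symptomatic = sum(sympt), resolved = sum(resolved),
               final_n = nrow(records))
  stopifnot(flow$final_n ==
              flow$baseline_total - flow$excluded_late - flow$resolved,
            flow$symptomatic + flow$resolved == flow$evaluated_in_window)
  structure(list(records = records, excluded = excluded, flow_counts = flow),
            class = "analysis_sample")
}

#' @export
print.analysis_sample <- function(x, ...) {
  f <- x$flow_counts
  cat(sprintf(paste0(
    "Analysis sample: %d baseline-tested, %d concussed\n",
    "  %d excluded (late testing), %d evaluated in window\n",
    "  %d significantly symptomatic, %d resolved (dropped)\n",
    "  final sample: %d (%d cases, %d controls)\n"),
    f$baseline_total, f$concussed, f$excluded_late, f$evaluated_in_window,
    f$symptomatic, f$resolved, f$final_n, f$symptomatic,
    f$final_n - f$symptomatic))
  invisible(x)
}

#' Harmonize adult and pediatric psychological scales
#'
#' Adds `anxiety_z` — the BAI (adults) or BAI-Y (youth) score standardized
#' within its instrument stratum (within-sample mean/SD) — and
#' `adhd_inattention_t`, the T-scored inattention subscale taken from CAARS
#' for adults and Conners 3 for youth. Original columns are retained.
#'
#' @param cohort a cohort data.frame.
#' @return The cohort with `anxiety_z` and `adhd_inattention_t` columns added.
#' @export
harmonize_scores <- function(cohort) {
  adult_inst <- !is.na(cohort$bai)
  youth_inst <- !is.na(cohort$bai_y)
  if (any(adult_inst & youth_inst))
    stop("record carries both adult and youth anxiety instruments")
  z <- function(v, rows) {
    out <- rep(NA_real_, length(v))
    if (sum(rows) >= 2)
      out[rows] <- (v[rows] - mean(v[rows])) / stats::sd(v[rows])
    out
  }
  za <- z(cohort$bai, adult_inst)
  zy <- z(cohort$bai_y, youth_inst)
  cohort$anxiety_z <- ifelse(adult_inst, za, zy)
  cohort$adhd_inattention_t <- ifelse(!is.na(cohort$caars_inattention),
                                      cohort$caars_inattention,
                                      cohort$conners3_inattention)
  cohort
}

#' Descriptive summary of the analysis sample
#'
#' Per group (non-concussed controls vs significantly symptomatic), reports
#' mean (SD) age and the proportions of the six categorical baseline
#' characteristics.
#'
#' @param sample an `analysis_sample`.
#' @return A data.frame with one row per characteristic and one column per
#'   group; groups with no members are reported as `NA` columns.
#' @export
describe_cohort <- function(sample) {
  stopifnot(inherits(sample, "analysis_sample"))
  r <- sample$records
  cats <- c("prior_head_injury", "caucasian", "male", "learning_disability",
            "psychiatric", "neurological")
  one_group <- function(g) {
    s <- r[r$group == g, , drop = FALSE]
    if (!nrow(s)) return(rep(NA_real_, 2 + length(cats)))
    c(mean(s$age, na.rm = TRUE), stats::sd(s$age, na.rm = TRUE),
      vapply(cats, function(v) mean(s[[v]], na.rm = TRUE), numeric(1)))
  }
  out <- data.frame(
    characteristic = c("age_mean", "age_sd", paste0("prop_", cats)),
    non_concussed = one_group("non_concussed"),
    symptomatic = one_group("symptomatic"))
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as CSV
#'
#' Missing values are written as empty fields. The column dictionary is the
#' [simulate_cohort()] schema: identifiers, demographics and history flags
#' (0/1), the six pursuit metrics, cognitive scores (ANAM SRT, TRAILS),
#' the 19 RPQ items, adult (BAI, CES-D, CAARS) and youth (BAI-Y, BDI-Y,
#' Conners 3) psychological scales, and the outcome fields `concussed`,
#' `days_to_test`, `bisq_attention_memory`.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
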