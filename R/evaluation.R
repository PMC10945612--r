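#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midrank tie handling: the probability that a randomly chosen event scores
#' higher than a randomly chosen non-event, counting exact ties as one half.
#'
#' @param scores numeric scores (e.g. model logits); any strictly increasing
#'   transform gives the same AUC.
#' @param outcomes binary outcomes.
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes), all(outcomes %in% c(0, 1)))
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one event and one non-event")
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return A data.frame of `threshold`, `fpr`, `tpr` over the distinct score
#'   values (plus the all-positive endpoint).
#' @export
roc_coordinates <- function(scores, outcomes) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(scores >= t & outcomes == 0) / n0,
                 numeric(1)),
    tpr = vapply(th, function(t) sum(scores >= t & outcomes == 1) / n1,
                 numeric(1)))
}

#' Misclassification error of a logistic model
#'
#' Error rate of the classification rule "predict an event when the fitted
#' probability exceeds the threshold". The default threshold of 0.5 makes
#' the constant model predict all-negative under a rare outcome, so the
#' prevalence threshold is worth reporting alongside.
#'
#' @param logits model logits.
#' @param outcomes binary outcomes.
#' @param threshold probability threshold, or `"prevalence"` to use the
#'   observed event rate.
#' @return The misclassification error rate.
#' @export
misclassification <- function(logits, outcomes, threshold = 0.5) {
  stopifnot(length(logits) == length(outcomes))
  p <- stats::plogis(logits)
  if (identical(threshold, "prevalence")) threshold <- mean(outcomes)
  mean((p > threshold) != (outcomes == 1))
}

#' Side-by-side comparison of the two modelling arms
#'
#' Evaluates the traditional summary model and the elastic-net refit on the
#' identical analysis-sample rows (in-sample logits): McFadden pseudo
#' R-squared, ROC AUC, misclassification error at the 0.5 and prevalence
#' thresholds, and deviance ratio.
#'
#' @param summary_model a `pursuit_logit` (the traditional summary model).
#' @param enet_refit a `pursuit_logit` (plain refit of the elastic-net
#'   support).
#' @param data the analysis-sample records both models were fitted on.
#' @return An object of class `model_comparison`: per-arm metric list,
#'   `winner` per index, the shared-row description and the two variable
#'   lists.
#' @export
compare_models <- function(summary_model, enet_refit, data = NULL) {
  stopifnot(inherits(summary_model, "pursuit_logit"),
            inherits(enet_refit, "pursuit_logit"))
  if (summary_model$n != enet_refit$n ||
      !isTRUE(all.equal(summary_model$y, enet_refit$y)))
    stop("models were not evaluated on the identical sample rows")
  arm <- function(m) list(
    pseudo_r2 = mcfadden_r2(m),
    auc = roc_auc(m$logits, m$y),
    misclassification = misclassification(m$logits, m$y),
    misclassification_prevalence =
      misclassification(m$logits, m$y, "prevalence"),
    deviance_ratio = 1 - (-2 * m$loglik) / (-2 * m$null_loglik),
    variables = setdiff(names(m$coefficients), "(Intercept)"))
  a <- arm(summary_model); b <- arm(enet_refit)
  idx <- c("pseudo_r2", "auc", "misclassification", "deviance_ratio")
  winner <- vapply(idx, function(k) {
    av <- a[[k]]; bv <- b[[k]]
    better_high <- k != "misclassification"
    if (isTRUE(all.equal(av, bv))) "tie"
    else if ((av > bv) == better_high) "summary" else "elastic_net"
  }, character(1))
  structure(list(summary = a, elastic_net = b, winner = winner,
                 n = summary_model$n, n_events = summary_model$n_events),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison on %d athletes (%d cases)\n", x$n, x$n_events))
  fmt <- function(a) sprintf("R2 %.3f | AUC %.3f | miscl %.4f | dev.ratio %.3f",
                             a$pseudo_r2, a$auc, a$misclassification,
                             a$deviance_ratio)
  cat("  summary     :", fmt(x$summary), "\n")
  cat("  elastic net :", fmt(x$elastic_net), "\n")
  invisible(x)
}

#' Serialize / restore a model comparison
#' @param x a `model_comparison`.
#' @param path JSON file path.
#' @return `write_comparison()` returns `path` invisibly;
#'   `read_comparison()` the restored `model_comparison`.
#' @export
write_comparison <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "model_comparison")
}

#' Auxiliary timing and confound checks
#'
#' The side analyses supporting the main models: (1) pooled-variance
#' two-sample t-test of days-to-testing between still-symptomatic and
#' resolved concussed athletes; (2) OLS slope of the BISQ attention-memory
#' score on days-to-testing with its t-test; (3) pooled two-sample t-test of
#' baseline SD radial by prior head injury; (4) Pearson correlation of SD
#' radial with the baseline RPQ sleep item.
#'
#' @param cohort the full cohort (before dropping resolved athletes), with a
#'   14-day evaluation window applied internally.
#' @param window_days evaluation window in days.
#' @param cutoff BISQ classification cutoff.
#' @return A list of class `auxiliary_checks` with elements
#'   `time_to_testing`, `bisq_slope`, `sd_radial_head_injury`,
#'   `sd_radial_sleep`; a check whose group has fewer than 2 members is
#'   reported as `NULL` with a note.
#' @export
auxiliary_checks <- function(cohort, window_days = 14, cutoff = 0.53) {
  conc <- cohort$concussed == 1 & !is.na(cohort$days_to_test) &
    cohort$days_to_test <= window_days
  sympt <- conc & classify_symptomatic(cohort$bisq_attention_memory,
                                       cutoff) %in% TRUE
  resolved <- conc & !sympt
  out <- list()
  notes <- character(0)

  if (sum(sympt) >= 2 && sum(resolved) >= 2) {
    tt <- stats::t.test(cohort$days_to_test[sympt],
                        cohort$days_to_test[resolved], var.equal = TRUE)
    out$time_to_testing <- list(t = unname(tt$statistic),
                                df = unname(tt$parameter),
                                p = tt$p.value,
                                mean_symptomatic = mean(cohort$days_to_test[sympt]),
                                mean_resolved = mean(cohort$days_to_test[resolved]))
  } else notes <- c(notes, "time_to_testing skipped: group with < 2 members")

  if (sum(conc) >= 3) {
    sl <- stats::lm(bisq_attention_memory ~ days_to_test,
                    data = cohort[conc, ])
    cf <- summary(sl)$coefficients
    out$bisq_slope <- list(slope = cf["days_to_test", "Estimate"],
                           t = cf["days_to_test", "t value"],
                           p = cf["days_to_test", "Pr(>|t|)"])
  } else notes <- c(notes, "bisq_slope skipped: too few evaluated athletes")

  hi <- !is.na(cohort$sd_radial) & !is.na(cohort$prior_head_injury)
  g1 <- hi & cohort$prior_head_injury == 1
  g0 <- hi & cohort$prior_head_injury == 0
  if (sum(g1) >= 2 && sum(g0) >= 2) {
    tt2 <- stats::t.test(cohort$sd_radial[g1], cohort$sd_radial[g0],
                         var.equal = TRUE)
    out$sd_radial_head_injury <- list(t = unname(tt2$statistic),
                                      df = unname(tt2$parameter),
                                      p = tt2$p.value)
  } else notes <- c(notes, "sd_radial_head_injury skipped: group with < 2 members")

  ok <- !is.na(cohort$sd_radial) & !is.na(cohort$rpq_sleep)
  if (sum(ok) >= 3) {
    out$sd_radial_sleep <- list(
      r = stats::cor(cohort$sd_radial[ok], cohort$rpq_sleep[ok]))
  } else notes <- c(notes, "sd_radial_sleep skipped: too few complete pairs")

  structure(c(out, list(notes = notes)), class = "auxiliary_checks")
}
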