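#' Cohort generator configuration
#'
#' Marginal distributions for the synthetic athlete cohort and the logistic
#' outcome model for a significant post-concussion symptom burden. Defaults
#' reproduce the reference cohort's marginals: age 18.6 (SD 3.0) years on
#' 12-30, 62% male, 53% Caucasian, 27.5% prior head injury, and a 2.9%
#' concussion incidence; default outcome log-odds are the summary-model
#' effect sizes (prior head injury OR 3.15, SD radial OR 2.55 per degree,
#' ADHD inattention OR 1.035 per T point, age OR 0.875 per year, and the
#' RPQ noise/sleep/irritability item effects).
#'
#' @param n_athletes number of athletes.
#' @param concussion_rate probability of sustaining a concussion.
#' @param symptomatic_rate target marginal probability that a concussed
#'   athlete still carries a significant symptom burden when tested (drives
#'   the outcome-model intercept).
#' @param age_mean,age_sd,age_range age marginal (truncated normal, years).
#' @param p_male,p_caucasian,p_prior_head_injury,p_learning_disability,p_psychiatric,p_neurological
#'   Bernoulli proportions for the categorical characteristics.
#' @param pursuit_means,pursuit_sds named length-6 vectors of pursuit-metric
#'   marginals (`sd_radial`, `sd_tangential`, `mean_radial_error`,
#'   `phase_error_mean`, `gain_h`, `gain_v`).
#' @param outcome_coefficients named log-odds for P(symptomatic | concussed);
#'   names must be among the generated model covariates (`age`,
#'   `prior_head_injury`, `sd_radial`, `adhd_inattention_t`, `anxiety_z`,
#'   `rpq_noise`, `rpq_sleep`, `rpq_irritable`).
#' @param bisq_cutoff symptom-burden classification cutoff on the BISQ
#'   attention-memory score.
#' @param bisq_fidelity probability that the generated BISQ score falls on
#'   the side of the cutoff dictated by the latent symptomatic state.
#' @param days_mean,days_sd,days_range time from injury to post-concussion
#'   testing (truncated normal, days); the default upper bound of 16 lets a
#'   small fraction of assessments fall outside the 14-day analysis window.
#' @param missing_pursuit,missing_cognitive,missing_rpq,missing_psych
#'   per-block probabilities that an athlete's block of measures is missing;
#'   the pursuit default mirrors the high technical-failure rate of
#'   eye-movement screening.
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_athletes = 3091, concussion_rate = 0.029,
                          symptomatic_rate = 0.39,
                          age_mean = 18.6, age_sd = 3.0, age_range = c(12, 30),
                          p_male = 0.62, p_caucasian = 0.53,
                          p_prior_head_injury = 0.275,
                          p_learning_disability = 0.085,
                          p_psychiatric = 0.072, p_neurological = 0.035,
                          pursuit_means = c(sd_radial = 0.68,
                                            sd_tangential = 0.95,
                                            mean_radial_error = 0.10,
                                            phase_error_mean = -4.0,
                                            gain_h = 0.95, gain_v = 0.90),
                          pursuit_sds = c(sd_radial = 0.30,
                                          sd_tangential = 0.35,
                                          mean_radial_error = 0.30,
                                          phase_error_mean = 3.0,
                                          gain_h = 0.08, gain_v = 0.10),
                          outcome_coefficients = c(
                            age = log(0.875),
                            prior_head_injury = log(3.152),
                            sd_radial = log(2.553),
                            adhd_inattention_t = log(1.035),
                            anxiety_z = log(0.944),
                            rpq_noise = log(1.479),
                            rpq_sleep = log(1.217),
                            rpq_irritable = log(1.120)),
                          bisq_cutoff = 0.53, bisq_fidelity = 1.0,
                          days_mean = 5.8, days_sd = 3.5,
                          days_range = c(0, 16),
                          missing_pursuit = 0.266, missing_cognitive = 0.02,
                          missing_rpq = 0.02, missing_psych = 0.02,
                          seed = NULL) {
  stopifnot(n_athletes >= 1,
            concussion_rate >= 0, concussion_rate <= 1,
            symptomatic_rate > 0, symptomatic_rate < 1,
            bisq_fidelity >= 0, bisq_fidelity <= 1,
            all(c(missing_pursuit, missing_cognitive, missing_rpq,
                  missing_psych) >= 0))
  allowed <- c("age", "prior_head_injury", "sd_radial", "adhd_inattention_t",
               "anxiety_z", "rpq_noise", "rpq_sleep", "rpq_irritable")
  if (length(outcome_coefficients) &&
      !all(names(outcome_coefficients) %in% allowed))
    stop("outcome_coefficients named for an absent feature: ",
         paste(setdiff(names(outcome_coefficients), allowed), collapse = ", "))
  cfg <- mget(names(formals(cohort_config)), envir = environment())
  structure(cfg, class = "cohort_config")
}

# truncated normal whose *truncated* mean equals `mean`: the location of the
# parent normal is shifted to undo the truncation bias
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       interval = c(lo - 2 * sd, hi + 2 * sd),
                       tol = 1e-10)$root
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

rpq_item <- function(n) pmin(stats::rpois(n, 0.4), 4L)

# expected covariate means under the config, used to centre the outcome
# model's linear predictor so the intercept hits symptomatic_rate
outcome_covariate_means <- function(config) {
  c(age = config$age_mean,
    prior_head_injury = config$p_prior_head_injury,
    sd_radial = unname(config$pursuit_means["sd_radial"]),
    adhd_inattention_t = 50,
    anxiety_z = 0,
    rpq_noise = 0.4, rpq_sleep = 0.4, rpq_irritable = 0.4)
}

#' Simulate an athlete cohort
#'
#' Draws per-athlete baseline characteristics from the configured marginals,
#' assigns concussion by a Bernoulli draw, and for concussed athletes draws
#' a latent symptomatic state from the logistic outcome model. The BISQ
#' attention-memory score is then generated on the side of the cutoff the
#' latent state dictates (with probability `bisq_fidelity`), and testing
#' delay from a truncated normal. Blocks of measures are made missing at
#' random at the configured rates. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A data.frame (one row per athlete) with the documented cohort
#'   columns; the true outcome-model specification used for generation is
#'   attached as attribute `"truth"`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_athletes
    d <- data.frame(id = sprintf("A%05d", seq_len(n)))
    d$age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                         config$age_range[1], config$age_range[2])
    d$male <- stats::rbinom(n, 1, config$p_male)
    d$caucasian <- stats::rbinom(n, 1, config$p_caucasian)
    d$prior_head_injury <- stats::rbinom(n, 1, config$p_prior_head_injury)
    d$learning_disability <- stats::rbinom(n, 1, config$p_learning_disability)
    d$psychiatric <- stats::rbinom(n, 1, config$p_psychiatric)
    d$neurological <- stats::rbinom(n, 1, config$p_neurological)

    for (m in names(config$pursuit_means))
      d[[m]] <- stats::rnorm(n, config$pursuit_means[[m]],
                             config$pursuit_sds[[m]])
    d$sd_radial <- pmax(d$sd_radial, 0.02)
    d$sd_tangential <- pmax(d$sd_tangential, 0.02)
    d$gain_h <- pmax(d$gain_h, 0.05)
    d$gain_v <- pmax(d$gain_v, 0.05)

    d$srt_median_rt <- stats::rnorm(n, 230, 30)
    d$srt_rt_sd <- pmax(stats::rnorm(n, 40, 15), 3)
    d$srt_throughput <- stats::rnorm(n, 250, 30)
    d$trails_a_time <- pmax(stats::rnorm(n, 25, 8), 8)
    d$trails_b_time <- pmax(stats::rnorm(n, 55, 20), 15)
    d$trails_a_errors <- stats::rpois(n, 0.2)
    d$trails_b_errors <- stats::rpois(n, 0.5)
    d$trails_a_ss <- stats::rnorm(n, 50, 10)
    d$trails_b_ss <- stats::rnorm(n, 50, 10)

    rpq_items <- c("headaches", "dizziness", "nausea", "noise", "sleep",
                   "fatigue", "irritable", "depressed", "frustrated",
                   "forgetfulness", "concentration", "longer_to_think",
                   "vision", "light", "double_vision", "restlessness",
                   "balance", "mental_fogginess", "drowsiness")
    for (it in rpq_items) d[[paste0("rpq_", it)]] <- rpq_item(n)

    youth <- d$age < 18
    d$bai <- ifelse(youth, NA, pmax(round(stats::rnorm(n, 6, 6)), 0))
    d$cesd <- ifelse(youth, NA, pmax(round(stats::rnorm(n, 10, 7)), 0))
    for (v in c("caars_inattention", "caars_hyperactivity",
                "caars_impulsivity", "caars_self_concept",
                "caars_adhd_index"))
      d[[v]] <- ifelse(youth, NA, stats::rnorm(n, 50, 10))
    d$bai_y <- ifelse(youth, stats::rnorm(n, 50, 10), NA)
    d$bdi_y <- ifelse(youth, stats::rnorm(n, 50, 10), NA)
    for (v in c("conners3_inattention", "conners3_hyperactive_impulsive",
                "conners3_learning_problems", "conners3_defiance_aggression",
                "conners3_family_relations"))
      d[[v]] <- ifelse(youth, stats::rnorm(n, 50, 10), NA)

    # model covariates as the generator sees them
    X <- cbind(
      age = d$age,
      prior_head_injury = d$prior_head_injury,
      sd_radial = d$sd_radial,
      adhd_inattention_t = ifelse(youth, d$conners3_inattention,
                                  d$caars_inattention),
      anxiety_z = ifelse(youth, (d$bai_y - 50) / 10, (d$bai - 6) / 6),
      rpq_noise = d$rpq_noise,
      rpq_sleep = d$rpq_sleep,
      rpq_irritable = d$rpq_irritable)

    beta <- config$outcome_coefficients
    mu <- outcome_covariate_means(config)
    eta0 <- stats::qlogis(config$symptomatic_rate)
    intercept <- eta0 - if (length(beta)) sum(beta * mu[names(beta)]) else 0
    eta <- intercept + if (length(beta))
      drop(X[, names(beta), drop = FALSE] %*% beta) else 0

    d$concussed <- stats::rbinom(n, 1, config$concussion_rate)
    symptomatic <- rep(NA, n)
    ci <- which(d$concussed == 1)
    symptomatic[ci] <- stats::rbinom(length(ci), 1, stats::plogis(eta[ci]))

    d$days_to_test <- NA_real_
    d$days_to_test[ci] <- rtruncnorm1(length(ci), config$days_mean,
                                      config$days_sd, config$days_range[1],
                                      config$days_range[2])

    d$bisq_attention_memory <- NA_real_
    if (length(ci)) {
      side <- symptomatic[ci] == 1
      flip <- stats::runif(length(ci)) > config$bisq_fidelity
      side <- xor(side, flip)
      lo <- stats::rbeta(length(ci), 2, 5) * config$bisq_cutoff
      hi <- config$bisq_cutoff +
        stats::rbeta(length(ci), 2, 5) * (3 - config$bisq_cutoff)
      d$bisq_attention_memory[ci] <- ifelse(side, hi, lo)
    }

    # block-wise missingness (MCAR)
    blocks <- list(
      pursuit = names(config$pursuit_means),
      cognitive = c("srt_median_rt", "srt_rt_sd", "srt_throughput",
                    "trails_a_time", "trails_b_time", "trails_a_errors",
                    "trails_b_errors", "trails_a_ss", "trails_b_ss"),
      rpq = paste0("rpq_", rpq_items),
      psych = c("bai", "cesd", "bai_y", "bdi_y",
                grep("^caars_|^conners3_", names(d), value = TRUE)))
    rates <- c(pursuit = config$missing_pursuit,
               cognitive = config$missing_cognitive,
               rpq = config$missing_rpq, psych = config$missing_psych)
    for (b in names(blocks)) {
      gone <- stats::runif(n) < rates[[b]]
      d[gone, blocks[[b]]] <- NA
    }

    attr(d, "truth") <- list(intercept = intercept, coefficients = beta,
                             design = X, symptomatic = symptomatic)
    d
  })
}

#' Deterministic participant-flow fixture
#'
#' A fixed cohort whose counts reproduce the reference participant flow
#' exactly: 3091 baseline-tested athletes, 90 concussed, exactly one
#' concussed athlete assessed outside the 14-day window, and among the 89
#' evaluated athletes a 35/54 split into significantly symptomatic (BISQ
#' attention-memory score at or above 0.53) and resolved. Testing delays of
#' the evaluated athletes lie in \[0, 14\] days with mean exactly 5.8. Group
#' marginals (age, prior head injury, race, sex, learning disability,
#' psychiatric and neurological history) follow the reference sample
#' characteristics. No random number is drawn.
#'
#' @param scale positive scaling factor; counts are multiplied by `scale`
#'   and rounded half up, giving proportionally reduced fixtures for fast
#'   checks. `scale = 1` reproduces the flow exactly.
#' @return A cohort data.frame in the same schema as [simulate_cohort()].
#' @export
make_flow_fixture <- function(scale = 1) {
  stopifnot(scale > 0)
  rnd <- function(x) floor(x * scale + 0.5)
  n_control <- rnd(3001)
  n_sympt <- rnd(35)
  n_resolved <- rnd(54)
  n_late <- rnd(1)
  n <- n_control + n_sympt + n_resolved + n_late

  # deterministic flag vector with k ones spread evenly over n slots
  spread <- function(k, n) {
    f <- integer(n)
    if (k > 0) f[floor((seq_len(k) - 0.5) * n / k) + 1L] <- 1L
    f
  }
  # deterministic ages: equally spaced normal quantiles, truncated range,
  # assigned in a fixed stride permutation so row order carries no age trend
  stride_perm <- function(m) {
    s <- 7L
    while (m > 1 && gcd2(s, m) != 1L) s <- s + 2L
    ((seq_len(m) - 1L) * s) %% m + 1L
  }
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  ages <- function(n, mean, sd) {
    q <- stats::qnorm((seq_len(n) - 0.5) / n, mean, sd)
    pmin(pmax(q, 12), 30)[stride_perm(n)]
  }

  group <- c(rep("control", n_control), rep("symptomatic", n_sympt),
             rep("resolved", n_resolved), rep("late", n_late))
  d <- data.frame(id = sprintf("F%05d", seq_len(n)), group = group,
                  stringsAsFactors = FALSE)

  fill <- function(d, rows, age_mean, age_sd, props) {
    m <- sum(rows)
    d$age[rows] <- ages(m, age_mean, age_sd)
    for (v in names(props)) d[[v]][rows] <- spread(rnd2(props[[v]], m), m)
    d
  }
  rnd2 <- function(p, m) floor(p * m + 0.5)
  d$age <- NA_real_
  for (v in c("male", "caucasian", "prior_head_injury",
              "learning_disability", "psychiatric", "neurological"))
    d[[v]] <- NA_integer_
  ctrl_props <- c(male = 0.621, caucasian = 0.529, prior_head_injury = 0.275,
                  learning_disability = 0.085, psychiatric = 0.072,
                  neurological = 0.035)
  case_props <- c(male = 0.514, caucasian = 0.400, prior_head_injury = 0.514,
                  learning_disability = 0.086, psychiatric = 0.086,
                  neurological = 0.057)
  d <- fill(d, d$group == "control", 18.6, 3.0, ctrl_props)
  d <- fill(d, d$group != "control", 17.5, 2.9, case_props)

  d$concussed <- as.integer(d$group != "control")

  # testing delays of the evaluated concussed athletes: fixed multiset on
  # [0, 14] days with mean exactly 5.8 (tenth-precision; 89 integers cannot
  # average exactly 5.8)
  n_eval <- n_sympt + n_resolved
  base_days <- c(rep(0:14, length.out = n_eval))
  base_days <- sort(base_days)
  target_sum <- round(5.8 * n_eval, 1)
  delta <- target_sum - sum(base_days)
  # absorb the adjustment over the middle entries, one unit at a time
  i <- which.min(abs(base_days - 7))
  while (abs(delta) >= 1) {
    step <- sign(delta)
    cand <- which(base_days + step >= 0 & base_days + step <= 14)
    j <- cand[((i - 1) %% length(cand)) + 1]
    base_days[j] <- base_days[j] + step
    delta <- delta - step
    i <- i + 1
  }
  if (abs(delta) > 1e-9) {
    j <- which(base_days + delta >= 0 & base_days + delta <= 14)[1]
    base_days[j] <- base_days[j] + delta
  }
  d$days_to_test <- NA_real_
  d$days_to_test[d$group %in% c("symptomatic", "resolved")] <-
    base_days[stride_perm(n_eval)]
  d$days_to_test[d$group == "late"] <- 16

  # BISQ scores: symptomatic at/above the 0.53 cutoff, resolved below
  d$bisq_attention_memory <- NA_real_
  si <- which(d$group == "symptomatic")
  ri <- which(d$group == "resolved")
  d$bisq_attention_memory[si] <-
    0.53 + 2.0 * (seq_along(si) - 1) / max(length(si), 1)
  d$bisq_attention_memory[ri] <-
    0.50 * (seq_along(ri) - 1) / max(length(ri), 1)
  d$bisq_attention_memory[d$group == "late"] <- 1.0

  # remaining schema columns: deterministic patterned values (no signal, no
  # randomness) so the fixture carries the full cohort schema
  det <- function(mean, spread, period, offset = 0)
    mean + spread * ((((seq_len(n) + offset) * 7) %% period) / period - 0.5)
  d$sd_radial <- det(0.68, 0.6, 101)
  d$sd_tangential <- det(0.95, 0.7, 103)
  d$mean_radial_error <- det(0.10, 0.6, 107)
  d$phase_error_mean <- det(-4, 6, 109)
  d$gain_h <- det(0.95, 0.16, 113)
  d$gain_v <- det(0.90, 0.2, 127)
  d$srt_median_rt <- det(230, 60, 131)
  d$srt_rt_sd <- det(40, 30, 137)
  d$srt_throughput <- det(250, 60, 139)
  d$trails_a_time <- det(25, 16, 149)
  d$trails_b_time <- det(55, 40, 151)
  d$trails_a_errors <- (seq_len(n) * 2) %% 3L
  d$trails_b_errors <- (seq_len(n) * 5 + 1) %% 4L
  d$trails_a_ss <- det(50, 20, 157)
  d$trails_b_ss <- det(50, 20, 163)
  rpq_items <- c("headaches", "dizziness", "nausea", "noise", "sleep",
                 "fatigue", "irritable", "depressed", "frustrated",
                 "forgetfulness", "concentration", "longer_to_think",
                 "vision", "light", "double_vision", "restlessness",
                 "balance", "mental_fogginess", "drowsiness")
  rpq_primes <- c(5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L, 43L,
                  47L, 53L, 59L, 61L, 67L, 71L, 73L)
  for (k in seq_along(rpq_items))
    d[[paste0("rpq_", rpq_items[k])]] <-
      ((seq_len(n) * (k + 3L) + k) %% rpq_primes[k]) %% 4L
  youth <- d$age < 18
  nv <- function(mean, spread, period) ifelse(youth, NA, det(mean, spread, period))
  yv <- function(mean, spread, period) ifelse(youth, det(mean, spread, period), NA)
  d$bai <- nv(6, 8, 167); d$cesd <- nv(10, 10, 173)
  d$caars_inattention <- nv(50, 20, 179)
  d$caars_hyperactivity <- nv(50, 20, 181)
  d$caars_impulsivity <- nv(50, 20, 191)
  d$caars_self_concept <- nv(50, 20, 193)
  d$caars_adhd_index <- nv(50, 20, 197)
  d$bai_y <- yv(50, 20, 199); d$bdi_y <- yv(50, 20, 211)
  d$conners3_inattention <- yv(50, 20, 223)
  d$conners3_hyperactive_impulsive <- yv(50, 20, 227)
  d$conners3_learning_problems <- yv(50, 20, 229)
  d$conners3_defiance_aggression <- yv(50, 20, 233)
  d$conners3_family_relations <- yv(50, 20, 239)

  d$group <- NULL
  d
}
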