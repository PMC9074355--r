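#' Configuration for a synthetic breast-cancer cohort
#'
#' Defines a cohort whose histologic grade, mitotic count and cause-specific
#' death hazards all depend on an underlying true Ki-67 proliferation
#' fraction, mirroring the structure of a population-based breast-cancer
#' series with long follow-up: three grades, mitoses per 10 high-power
#' fields, molecular subtype as a categorical covariate, and death from
#' breast cancer competing with death from other causes.
#'
#' The generative model: a grade component is drawn from `grade_probs`;
#' true Ki-67 is drawn from the grade-specific Beta distribution; the
#' mitotic count is negative-binomial with mean increasing in Ki-67;
#' cause-specific event times are exponential with log-linear hazards in
#' true Ki-67, and follow-up is administratively censored.
#'
#' @param n_patients Cohort size (default 248).
#' @param true_ki67_distribution Named list `grade1/grade2/grade3` of Beta
#'   shape pairs for true Ki-67 (a fraction in `[0, 1]`).
#' @param grade_probs Probabilities of grades 1-3; must sum to 1.
#' @param mitoses_dispersion Negative-binomial size parameter for the
#'   mitotic count (smaller = more overdispersed).
#' @param hazard_bc,hazard_other Lists with `rate` (baseline events/year at
#'   Ki-67 = 0) and `beta` (log-hazard slope per unit true Ki-67 fraction).
#' @param admin_censor_years Administrative censoring horizon.
#' @param seed Integer seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 248,
                          true_ki67_distribution = list(
                            grade1 = c(2.0, 12.0),
                            grade2 = c(2.5, 7.0),
                            grade3 = c(5.0, 6.0)),
                          grade_probs = c(0.065, 0.528, 0.407),
                          mitoses_dispersion = 3,
                          hazard_bc = list(rate = 0.030, beta = 2.5),
                          hazard_other = list(rate = 0.050, beta = 0),
                          admin_censor_years = 30,
                          seed = 1L) {
  stopifnot(n_patients >= 1, mitoses_dispersion > 0,
            hazard_bc$rate > 0, hazard_other$rate > 0,
            admin_censor_years >= 0)
  if (abs(sum(grade_probs) - 1) > 1e-8)
    stop("`grade_probs` must sum to 1")
  if (length(grade_probs) != 3)
    stop("`grade_probs` must have length 3 (grades 1-3)")
  structure(
    list(n_patients = as.integer(n_patients),
         true_ki67_distribution = true_ki67_distribution,
         grade_probs = grade_probs,
         mitoses_dispersion = mitoses_dispersion,
         hazard_bc = hazard_bc, hazard_other = hazard_other,
         admin_censor_years = admin_censor_years,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a synthetic patient cohort with competing risks
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient: `patient_id`, `true_ki67`
#'   (fraction), `grade` (1-3), `mitoses_10hpf`, `subtype`, `time_years`
#'   and `event` (factor with levels censored, bc_death, other_death).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    n <- config$n_patients
    grade <- sample.int(3, n, replace = TRUE, prob = config$grade_probs)
    shp <- config$true_ki67_distribution
    ki67 <- numeric(n)
    for (g in 1:3) {
      idx <- which(grade == g)
      s <- shp[[paste0("grade", g)]]
      if (length(idx)) ki67[idx] <- stats::rbeta(length(idx), s[1], s[2])
    }
    mit_mean <- 1.5 + 28 * ki67
    mitoses <- stats::rnbinom(n, size = config$mitoses_dispersion,
                              mu = mit_mean)
    # subtype probabilities shift towards aggressive phenotypes with Ki-67
    sub_levels <- c("LuminalA", "LuminalB_HER2neg", "LuminalB_HER2pos",
                    "HER2", "TN")
    subtype <- vapply(ki67, function(k) {
      w <- c(LuminalA = exp(-4 * k) * 2.2,
             LuminalB_HER2neg = 0.9 + 1.2 * k,
             LuminalB_HER2pos = 0.35,
             HER2 = 0.10 + 0.25 * k,
             TN = 0.10 + 0.45 * k)
      sample(sub_levels, 1, prob = w)
    }, character(1))
    t_bc <- stats::rexp(n, config$hazard_bc$rate *
                          exp(config$hazard_bc$beta * ki67))
    t_ot <- stats::rexp(n, config$hazard_other$rate *
                          exp(config$hazard_other$beta * ki67))
    time <- pmin(t_bc, t_ot, config$admin_censor_years)
    event <- ifelse(time == config$admin_censor_years, "censored",
                    ifelse(t_bc <= t_ot, "bc_death", "other_death"))
    tibble::tibble(
      patient_id = seq_len(n),
      true_ki67 = ki67,
      grade = grade,
      mitoses_10hpf = as.integer(mitoses),
      subtype = factor(subtype, levels = sub_levels),
      time_years = time,
      event = factor(event, levels = c("censored", "bc_death", "other_death"))
    )
  })
}
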