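toy_records <- function(time, event) {
  tibble::tibble(time_years = time,
                 event = factor(event, levels = c("censored", "bc_death",
                                                  "other_death")))
}

test_that("Pearson chi-squared matches hand computation", {
  even <- pearson_chi2(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  diag2 <- pearson_chi2(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(diag2$statistic, 40)
  expect_equal(diag2$df, 1)

  m <- matrix(c(12, 5, 9, 20, 7, 3), 2, 3)
  expect_equal(pearson_chi2(m)$statistic,
               pearson_chi2(m[2:1, c(2, 3, 1)])$statistic)
  expect_error(pearson_chi2(matrix(c(1, 1, 0, 0), 2, 2)), "marginal")
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
})

test_that("Bland-Altman agreement has the defined bias and limits", {
  x <- c(10, 20, 30, 40, 55)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)

  ba5 <- bland_altman(x, x + 5)
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$sd_diff, 0)

  prop <- bland_altman(x, x * 1.2)
  expect_gt(prop$slope, 0)
  expect_equal(prop$loa_high - prop$loa_low, 2 * 1.96 * prop$sd_diff)
  expect_error(bland_altman(x, x[-1]), "lengths differ")
})

test_that("the Aalen-Johansen estimator matches the 3-subject hand result", {
  toy <- toy_records(c(1, 2, 3), c("bc_death", "other_death", "censored"))
  cif <- cumulative_incidence(toy)
  at <- cif_at(cif, times = c(1, 2, 3))
  bc <- at[at$event == "bc_death", ]
  ot <- at[at$event == "other_death", ]
  expect_equal(bc$estimate[bc$time == 1], 1 / 3)
  expect_equal(bc$estimate[bc$time == 3], 1 / 3)
  expect_equal(ot$estimate[ot$time == 2], 1 / 3)
})

test_that("with no events the cumulative incidence is identically zero", {
  rec <- toy_records(1:10, rep("censored", 10))
  cif <- cumulative_incidence(rec)
  expect_true(nrow(cif) == 0 || all(cif$estimate == 0))
})

test_that("without competing events the CIF equals 1 - Kaplan-Meier exactly", {
  rec <- withr::with_seed(2, toy_records(
    round(stats::rexp(150, 0.1), 3),
    sample(c("censored", "bc_death"), 150, replace = TRUE)))
  cif <- cumulative_incidence(rec)
  f <- cif[cif$event == "bc_death", ]
  post <- stats::aggregate(estimate ~ time, data = f, FUN = max)
  km <- survival::survfit(
    survival::Surv(time_years, event == "bc_death") ~ 1, data = rec)
  sm <- summary(km, times = post$time)
  expect_equal(post$estimate, 1 - sm$surv, tolerance = 1e-12)
})

test_that("CIF curves are monotone and sum to at most one", {
  co <- simulate_cohort(cohort_config(n_patients = 400, seed = 31))
  co$grp <- ifelse(co$true_ki67 > 0.3, "High", "Low")
  cif <- cumulative_incidence(co, "grp")
  for (g in unique(cif$group)) for (e in unique(cif$event)) {
    est <- cif$estimate[cif$group == g & cif$event == e]
    expect_true(all(diff(est) >= -1e-12))
  }
  at <- cif_at(cif, times = c(5, 10, 20))
  tot <- stats::aggregate(estimate ~ group + time, data = at, FUN = sum)
  expect_true(all(tot$estimate <= 1 + 1e-9))
})

test_that("Gray's test is null on exchangeable groups and detects separation", {
  rec <- withr::with_seed(3, toy_records(
    round(stats::rexp(100, 0.1), 2),
    sample(c("censored", "bc_death", "other_death"), 100, replace = TRUE)))
  dup <- dplyr::bind_rows(rec, rec)
  dup$grp <- rep(c("a", "b"), each = 100)
  g <- gray_test(dup, "grp")
  expect_lt(g$statistic, 1e-9)
  expect_gt(g$p_value, 0.999)

  swapped <- dup
  swapped$grp <- ifelse(dup$grp == "a", "b", "a")
  expect_equal(gray_test(swapped, "grp")$statistic, g$statistic,
               tolerance = 1e-12)

  # strongly separated cause-specific hazards (HR 3, n = 500/group)
  pow <- withr::with_seed(4, {
    n <- 500
    mk <- function(rate, grp) {
      t_bc <- stats::rexp(n, rate); t_ot <- stats::rexp(n, 0.05)
      tm <- pmin(t_bc, t_ot, 15)
      ev <- ifelse(tm == 15, "censored",
                   ifelse(t_bc <= t_ot, "bc_death", "other_death"))
      out <- toy_records(tm, ev); out$grp <- grp; out
    }
    dplyr::bind_rows(mk(0.03, "low"), mk(0.09, "high"))
  })
  expect_lt(gray_test(pow, "grp")$p_value, 0.01)
})

test_that("Cox partial likelihood matches a grid-search oracle", {
  rec <- toy_records(c(1, 2, 3, 4),
                     c("bc_death", "bc_death", "censored", "bc_death"))
  rec$x <- c(1, 0, 1, 0)
  # brute-force partial log-likelihood for this 4-subject instance
  pll <- function(b) {
    log(exp(b) / (2 * exp(b) + 2)) + log(1 / (1 + exp(b) + 1)) + log(1)
  }
  oracle <- stats::optimize(pll, c(-6, 6), maximum = TRUE)$maximum
  fit <- tidy(cox_ph(rec, "x"))
  expect_equal(fit$estimate, oracle, tolerance = 1e-4)
})

test_that("Cox recovers a known log-hazard ratio", {
  rec <- withr::with_seed(8, {
    n <- 4000
    x <- stats::rbinom(n, 1, 0.5)
    tm <- stats::rexp(n, 0.05 * exp(log(2) * x))
    cen <- pmin(tm, 12)
    toy_records(cen, ifelse(tm <= 12, "bc_death", "censored")) |>
      dplyr::mutate(x = x)
  })
  fit <- tidy(cox_ph(rec, "x"))
  expect_lt(abs(fit$estimate - log(2)) / log(2), 0.1)

  # independent covariate: CI covers 1
  rec$z <- withr::with_seed(9, stats::rnorm(nrow(rec)))
  fz <- tidy(cox_ph(rec, "z"))
  expect_true(fz$conf_low < 1 && fz$conf_high > 1)
})

test_that("competing events are censored in the cause-specific Cox model", {
  co <- simulate_cohort(cohort_config(n_patients = 800, seed = 41))
  fit <- cox_ph(co, "true_ki67")
  expect_equal(fit$fit$nevent, sum(co$event == "bc_death"))
})

test_that("Harrell's C spans perfect, random and degenerate orderings", {
  n <- 60
  rec <- toy_records(sort(stats::runif(n, 1, 10)), rep("bc_death", n))
  # higher risk score = shorter survival: perfect concordance
  expect_equal(harrell_c(rec, rev(seq_len(n)))$c_index, 1.0)
  expect_equal(harrell_c(rec, rep(1, n))$c_index, 0.5)

  rnd <- withr::with_seed(10, {
    m <- 1000
    r <- toy_records(stats::rexp(m, 0.1),
                     sample(c("bc_death", "censored"), m, replace = TRUE))
    harrell_c(r, stats::rnorm(m))
  })
  expect_lt(abs(rnd$c_index - 0.5), 3 * rnd$std_error)
})

test_that("the characteristic-by-category table sums and percentages close", {
  co <- simulate_cohort(cohort_config(n_patients = 300, seed = 13))
  sc <- derive_cutoffs(100 * stats::median(co$true_ki67), "DIA")
  co$ki67_cat <- classify_case(100 * co$true_ki67, sc)
  t1 <- build_table1(co, "ki67_cat")
  s <- t1$summary
  for (ch in unique(s$characteristic)) for (cat in unique(s$category)) {
    sub <- s[s$characteristic == ch & s$category == cat, ]
    expect_equal(sum(sub$n),
                 sum(co$ki67_cat == cat))
    expect_equal(sum(sub$pct), 100, tolerance = 1e-9)
  }
  expect_true(all(t1$tests$statistic >= 0, na.rm = TRUE))

  # single-category cohort: that column holds 100% of every characteristic
  co1 <- co; co1$ki67_cat <- factor("High", levels = levels(co$ki67_cat))
  t2 <- build_table1(co1, "ki67_cat")
  high <- t2$summary[t2$summary$category == "High", ]
  expect_equal(sum(high$pct),
               100 * length(unique(high$characteristic)), tolerance = 1e-9)
})
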