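#' Pearson's chi-squared test on a contingency table
#'
#' Classic uncorrected Pearson test: `sum((O - E)^2 / E)` with expected
#' counts from the product of the marginals and `(r-1)(c-1)` degrees of
#' freedom.
#'
#' @param counts Numeric matrix of nonnegative counts.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("every row and column marginal must be positive")
  ct <- stats::chisq.test(counts, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' Column percentages of a count table
#'
#' Percentages of each count within its column total - the layout used for
#' characteristic-by-category cohort tables (each Ki-67 category column
#' sums to 100% over the levels of a characteristic).
#'
#' @param counts Numeric matrix (levels x categories).
#' @return Matrix of percentages.
#' @export
column_percentages <- function(counts) {
  counts <- as.matrix(counts)
  sweep(counts, 2, colSums(counts), "/") * 100
}

#' Bland-Altman agreement between two scoring methods
#'
#' Differences are `comparator - reference`; the bias is their mean, the
#' limits of agreement are `bias +/- 1.96 * sd` (n-1 denominator). The
#' slope of the differences on the pair means is also fitted, to quantify
#' proportional bias (differences growing with the measured level).
#'
#' @param reference,comparator Equal-length paired numeric vectors.
#' @return A `ki67_ba` object: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `slope`, and a `data` tibble of per-pair (mean, difference).
#' @export
bland_altman <- function(reference, comparator) {
  if (length(reference) != length(comparator))
    stop("`reference` and `comparator` lengths differ (",
         length(reference), " vs ", length(comparator), ")")
  if (length(reference) < 2) stop("need at least 2 pairs")
  diffs <- comparator - reference
  means <- (comparator + reference) / 2
  bias <- mean(diffs)
  sdd <- stats::sd(diffs)
  slope <- if (stats::var(means) > 0)
    unname(stats::coef(stats::lm(diffs ~ means))[2]) else 0
  structure(
    list(bias = bias, sd_diff = sdd,
         loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
         slope = slope,
         data = tibble::tibble(mean = means, difference = diffs)),
    class = "ki67_ba"
  )
}

#' @export
print.ki67_ba <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.2f, SD %.2f, limits of agreement [%.2f, %.2f], slope on mean %.3f (n = %d)\n",
    x$bias, x$sd_diff, x$loa_low, x$loa_high, x$slope, nrow(x$data)))
  invisible(x)
}

#' Glance at a Bland-Altman analysis
#' @param x A `ki67_ba`.
#' @param ... Unused.
#' @return One-row tibble of the agreement summary.
#' @export
glance.ki67_ba <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 slope = x$slope, n = nrow(x$data))
}

check_records <- function(records) {
  need <- c("time_years", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort records lack column(s): ", paste(miss, collapse = ", "))
  if (any(records$time_years < 0)) stop("negative follow-up time")
  records
}

#' Cumulative incidence of an event under competing risks
#'
#' Aalen-Johansen estimator per group:
#' `CIF(t) = sum over event times <= t of S(t-) * d_event(t) / n(t)` with
#' `S` the all-cause Kaplan-Meier. Death from other causes is treated as a
#' competing event, not censoring. Pointwise confidence intervals use the
#' log(-log) transform.
#'
#' @param records Cohort tibble with `time_years` and `event` (factor with
#'   the censoring level first, e.g. censored / bc_death / other_death).
#' @param group Optional column name holding the group factor.
#' @param conf_level Confidence level (default 0.95).
#' @return A `ki67_cif` tibble: `group`, `event`, `time`, `estimate`,
#'   `std_error`, `conf_low`, `conf_high` step-function rows.
#' @export
cumulative_incidence <- function(records, group = NULL, conf_level = 0.95) {
  records <- check_records(records)
  grp <- if (is.null(group)) rep("all", nrow(records))
         else as.character(records[[group]])
  if (any(table(grp) == 0) || nrow(records) == 0)
    stop("empty group in cumulative incidence")
  fstatus <- as.character(records$event)
  if (all(fstatus == "censored")) {
    res <- tibble::tibble(group = character(), event = character(),
                          time = numeric(), estimate = numeric(),
                          std_error = numeric(), conf_low = numeric(),
                          conf_high = numeric())
    class(res) <- c("ki67_cif", class(res))
    return(res)
  }
  fit <- cmprsk::cuminc(ftime = records$time_years, fstatus = fstatus,
                        group = grp, cencode = "censored")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  curves <- fit[setdiff(names(fit), "Tests")]
  out <- lapply(names(curves), function(nm) {
    cu <- curves[[nm]]
    # cuminc names curves "<group> <event>"
    parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
    ev <- parts[length(parts)]
    g <- paste(parts[-length(parts)], collapse = " ")
    est <- cu$est
    se <- sqrt(pmax(cu$var, 0))
    lo <- hi <- rep(NA_real_, length(est))
    okc <- est > 0 & est < 1 & se > 0
    # log(-log) transform CI for a probability
    th <- z * se[okc] / (est[okc] * log(est[okc]))
    lo[okc] <- est[okc]^exp(-th)
    hi[okc] <- est[okc]^exp(th)
    swap <- okc & lo > hi
    tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
    tibble::tibble(group = g, event = ev, time = cu$time,
                   estimate = est, std_error = se,
                   conf_low = lo, conf_high = hi)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "tests") <- fit$Tests
  class(res) <- c("ki67_cif", class(res))
  res
}

#' Evaluate cumulative incidence at fixed times
#'
#' @param cif A `ki67_cif` from [cumulative_incidence()].
#' @param times Times to evaluate (default 5 and 10 years).
#' @return Tibble with one row per group x event x time (step-function
#'   value at the last event time <= t).
#' @export
cif_at <- function(cif, times = c(5, 10)) {
  stopifnot(inherits(cif, "ki67_cif"))
  combos <- unique(cif[c("group", "event")])
  out <- list()
  for (r in seq_len(nrow(combos))) {
    sub <- cif[cif$group == combos$group[r] & cif$event == combos$event[r], ]
    for (t in times) {
      i <- which(sub$time <= t)
      row <- if (length(i)) sub[max(i), ] else
        tibble::tibble(estimate = 0, std_error = 0,
                       conf_low = NA_real_, conf_high = NA_real_)
      out[[length(out) + 1]] <- tibble::tibble(
        group = combos$group[r], event = combos$event[r], time = t,
        estimate = row$estimate, std_error = row$std_error,
        conf_low = row$conf_low, conf_high = row$conf_high)
    }
  }
  dplyr::bind_rows(out)
}

#' Gray's test for equality of cumulative incidence curves
#'
#' K-sample test on the subdistribution hazard (rho = 0) of the event of
#' interest, with competing events handled as in [cumulative_incidence()].
#'
#' @param records Cohort tibble.
#' @param group Grouping column name.
#' @param event_of_interest Event level tested (default `"bc_death"`).
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
gray_test <- function(records, group, event_of_interest = "bc_death") {
  records <- check_records(records)
  grp <- as.character(records[[group]])
  if (length(unique(grp)) < 2) stop("need at least 2 groups")
  fit <- cmprsk::cuminc(ftime = records$time_years,
                        fstatus = as.character(records$event),
                        group = grp, cencode = "censored")
  tests <- fit$Tests
  if (is.null(tests) || !event_of_interest %in% rownames(tests))
    stop("no events of type `", event_of_interest, "` to test")
  tibble::tibble(statistic = tests[event_of_interest, "stat"],
                 df = tests[event_of_interest, "df"],
                 p_value = tests[event_of_interest, "pv"])
}

#' Cause-specific Cox proportional hazards model
#'
#' Fits the cause-specific hazard of the event of interest by partial
#' likelihood, censoring competing events at their event time. Ties use
#' the Efron method by default (switchable to Breslow).
#'
#' @param records Cohort tibble.
#' @param covariates Character vector of covariate column names.
#' @param event_of_interest Event level modelled (default `"bc_death"`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `ki67_cox` object wrapping the `survival::coxph` fit; see
#'   [tidy.ki67_cox()] for hazard ratios with Wald confidence intervals.
#' @export
cox_ph <- function(records, covariates, event_of_interest = "bc_death",
                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  records <- check_records(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss))
    stop("records lack covariate(s): ", paste(miss, collapse = ", "))
  status <- as.integer(records$event == event_of_interest)
  if (sum(status) == 0) stop("no events of type `", event_of_interest, "`")
  df <- records[covariates]
  df$.time <- records$time_years
  df$.status <- status
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox model failed to converge")
  structure(list(fit = fit, covariates = covariates,
                 event_of_interest = event_of_interest, ties = ties),
            class = "ki67_cox")
}

#' @export
print.ki67_cox <- function(x, ...) {
  cat("Cause-specific Cox model (", x$event_of_interest, ", ", x$ties,
      " ties)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a cause-specific Cox fit into hazard ratios
#' @param x A `ki67_cox`.
#' @param conf_level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log HR), `hr`, `std_error`,
#'   `conf_low`, `conf_high` (HR scale), `p_value`.
#' @export
tidy.ki67_cox <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$fit, conf.int = conf_level)
  co <- s$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = exp(co[, "coef"]),
    std_error = co[, "se(coef)"],
    conf_low = exp(co[, "coef"] - z * co[, "se(coef)"]),
    conf_high = exp(co[, "coef"] + z * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"]
  )
}

#' Glance at a cause-specific Cox fit
#' @param x A `ki67_cox`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `n_event`, `concordance`, `logLik`.
#' @export
glance.ki67_cox <- function(x, ...) {
  f <- x$fit
  tibble::tibble(n = f$n, n_event = f$nevent,
                 concordance = unname(f$concordance["concordance"]),
                 logLik = as.numeric(stats::logLik(f)))
}

#' Harrell's concordance index for a risk score
#'
#' Fraction of usable (comparable under censoring) pairs in which the
#' higher risk score has the shorter event time; tied scores count 0.5.
#' By default the event of interest defines failure and competing events
#' are censored at their time (cause-specific concordance); set
#' `all_cause = TRUE` to treat any death as the event.
#'
#' @param records Cohort tibble.
#' @param risk_scores Numeric vector aligned with `records` (higher =
#'   higher risk).
#' @param event_of_interest Event level (default `"bc_death"`).
#' @param all_cause If `TRUE`, any non-censored event counts as failure.
#' @return One-row tibble with `c_index`, `std_error`, `n`, `n_event`.
#' @export
harrell_c <- function(records, risk_scores,
                      event_of_interest = "bc_death", all_cause = FALSE) {
  records <- check_records(records)
  if (length(risk_scores) != nrow(records))
    stop("`risk_scores` must align with `records`")
  status <- if (all_cause) as.integer(records$event != "censored")
            else as.integer(records$event == event_of_interest)
  df <- data.frame(time = records$time_years, status = status,
                   score = risk_scores)
  fit <- survival::concordance(survival::Surv(time, status) ~ score,
                               data = df, reverse = TRUE)
  if (!is.finite(fit$concordance))
    stop("no usable pairs for concordance")
  tibble::tibble(c_index = fit$concordance,
                 std_error = sqrt(fit$var),
                 n = nrow(df), n_event = sum(status))
}

#' Characteristic-by-category cohort summary table
#'
#' For each characteristic, counts and column percentages per Ki-67
#' category (each category column sums to 100% over the characteristic's
#' levels) plus a Pearson chi-squared p-value. Mitotic counts are
#' summarized as cohort-quartile groups.
#'
#' @param records Cohort tibble.
#' @param category Column name of the Ki-67 category factor.
#' @param characteristics Columns to summarize (default grade, subtype and
#'   mitoses quartiles when present).
#' @return A list with `summary` (tibble: characteristic, level, category,
#'   n, pct) and `tests` (tibble: characteristic, statistic, df, p_value).
#' @export
build_table1 <- function(records, category, characteristics = NULL) {
  if (!category %in% names(records))
    stop("records lack category column `", category, "`")
  rec <- records
  if ("mitoses_10hpf" %in% names(rec)) {
    q <- stats::quantile(rec$mitoses_10hpf, c(0.25, 0.5, 0.75))
    rec$mitoses_quartile <- cut(
      rec$mitoses_10hpf, breaks = c(-Inf, q, Inf),
      labels = c(paste0("<=", q[1]), paste0(">", q[1], "-<=", q[2]),
                 paste0(">", q[2], "-<=", q[3]), paste0(">", q[3])))
  }
  if (is.null(characteristics))
    characteristics <- intersect(c("grade", "subtype", "mitoses_quartile"),
                                 names(rec))
  cat_f <- factor(rec[[category]])
  sm <- list(); ts <- list()
  for (ch in characteristics) {
    tab <- table(level = factor(rec[[ch]]), category = cat_f)
    pct <- column_percentages(tab)
    df <- as.data.frame.table(tab, responseName = "n")
    df$pct <- as.data.frame.table(pct)$Freq
    df$characteristic <- ch
    sm[[ch]] <- tibble::as_tibble(df[c("characteristic", "level",
                                       "category", "n", "pct")])
    ts[[ch]] <- tryCatch(
      dplyr::mutate(pearson_chi2(as.matrix(tab)), characteristic = ch,
                    .before = 1),
      error = function(e) tibble::tibble(characteristic = ch,
                                         statistic = NA_real_,
                                         df = NA_real_,
                                         p_value = NA_real_))
  }
  list(summary = dplyr::bind_rows(sm), tests = dplyr::bind_rows(ts))
}
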