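#' Cumulative Ki-67 percentages over 100-cell increments
#'
#' After each increment of `set_size` counted tumour nuclei, the cumulative
#' percentage is `100 * sum(n_positive[1..k]) / (set_size * k)`. Arithmetic
#' is exact; rounding to one decimal happens only in reports.
#'
#' @param n_positive Integer vector of positive counts per increment, each
#'   in `[0, set_size]`.
#' @param set_size Nuclei per increment (default 100).
#' @return Numeric vector of cumulative percentages, one per increment.
#' @examples
#' cumulative_percentages(c(40, 36, 30, 22, 22))
#' @export
cumulative_percentages <- function(n_positive, set_size = 100) {
  if (any(is.na(n_positive)) || any(n_positive < 0 | n_positive > set_size))
    stop("each count must lie in [0, ", set_size, "]")
  k <- seq_along(n_positive)
  100 * cumsum(n_positive) / (set_size * k)
}

#' Score a case from its counting increments
#'
#' @param increments A `ki67_increments` tibble from [select_increments()]
#'   (or any tibble with `rank` and `n_positive`).
#' @param case_id Case identifier.
#' @param method Scoring arm, `"DIA"` or `"VA"`.
#' @param set_size Nuclei per increment (default 100).
#' @return A tidy `case score` tibble: one row per increment with
#'   `case_id`, `method`, `increment`, `n_positive`, `cumulative_pct`.
#' @export
score_case <- function(increments, case_id, method = c("DIA", "VA"),
                       set_size = 100) {
  method <- match.arg(method)
  inc <- increments[order(increments$rank), , drop = FALSE]
  tibble::tibble(
    case_id = case_id,
    method = method,
    increment = inc$rank,
    n_positive = inc$n_positive,
    cumulative_pct = cumulative_percentages(inc$n_positive, set_size)
  )
}

#' Cohort median of the cumulative percentage at increment k
#'
#' @param scores Long case-score tibble (rows = case x increment) from
#'   [score_case()].
#' @param k Increment number (e.g. 5 for the 500-cell value).
#' @return The sample median (even n: mean of the middle pair).
#' @export
cohort_median <- function(scores, k = 5) {
  v <- scores$cumulative_pct[scores$increment == k]
  if (length(v) == 0) stop("no scores at increment ", k)
  stats::median(v)
}

#' Median-derived Low/Intermediate/High cut-offs
#'
#' Following the St. Gallen in-house-median convention: Ki-67 Low is more
#' than 10 percentage points below the cohort median, High more than 10
#' points above, Intermediate in between (boundaries inclusive to
#' Intermediate).
#'
#' @param median_pct Cohort median cumulative percentage.
#' @param method Label for the scoring arm (`"DIA"` or `"VA"`).
#' @return A `ki67_cutoffs` object with `low_below` (= median - 10) and
#'   `high_above` (= median + 10), clipped to `[0, 100]`.
#' @examples
#' derive_cutoffs(22.3, "VA")  # Low < 12.3, High > 32.3
#' @export
derive_cutoffs <- function(median_pct, method = "DIA") {
  if (median_pct < 10 || median_pct > 90)
    warning("median ", median_pct, "% leaves a degenerate Low or High ",
            "category; cut-offs clipped to [0, 100]")
  structure(
    list(method = method, median_pct = median_pct,
         low_below = max(0, median_pct - 10),
         high_above = min(100, median_pct + 10)),
    class = "ki67_cutoffs"
  )
}

#' @export
print.ki67_cutoffs <- function(x, ...) {
  cat(x$method, " cut-offs (median ", round(x$median_pct, 1), "%): Low < ",
      round(x$low_below, 1), "%, Intermediate ", round(x$low_below, 1),
      "-", round(x$high_above, 1), "%, High > ", round(x$high_above, 1),
      "%\n", sep = "")
  invisible(x)
}

#' Classify cases into Ki-67 Low / Intermediate / High
#'
#' @param value_pct Numeric vector of cumulative percentages.
#' @param scheme A `ki67_cutoffs` from [derive_cutoffs()].
#' @return Factor with levels Low, Intermediate, High.
#' @export
classify_case <- function(value_pct, scheme) {
  stopifnot(inherits(scheme, "ki67_cutoffs"))
  out <- ifelse(value_pct < scheme$low_below, "Low",
                ifelse(value_pct > scheme$high_above, "High",
                       "Intermediate"))
  factor(out, levels = c("Low", "Intermediate", "High"))
}

ki67_levels <- c("Low", "Intermediate", "High")

#' Reclassification transition table between two increments
#'
#' Cross-tabulates each case's Ki-67 category at increment `k_from`
#' against its category at `k_to` under one cut-off scheme. Row sums give
#' the `k_from` category counts, column sums the `k_to` counts.
#'
#' @param scores Long case-score tibble covering both increments.
#' @param scheme A `ki67_cutoffs`.
#' @param k_from,k_to Increments compared (defaults 1 and 5).
#' @return A `ki67_transition` object wrapping the 3x3 count matrix.
#' @export
transition_table <- function(scores, scheme, k_from = 1, k_to = 5) {
  stopifnot(inherits(scheme, "ki67_cutoffs"))
  a <- scores[scores$increment == k_from, c("case_id", "cumulative_pct")]
  b <- scores[scores$increment == k_to, c("case_id", "cumulative_pct")]
  j <- merge(a, b, by = "case_id", suffixes = c("_from", "_to"))
  if (nrow(j) < length(unique(scores$case_id)))
    stop("some cases lack increment ", k_from, " or ", k_to)
  from <- classify_case(j$cumulative_pct_from, scheme)
  to <- classify_case(j$cumulative_pct_to, scheme)
  counts <- table(from = from, to = to)
  new_transition(unclass(as.matrix(counts)), scheme$method, k_from, k_to)
}

new_transition <- function(counts, method, k_from, k_to) {
  dimnames(counts) <- list(from = ki67_levels, to = ki67_levels)
  structure(list(counts = counts, method = method,
                 k_from = k_from, k_to = k_to,
                 from_totals = rowSums(counts),
                 to_totals = colSums(counts),
                 n = sum(counts)),
            class = "ki67_transition")
}

#' Reconstruct a transition table from category counts and flows
#'
#' Builds the 3x3 transition matrix implied by starting category counts
#' and the off-diagonal reclassification flows (cases staying in category
#' fill the diagonal), e.g. to check reported reclassification numbers for
#' arithmetic conservation.
#'
#' @param start_counts Named numeric vector of counts at the first
#'   increment (names Low, Intermediate, High).
#' @param flows Named numeric vector of off-diagonal flows, names like
#'   `"Low->Intermediate"`.
#' @param method,k_from,k_to Labels stored on the result.
#' @return A `ki67_transition`; its `to_totals` are the implied end counts.
#' @examples
#' tr <- transition_from_flows(
#'   c(Low = 48, Intermediate = 123, High = 77),
#'   c("Low->Intermediate" = 12, "Intermediate->Low" = 8,
#'     "Intermediate->High" = 8, "High->Intermediate" = 13))
#' tr$to_totals
#' @export
transition_from_flows <- function(start_counts, flows, method = "VA",
                                  k_from = 1, k_to = 5) {
  counts <- matrix(0, 3, 3, dimnames = list(ki67_levels, ki67_levels))
  for (nm in names(flows)) {
    p <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (length(p) != 2 || !all(p %in% ki67_levels))
      stop("malformed flow name `", nm, "`; expected e.g. `Low->High`")
    counts[p[1], p[2]] <- flows[[nm]]
  }
  stay <- start_counts[ki67_levels] - rowSums(counts)
  if (any(stay < 0))
    stop("flows out of a category exceed its starting count")
  diag(counts) <- stay
  new_transition(counts, method, k_from, k_to)
}

#' @export
print.ki67_transition <- function(x, ...) {
  cat("Ki-67 reclassification (", x$method, "), increment ", x$k_from,
      " -> ", x$k_to, ", n = ", x$n, "\n", sep = "")
  print(x$counts)
  cat("start:", paste(x$from_totals, collapse = "/"),
      " end:", paste(x$to_totals, collapse = "/"), "\n")
  invisible(x)
}

#' Tidy a transition table
#' @param x A `ki67_transition`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `n`.
#' @export
tidy.ki67_transition <- function(x, ...) {
  df <- as.data.frame.table(x$counts, responseName = "n")
  tibble::tibble(from = df$from, to = df$to, n = df$n)
}
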