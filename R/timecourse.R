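#' Baseline subtraction for a time series
#'
#' Subtracts the first (baseline) value from every value of a series
#' ordered by time, so trajectories that start at different levels become
#' comparable; the first element of the result is 0 by construction.
#'
#' @param series Nonempty numeric vector ordered by time.
#' @return Numeric vector `series - series[1]`.
#' @export
baseline_subtract <- function(series) {
  if (length(series) == 0L) stop("series is empty")
  series - series[1]
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with mid-ranks for ties. The reported statistic is
#' `U = min(U_a, U_b)`. For combined sample sizes `n_a + n_b <= 12` the
#' two-sided p-value is computed by exhaustive enumeration of all
#' `choose(n, n_a)` group assignments of the pooled values
#' (`p = P(min(U_a, U_b) <= observed)` under the permutation null), which is
#' exact also under ties; for larger samples the normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @param exact_max Combined size up to which enumeration is used
#'   (default 12).
#' @return List with `u` (min of the two U statistics), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_max = 12L) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be nonempty")
  na <- length(sample_a); nb <- length(sample_b)
  u_min <- .u_stat(sample_a, sample_b)
  if (na + nb <= exact_max) {
    pooled <- c(sample_a, sample_b)
    combs <- utils::combn(na + nb, na)
    stats <- apply(combs, 2L, function(ia)
      .u_stat(pooled[ia], pooled[-ia]))
    p <- mean(stats <= u_min + 1e-12)
    list(u = u_min, p = p, method = "exact")
  } else {
    n <- na + nb
    mu <- na * nb / 2
    ties <- table(c(sample_a, sample_b))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u_min, p = 1, method = "normal"))
    z <- (u_min - mu + 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * stats::pnorm(z))
    list(u = u_min, p = p, method = "normal")
  }
}

## U = min(U_a, U_b) from mid-rank sums
.u_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))  # mid-ranks for ties
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(ua, na * nb - ua)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons `m` and caps at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons; defaults to `length(p_values)`.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Build tidy time-point records from batch counts and a sample sheet
#'
#' Joins the per-frame batch counts (columns `path`, `cell_count`,
#' `red_count`) with a sample sheet mapping `path` to `group`, `dose`,
#' `field_of_view` and `time_index`, and computes `red_pct`.
#'
#' @param counts Data.frame from [count_directory()] or equivalent.
#' @param sheet Data.frame with columns `path`, `group`, `dose`,
#'   `field_of_view`, `time_index`.
#' @return Tidy data.frame of time-point records.
#' @export
make_timepoint_records <- function(counts, sheet) {
  need <- c("path", "group", "dose", "field_of_view", "time_index")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  df <- merge(counts, sheet, by = "path")
  df$red_pct <- ifelse(df$cell_count > 0, 100 * df$red_count / df$cell_count,
                       NA_real_)
  df[order(df$group, df$field_of_view, df$time_index), ]
}

#' Endpoint comparison of red-cell percentage changes between groups
#'
#' For every group and field of view, computes the change in red-cell
#' percentage between the first and the last time point, then compares all
#' group pairs with the two-sided Mann-Whitney test and applies Bonferroni
#' correction over the number of pairs (`choose(n_groups, 2)`).
#'
#' @param records Data.frame with columns `group`, `field_of_view`,
#'   `time_index`, `red_pct` (as from [make_timepoint_records()]).
#' @return Data.frame with columns `group_a`, `group_b`, `u_statistic`,
#'   `p_value`, `p_corrected`, one row per group pair (groups in sorted
#'   order).
#' @export
endpoint_comparison <- function(records) {
  need <- c("group", "field_of_view", "time_index", "red_pct")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  t0 <- min(records$time_index); t1 <- max(records$time_index)
  deltas <- lapply(split(records, records$group), function(g) {
    per_field <- split(g, g$field_of_view)
    vapply(per_field, function(f) {
      a <- f$red_pct[f$time_index == t0]
      b <- f$red_pct[f$time_index == t1]
      if (length(a) != 1L || length(b) != 1L)
        stop("group ", g$group[1], ", field ", f$field_of_view[1],
             ": missing first or last time point")
      b - a
    }, numeric(1))
  })
  groups <- sort(names(deltas))
  if (length(groups) < 2L) stop("need at least two groups to compare")
  pairs <- utils::combn(groups, 2L)
  res <- apply(pairs, 2L, function(pr) {
    mw <- mann_whitney_u(deltas[[pr[1]]], deltas[[pr[2]]])
    c(u = mw$u, p = mw$p)
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    u_statistic = res["u", ], p_value = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_corrected <- bonferroni(out$p_value, m = nrow(out))
  rownames(out) <- NULL
  out
}
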