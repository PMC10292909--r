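# Mutation/SV rate estimation for MA experiments. The estimator is the
# Poisson MLE mu = m / (sum_i N_i * T): m mutations over n lines, N analyzed
# sites per line (N = 1 for per-genome rates), and T cell divisions per line
# (transfers * log2(CFU per colony)). Confidence intervals are exact
# (Garwood) Poisson intervals from chi-square quantiles, which reproduce the
# printed MA-study intervals and are conservative (coverage >= nominal).

#' Cell divisions per transfer from colony-forming units
#'
#' A colony founded by one cell that grew to `cfu` cells went through
#' `log2(cfu)` doublings.
#'
#' @param cfu colony-forming units per colony (> 1).
#' @return divisions per transfer (real).
#' @examples
#' divisions_per_transfer(2^28) # 28
#' @export
divisions_per_transfer <- function(cfu) {
  if (any(cfu <= 1)) stop("cfu must be > 1")
  log2(cfu)
}

#' Total cell divisions per line
#'
#' @param transfers number of single-colony transfers.
#' @param per_transfer divisions per transfer.
#' @return `transfers * per_transfer`.
#' @examples
#' total_divisions(160, 28) # 4480 (typical WT line)
#' total_divisions(160, 27) # 4320 (typical mutS-deficient line)
#' @export
total_divisions <- function(transfers, per_transfer) {
  if (any(transfers <= 0) || any(per_transfer <= 0))
    stop("transfers and per_transfer must be positive")
  transfers * per_transfer
}

#' Exact (Garwood) Poisson confidence interval on a rate
#'
#' For an observed count `m` over exposure `denominator`, the bounds on the
#' count are `0.5 * qchisq(alpha/2, 2m)` (0 when `m = 0`) and
#' `0.5 * qchisq(1 - alpha/2, 2m + 2)`; both are divided by the denominator.
#'
#' @param m observed event count (>= 0).
#' @param denominator exposure (e.g. `n_lines * T` genome-divisions).
#' @param alpha two-sided miss probability (default 0.05).
#' @return named numeric vector `c(low, high)` on the rate scale.
#' @examples
#' poisson_ci_exact(66, 67 * 4480) # 1.70e-4 .. 2.80e-4
#' @export
poisson_ci_exact <- function(m, denominator, alpha = 0.05) {
  if (m < 0) stop("m must be >= 0")
  if (denominator <= 0) stop("denominator must be > 0")
  low <- if (m == 0) 0 else 0.5 * stats::qchisq(alpha / 2, 2 * m)
  high <- 0.5 * stats::qchisq(1 - alpha / 2, 2 * m + 2)
  c(low = low / denominator, high = high / denominator)
}

new_rate_estimate <- function(m, denominator, alpha) {
  ci <- poisson_ci_exact(m, denominator, alpha)
  structure(
    list(m = m, denominator = denominator, rate = m / denominator,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         alpha = alpha),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> m=%d over %.5g: rate %.3g (%d%% CI %.3g-%.3g)\n",
    x$m, x$denominator, signif(x$rate, 3), round(100 * (1 - x$alpha)),
    signif(x$ci_low, 3), signif(x$ci_high, 3)))
  invisible(x)
}

#' Per-genome per-division mutation rate
#'
#' `rate = m / (n_lines * T)`, the mu estimator with one "site" (the whole
#' genome) per line; exact Poisson CI. Reported values should be rounded to
#' 3 significant figures (the list keeps full precision).
#'
#' @param m mutation/SV count summed over lines.
#' @param n_lines number of MA lines.
#' @param T_divisions cell divisions per line.
#' @param alpha CI miss probability (default 0.05).
#' @return a `rate_estimate` list: `m`, `denominator`, `rate`, `ci_low`,
#'   `ci_high`, `alpha`.
#' @examples
#' rate_per_genome(83, 67, 4480)$rate # 2.77e-4 at 3 s.f.
#' @export
rate_per_genome <- function(m, n_lines, T_divisions, alpha = 0.05) {
  if (n_lines <= 0 || T_divisions <= 0)
    stop("n_lines and T_divisions must be positive")
  new_rate_estimate(m, n_lines * T_divisions, alpha)
}

#' Per-site per-division mutation rate
#'
#' `rate = m / (sum(N_i) * T)` over the analyzed sites `N_i` of each line.
#'
#' @param m mutation count summed over lines.
#' @param sites_per_line numeric vector of analyzed sites N_i, one per line.
#' @param T_divisions cell divisions per line.
#' @param alpha CI miss probability.
#' @return a `rate_estimate` list.
#' @export
rate_per_site <- function(m, sites_per_line, T_divisions, alpha = 0.05) {
  if (length(sites_per_line) == 0L) stop("sites_per_line must be non-empty")
  if (any(sites_per_line <= 0)) stop("sites_per_line must be positive")
  new_rate_estimate(m, sum(sites_per_line) * T_divisions, alpha)
}

#' Spectrum summary of validated SVs
#'
#' Counts and per-line means by SV type, the insertion/deletion count ratio,
#' total inserted and deleted base pairs with their length ratio, and a
#' length histogram. Ratios with a zero denominator are reported as `NA`
#' (undefined), never infinity.
#'
#' @param calls validated SV record table.
#' @param n_lines number of MA lines the calls came from.
#' @param length_breaks histogram breakpoints in bp (right-closed).
#' @return a list of class `spectrum_summary`.
#' @export
spectrum_summary <- function(calls, n_lines,
                             length_breaks = c(0, 100, 500, 1000, 1500,
                                               5000, Inf)) {
  calls <- validate_sv_records(calls)
  counts <- stats::setNames(integer(length(SV_TYPES)), SV_TYPES)
  tab <- table(factor(calls$svtype, levels = SV_TYPES))
  counts[names(tab)] <- as.integer(tab)
  n_ins <- counts[["INS"]]; n_del <- counts[["DEL"]]
  total_ins <- sum(calls$length[calls$svtype == "INS"])
  total_del <- sum(calls$length[calls$svtype == "DEL"])
  structure(list(
    counts = counts,
    mean_per_line = counts / n_lines,
    total_mean_per_line = sum(counts) / n_lines,
    ins_del_count_ratio = if (n_del > 0) n_ins / n_del else NA_real_,
    total_ins_bp = total_ins,
    total_del_bp = total_del,
    del_ins_length_ratio = if (total_ins > 0) total_del / total_ins
                           else NA_real_,
    length_hist = table(cut(calls$length, breaks = length_breaks)),
    n_lines = n_lines
  ), class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary> over", x$n_lines, "lines\n")
  print(data.frame(count = x$counts,
                   mean_per_line = round(x$mean_per_line, 2)))
  cat(sprintf("INS/DEL count ratio: %s\n",
              format(round(x$ins_del_count_ratio, 2))))
  cat(sprintf("total INS %d bp, total DEL %d bp (DEL/INS length ratio %s)\n",
              x$total_ins_bp, x$total_del_bp,
              format(round(x$del_ins_length_ratio, 2))))
  invisible(x)
}

#' Positional distribution of SVs along the chromosome
#'
#' Bins SV start positions into fixed-width windows from position 1 and
#' tests goodness of fit against a uniform distribution with a chi-square
#' statistic; bins with expected count below 1 are pooled into their left
#' neighbour.
#'
#' @param calls SV record table.
#' @param genome_len chromosome length in bp.
#' @param bin_size window width in bp.
#' @return list of class `positional_distribution` with `bins` (data.frame),
#'   `chisq`, `df`, `p_value`; all `NA` with an empty bin table when there
#'   are no calls.
#' @export
positional_distribution <- function(calls, genome_len, bin_size = 2e5) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  n <- nrow(calls)
  if (n == 0L) {
    return(structure(list(bins = data.frame(), chisq = NA_real_,
                          df = NA_real_, p_value = NA_real_),
                     class = "positional_distribution"))
  }
  breaks <- unique(c(seq(0, genome_len, by = bin_size), genome_len))
  obs <- as.vector(table(cut(calls$start, breaks = breaks,
                             include.lowest = TRUE)))
  widths <- diff(breaks)
  expected <- n * widths / genome_len
  # pool bins with expectation < 1 from the right into their left neighbour
  while (length(obs) > 1L && any(expected < 1)) {
    i <- which(expected < 1)[1]
    j <- if (i == 1L) 2L else i - 1L
    obs[j] <- obs[j] + obs[i]
    expected[j] <- expected[j] + expected[i]
    obs <- obs[-i]; expected <- expected[-i]
    widths[j] <- widths[j] + widths[i]; widths <- widths[-i]
  }
  chisq <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  structure(list(
    bins = data.frame(width = widths, observed = obs, expected = expected),
    chisq = chisq, df = df,
    p_value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
              else NA_real_
  ), class = "positional_distribution")
}
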