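#' Paired sample (continuous vs pulsed)
#'
#' Holds per-subject values under the two techniques in matching order, so
#' each subject acts as its own control.
#'
#' @param x values under the continuous technique.
#' @param y values under the pulsed technique (same length, same subjects).
#' @param subject_ids optional identifiers.
#' @return A `paired_sample`.
#' @export
paired_sample <- function(x, y, subject_ids = seq_along(x)) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(subject_ids) != length(x))
    stop("`subject_ids` must match the sample length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("sample values must be finite")
  structure(list(subject_ids = subject_ids, x = as.numeric(x),
                 y = as.numeric(y)),
            class = "paired_sample")
}

as_paired <- function(x, y) {
  if (inherits(x, "paired_sample")) x else paired_sample(x, y)
}

new_test_result <- function(statistic, p, method, n_effective) {
  structure(list(statistic = statistic, p_two_sided = p, method = method,
                 n_effective = as.integer(n_effective)),
            class = "embl_test_result")
}

#' @export
print.embl_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_two_sided, x$n_effective))
  invisible(x)
}

#' Paired t-test
#'
#' On differences d = x - y: t = mean(d) / (sd(d) / sqrt(n)), two-sided p
#' from the t distribution with n - 1 degrees of freedom. Errors when the
#' differences have zero variance (the statistic is undefined).
#'
#' @param x a [paired_sample()] or the continuous-arm values.
#' @param y pulsed-arm values when `x` is a plain vector.
#' @return An `embl_test_result` with fields `statistic`, `p_two_sided`,
#'   `method = "paired_t"`, `n_effective`.
#' @export
paired_t_test <- function(x, y = NULL) {
  s <- as_paired(x, y)
  d <- s$x - s$y
  n <- length(d)
  if (n < 2) stop("paired t-test needs n >= 2")
  sdd <- stats::sd(d)
  if (sdd == 0)
    stop("differences have zero variance; the t statistic is undefined")
  t <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  new_test_result(t, p, "paired_t", n)
}

#' Exact Wilcoxon signed-rank test
#'
#' Statistic W = sum of signed ranks of |d| (midranks for ties). With
#' `mode = "exact"` the two-sided p-value P(|W| >= |w|) comes from the exact
#' null distribution over all 2^n equally likely sign assignments of the
#' observed |d| ranks (valid with ties; n <= 20). `mode = "normal"` uses the
#' tie-aware normal approximation z = W / sqrt(sum(rank^2)). Zero
#' differences are dropped before ranking (`zero_policy = "wilcoxon"`,
#' the classical policy); n = 7 pairs makes the exact mode the default.
#'
#' @param x a [paired_sample()] or the continuous-arm values.
#' @param y pulsed-arm values when `x` is a plain vector.
#' @param zero_policy only `"wilcoxon"` (drop zero differences).
#' @param mode `"exact"`, `"normal"`, or `"auto"` (exact when n <= 20).
#' @return An `embl_test_result` with `method` `"wilcoxon_exact"` or
#'   `"wilcoxon_normal"`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, zero_policy = "wilcoxon",
                                 mode = c("auto", "exact", "normal")) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  s <- as_paired(x, y)
  d <- s$x - s$y
  d <- d[d != 0]                       # drop zeros (Wilcoxon's policy)
  n <- length(d)
  if (n < 2) stop("fewer than 2 non-zero differences; test undefined")
  if (mode == "auto") mode <- if (n <= 20) "exact" else "normal"
  r <- rank(abs(d))                    # midranks for ties
  w <- sum(sign(d) * r)
  if (mode == "exact") {
    if (n > 20) stop("exact mode supports n <= 20")
    p <- signed_rank_exact_p(r, w)
    new_test_result(w, p, "wilcoxon_exact", n)
  } else {
    z <- w / sqrt(sum(r^2))
    p <- 2 * stats::pnorm(-abs(z))
    new_test_result(w, min(1, p), "wilcoxon_normal", n)
  }
}

# Exact two-sided p for the signed-rank sum W given the rank vector.
# The null distribution over 2^n sign assignments is obtained by convolving
# the per-rank characteristic polynomials on the integer support of 2*W+
# (doubling makes midranks integral). Equivalent to full enumeration.
signed_rank_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))       # 2*midranks are integers
  total <- sum(r2)
  counts <- rep(0, total + 1)          # counts[k+1] = #assignments with 2*W+ = k
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  # 2*W = 2*(2*W+) - total, on the doubled scale; two-sided tail of |W|
  support_w <- 2 * (0:total) - total   # values of 2*W
  tail <- sum(counts[abs(support_w) >= abs(round(2 * w)) - 1e-9])
  tail / 2^length(r)
}

#' Median and range summary
#'
#' Standard median (mean of the central pair for even n) with the min and
#' max, the "median (range)" presentation used for continuous variables.
#'
#' @param values non-empty numeric vector.
#' @return List with `median`, `min`, `max`.
#' @export
median_and_range <- function(values) {
  if (length(values) == 0) stop("`values` must be non-empty")
  if (!all(is.finite(values))) stop("`values` must be finite")
  list(median = stats::median(values), min = min(values), max = max(values))
}
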