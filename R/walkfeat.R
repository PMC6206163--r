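# Statistical descriptors of the DNA walk and assembly of the canonical
# 8-feature set.

#' Names of the eight canonical walk features, in order
#'
#' @return Character vector: sd, dfa, ac, ac_200, ac_300, sampen, hurst,
#'   rvntsl.
#' @export
walk_feature_names <- function() {
  c("sd", "dfa", "ac", "ac_200", "ac_300", "sampen", "hurst", "rvntsl")
}

#' Sample autocorrelation at a fixed lag
#'
#' rho(lag) = sum_{t=1}^{N-lag} (x_t - xbar)(x_{t+lag} - xbar) /
#' sum_{t=1}^{N} (x_t - xbar)^2.
#'
#' @param x Numeric series with positive variance, length > `lag`.
#' @param lag Non-negative integer lag.
#' @return Autocorrelation in \[-1, 1\] (1 at lag 0).
#' @export
autocorrelation <- function(x, lag) {
  N <- length(x)
  if (lag < 0) stop("lag must be non-negative")
  if (N <= lag) stop(sprintf("series length %d <= lag %d", N, lag))
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("zero-variance series: autocorrelation undefined")
  if (lag == 0) return(1)
  sum(xc[seq_len(N - lag)] * xc[(lag + 1):N]) / denom
}

#' Ratio of distinct values to series length (rvntsl)
#'
#' For an integer-valued walk this is the number of distinct levels the
#' walk visits divided by its length; compact, range-bound walks score low.
#'
#' @param x Non-empty series.
#' @return Value in (0, 1\].
#' @export
rvntsl <- function(x) {
  if (length(x) == 0L) stop("empty series")
  length(unique(x)) / length(x)
}

#' Extended statistical descriptors of a series
#'
#' Standard summaries beyond the canonical feature set: max, min, skewness
#' and excess kurtosis (moment form), interquartile range, zero and mean
#' crossing rates (fraction of adjacent pairs with a strict sign change
#' about 0 and about the mean), and spectral entropy (Shannon entropy of
#' the normalized periodogram over the positive frequencies, divided by
#' log of the number of bins, hence in \[0, 1\]).
#'
#' @param x Numeric series of length >= 4.
#' @return Named list with max, min, skewness, kurtosis,
#'   interquartile_range, zero_crossing_rate, mean_crossing_rate,
#'   spectral_entropy. Zero-variance input yields `NA` for skewness,
#'   kurtosis and spectral entropy.
#' @export
extended_stats <- function(x) {
  L <- length(x)
  if (L < 4L) stop("need at least 4 points")
  constant <- var(x) == 0
  cross_rate <- function(y) sum(y[-L] * y[-1] < 0) / (L - 1)
  spec_ent <- if (constant) NA_real_ else {
    p <- Mod(fft(x - mean(x)))^2
    p <- p[2:(floor(L / 2) + 1L)]
    nb <- length(p)
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log(p)) / log(nb)
  }
  list(
    max = max(x),
    min = min(x),
    skewness = if (constant) NA_real_ else e1071::skewness(x, type = 1),
    kurtosis = if (constant) NA_real_ else e1071::kurtosis(x, type = 1),
    interquartile_range = IQR(x),
    zero_crossing_rate = cross_rate(x),
    mean_crossing_rate = cross_rate(x - mean(x)),
    spectral_entropy = spec_ent
  )
}

#' The eight canonical walk features of a DNA walk
#'
#' Assembles, in fixed order: the sample standard deviation of the walk;
#' the DFA scaling exponent of the walk; autocorrelations of the walk at
#' lags 100, 200 and 300; the sample entropy of the walk; the
#' rescaled-range Hurst exponent of the step series; and rvntsl of the
#' walk. Deterministic: the same walk always yields identical output.
#'
#' @param walk A [build_walk()] result (length >= 302).
#' @param sampen_m,sampen_r Sample entropy parameters (defaults m = 2,
#'   r = 0.2 x SD of the walk).
#' @param dfa_order DFA detrending order (default 1).
#' @return Named numeric vector of length 8 ([walk_feature_names()]
#'   order). An undefined sample entropy is reported as `NA` (the record
#'   is then a no-call for prediction / droppable for training).
#' @export
walk_features <- function(walk, sampen_m = 2L, sampen_r = NULL,
                          dfa_order = 1L) {
  stopifnot(inherits(walk, "dna_walk"))
  if (walk$length < 302L) {
    stop(sprintf("walk '%s' too short (%d) for lag-300 autocorrelation",
                 walk$id, walk$length))
  }
  w <- walk$walk
  out <- c(
    sd = sd(w),
    dfa = dfa_exponent(w, poly_order = dfa_order)$alpha,
    ac = autocorrelation(w, 100L),
    ac_200 = autocorrelation(w, 200L),
    ac_300 = autocorrelation(w, 300L),
    sampen = sample_entropy(w, m = sampen_m, r = sampen_r),
    hurst = hurst_rs(walk$steps)$K,
    rvntsl = rvntsl(w)
  )
  stopifnot(identical(names(out), walk_feature_names()))
  out
}
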