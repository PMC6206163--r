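# Nonlinear descriptors of the DNA walk: rescaled-range Hurst exponent,
# detrended fluctuation analysis, sample entropy, and the largest Lyapunov
# exponent.

# Expected rescaled range of an i.i.d. series of length n (Anis-Lloyd with
# the (n - 1/2)/n finite-sample factor). Used to debias the R/S slope.
expected_rs <- function(n) {
  i <- seq_len(n - 1L)
  s <- sum(sqrt((n - i) / i))
  front <- if (n <= 340) {
    exp(lgamma((n - 1) / 2) - 0.5 * log(pi) - lgamma(n / 2))
  } else {
    1 / sqrt(n * pi / 2)
  }
  ((n - 0.5) / n) * front * s
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' Estimates the Hurst exponent K of a step (increment) series. For each
#' chunk size n (powers of 2 from 8 up to L/2) the series is split into
#' floor(L/n) chunks; per chunk the range R of the mean-adjusted cumulative
#' sum is divided by the chunk standard deviation, and the R/sigma values
#' are averaged. K is the least-squares slope of log(mean R/sigma) against
#' log(n), debiased by the Anis-Lloyd expected-R/S curve for uncorrelated
#' series so that a purely Brownian walk yields K near 0.5 at these series
#' lengths. Chunks with zero standard deviation are skipped.
#'
#' @param steps Numeric series of increments (for a DNA walk, the +/-1
#'   step series, not the cumulative walk).
#' @return Object of class `hurst_fit`: list with `K`, `chunk_sizes`,
#'   `rescaled_ranges` (mean R/sigma per size), `fit_intercept`, and
#'   `expected_rs` (the debiasing curve).
#' @export
hurst_rs <- function(steps) {
  L <- length(steps)
  if (L < 64L) stop("series too short for R/S analysis (need >= 64)")
  ns <- 2L^(3:floor(log2(L / 2)))
  if (length(ns) < 4L) {
    stop("fewer than 4 chunk sizes feasible (need length >= 128)")
  }
  rs <- vapply(ns, function(n) {
    k <- floor(L / n)
    vals <- vapply(seq_len(k), function(j) {
      ch <- steps[((j - 1L) * n + 1L):(j * n)]
      s <- sd(ch)
      if (s == 0) return(NA_real_)
      y <- cumsum(ch - mean(ch))
      (max(y) - min(y)) / s
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 4L) {
    stop("degenerate series: R/S undefined at nearly all chunk sizes")
  }
  e <- vapply(ns[ok], expected_rs, numeric(1))
  fit_emp <- stats::lm.fit(cbind(1, log(ns[ok])), log(rs[ok]))
  fit_exp <- stats::lm.fit(cbind(1, log(ns[ok])), log(e))
  K <- 0.5 + unname(fit_emp$coefficients[2] - fit_exp$coefficients[2])
  structure(list(K = K, chunk_sizes = ns[ok], rescaled_ranges = rs[ok],
                 fit_intercept = unname(fit_emp$coefficients[1]),
                 expected_rs = e),
            class = "hurst_fit")
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf("<hurst_fit> K = %.4f over %d chunk sizes (%d..%d)\n",
              x$K, length(x$chunk_sizes), min(x$chunk_sizes),
              max(x$chunk_sizes)))
  invisible(x)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' The input series is mean-centered and integrated into a profile; for
#' each window size n on a geometric grid the profile is partitioned into
#' floor(L/n) windows, each detrended by a least-squares polynomial of
#' order `poly_order`, and the RMS fluctuation is recorded. The exponent
#' alpha is the least-squares slope of log-fluctuation against log-n.
#' White noise gives alpha near 0.5; a random walk passed in directly
#' (already once-integrated, as the feature pipeline does with the DNA
#' walk) gives alpha near 1.5.
#'
#' @param x Numeric series (length >= 100).
#' @param poly_order Detrending polynomial order (default 1).
#' @param n_windows Number of geometrically spaced window sizes (default
#'   12) spanning `window_range`.
#' @param window_range Smallest and largest window size; defaults to
#'   c(4, L/4).
#' @return Object of class `dfa_fit`: list with `alpha`, `window_sizes`,
#'   `fluctuations`, `poly_order`, `fit_intercept`.
#' @export
dfa_exponent <- function(x, poly_order = 1L, n_windows = 12L,
                         window_range = NULL) {
  L <- length(x)
  if (L < 100L) stop("series too short for DFA (need >= 100)")
  if (is.null(window_range)) window_range <- c(4L, floor(L / 4))
  ns <- unique(round(exp(seq(log(window_range[1]), log(window_range[2]),
                             length.out = n_windows))))
  ns <- ns[ns >= poly_order + 2L]
  prof <- cumsum(x - mean(x))
  fl <- vapply(ns, function(n) {
    k <- floor(L / n)
    W <- matrix(prof[seq_len(k * n)], nrow = n)
    t <- seq_len(n)
    X <- stats::poly(t, poly_order, raw = TRUE)
    qrX <- qr(cbind(1, X))
    res <- qr.resid(qrX, W)
    sqrt(mean(res^2))
  }, numeric(1))
  usable <- fl > 0
  if (any(!usable)) {
    warning(sprintf("dropping %d window size(s) with zero fluctuation",
                    sum(!usable)))
  }
  if (sum(usable) < 4L) stop("fewer than 4 usable window sizes for DFA")
  fit <- stats::lm.fit(cbind(1, log(ns[usable])), log(fl[usable]))
  structure(list(alpha = unname(fit$coefficients[2]),
                 window_sizes = ns[usable], fluctuations = fl[usable],
                 poly_order = poly_order,
                 fit_intercept = unname(fit$coefficients[1])),
            class = "dfa_fit")
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("<dfa_fit> alpha = %.4f (order-%d detrending, %d scales)\n",
              x$alpha, x$poly_order, length(x$window_sizes)))
  invisible(x)
}

#' Sample entropy of a series
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of distinct length-m
#' templates within Chebyshev distance r and A the same for length m+1;
#' self-matches are excluded. Lower values indicate more self-similarity.
#'
#' @param x Numeric series.
#' @param m Template length (default 2).
#' @param r Tolerance; defaults to 0.2 times the series standard deviation.
#' @return Non-negative numeric, or `NA` (undefined-entropy sentinel) when
#'   no template pair matches at either length.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL) {
  if (length(x) < m + 2L) stop("series too short for sample entropy")
  if (is.null(r)) {
    s <- sd(x)
    if (s == 0) stop("constant series: SD-relative tolerance undefined")
    r <- 0.2 * s
  }
  if (r <= 0) stop("tolerance r must be positive")
  counts <- sampen_counts(as.numeric(x), as.integer(m), r)
  if (counts[1] == 0 || counts[2] == 0) return(NA_real_)
  -log(counts[1] / counts[2])
}

# First local minimum of the autocorrelation function, capped so that the
# delay embedding retains at least `keep` points.
auto_lag <- function(x, emb_dim, keep = 40L, lag_max = 200L) {
  N <- length(x)
  cap <- max(1L, floor((N - keep) / max(1L, emb_dim - 1L)))
  lag_max <- min(lag_max, N - 2L, cap)
  if (lag_max < 1L) return(1L)
  ac <- vapply(seq_len(lag_max), function(l) autocorrelation(x, l),
               numeric(1))
  up <- which(diff(ac) > 0)
  lag <- if (length(up)) up[1] else which(ac < 1 - exp(-1))[1]
  if (is.na(lag)) lag <- lag_max
  min(max(1L, lag), cap)
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Delay-embeds the series, finds each point's nearest Euclidean neighbour
#' with temporal separation greater than `min_tsep`, and fits the slope of
#' the mean log-divergence curve over the initial `fit_range` steps. A
#' positive slope indicates exponential divergence (chaos); periodic
#' signals give slopes near zero.
#'
#' @param x Numeric series.
#' @param lag Embedding delay; default: first minimum of the series
#'   autocorrelation, capped so the embedding keeps enough points.
#' @param emb_dim Embedding dimension (default 10).
#' @param min_tsep Theiler exclusion window (default = `lag`).
#' @param fit_range Steps of the divergence curve used in the fit
#'   (default 1..min(20, curve length)).
#' @return Object of class `lyap_fit`: list with `lambda_max`, `lag`,
#'   `emb_dim`, `min_tsep`, `divergence_curve`, `fit_range`.
#' @export
lyapunov_max <- function(x, lag = NULL, emb_dim = 10L, min_tsep = NULL,
                         fit_range = NULL) {
  N <- length(x)
  if (is.null(lag)) lag <- auto_lag(x, emb_dim)
  if (is.null(min_tsep)) min_tsep <- lag
  M <- N - (emb_dim - 1L) * lag
  if (M < 20L) {
    stop(sprintf("series too short to embed (lag %d, dim %d leaves %d points)",
                 lag, emb_dim, M))
  }
  idx <- outer(seq_len(M), seq(0L, (emb_dim - 1L) * lag, by = lag), "+")
  emb <- matrix(x[idx], nrow = M)
  kmax <- max(1L, min(if (is.null(fit_range)) 20L else max(fit_range), M - 1L))
  curve <- lyap_divergence(emb, as.integer(min_tsep), as.integer(kmax))
  if (all(!is.finite(curve))) stop("no valid neighbour pairs for divergence")
  if (is.null(fit_range)) fit_range <- seq_len(kmax)
  k <- fit_range
  ok <- is.finite(curve[k])
  if (sum(ok) < 2L) stop("divergence curve too short to fit")
  fit <- stats::lm.fit(cbind(1, k[ok]), curve[k][ok])
  structure(list(lambda_max = unname(fit$coefficients[2]),
                 lag = lag, emb_dim = emb_dim, min_tsep = min_tsep,
                 divergence_curve = curve, fit_range = range(k)),
            class = "lyap_fit")
}

#' @export
print.lyap_fit <- function(x, ...) {
  cat(sprintf("<lyap_fit> lambda_max = %.4f (lag %d, dim %d, fit %d..%d)\n",
              x$lambda_max, x$lag, x$emb_dim, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}
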