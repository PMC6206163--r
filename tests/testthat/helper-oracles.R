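# Independent brute-force oracles and small simulators used across the
# suite. These deliberately avoid the package's own computation paths.

# Direct two-loop evaluation of the sample autocorrelation formula.
naive_autocorrelation <- function(x, lag) {
  N <- length(x)
  xb <- mean(x)
  num <- 0
  for (t in seq_len(N - lag)) num <- num + (x[t] - xb) * (x[t + lag] - xb)
  den <- 0
  for (t in seq_len(N)) den <- den + (x[t] - xb)^2
  num / den
}

# Exhaustive pairwise template count for sample entropy.
brute_sampen <- function(x, m, r) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Position-by-position substring scan for k-mer counts.
naive_kmer_counts <- function(seq, k_min = 1, k_max = 6) {
  out <- integer(0)
  for (k in k_min:k_max) {
    words <- kmer_order(k, k)
    subs <- substring(seq, seq_len(nchar(seq) - k + 1),
                      seq_len(nchar(seq) - k + 1) + k - 1)
    tab <- table(factor(subs, levels = words))
    out <- c(out, as.integer(tab))
  }
  names(out) <- kmer_order(k_min, k_max)
  out
}

# Fractional Gaussian noise by Davies-Harte circulant embedding.
fgn_sim <- function(n, H) {
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  m <- 2 * n
  r <- c(g(0:(n - 1)), g(n), g((n - 1):1))
  lam <- Re(stats::fft(r))
  lam[lam < 0] <- 0
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  Re(stats::fft(sqrt(lam / (2 * m)) * z))[1:n]
}

# AUC as the normalized count of concordant positive/negative score
# pairs, ties counted one half (Mann-Whitney).
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

logistic_series <- function(n, x0 = 0.3) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force Rosenstein divergence curve on an explicit embedding,
# using a full distance matrix (distinct path from the compiled search).
brute_lyap_curve <- function(x, lag, emb_dim, min_tsep, kmax) {
  M <- length(x) - (emb_dim - 1) * lag
  idx <- outer(seq_len(M), seq(0, (emb_dim - 1) * lag, by = lag), "+")
  E <- matrix(x[idx], nrow = M)
  D <- as.matrix(stats::dist(E))
  for (i in seq_len(M)) {
    D[i, max(1, i - min_tsep):min(M, i + min_tsep)] <- Inf
  }
  nb <- apply(D, 1, which.min)
  vapply(seq_len(kmax), function(k) {
    ok <- which(seq_len(M) + k <= M & nb + k <= M)
    if (!length(ok)) return(NA_real_)
    d <- sqrt(rowSums((E[ok + k, , drop = FALSE] -
                         E[nb[ok] + k, , drop = FALSE])^2))
    d <- d[d > 0]
    if (!length(d)) return(NA_real_)
    mean(log(d))
  }, numeric(1))
}

# A small deterministic toy genome written to a temp FASTA.
make_toy_genome <- function(chrom_lengths = c(chr1 = 20000, chr2 = 15000),
                            gc = 0.5, seed = 99) {
  set.seed(seed)
  path <- tempfile(fileext = ".fa")
  recs <- lapply(names(chrom_lengths), function(ch) {
    seq_record(ch, rand_dna(chrom_lengths[[ch]], gc))
  })
  write_fasta(recs, path)
  path
}
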