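# Brute-force oracles, deliberately written as naive double loops so they are
# independent of the package's vectorized/collapsed implementations, plus
# small fixture builders.

oracle_hamming <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      d[i, j] <- sum(a != b)
    }
  }
  d
}

oracle_mpd <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  np <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      tot <- tot + sum(a != b)
      np <- np + 1
    }
  }
  tot / np
}

oracle_hunn <- function(x) {
  out <- x
  for (i in 2:(length(x) - 1)) {
    out[i] <- 0.24 * x[i - 1] + 0.52 * x[i] + 0.24 * x[i + 1]
  }
  out
}

# correlation of x(t-k) vs y(t) over the overlap, from first principles
oracle_ccf <- function(x, y, k) {
  n <- length(x)
  xs <- c(); ys <- c()
  for (t in seq_len(n)) {
    if (t - k >= 1 && t - k <= n) {
      xs <- c(xs, x[t - k]); ys <- c(ys, y[t])
    }
  }
  mx <- mean(xs); my <- mean(ys)
  sum((xs - mx) * (ys - my)) /
    sqrt(sum((xs - mx)^2) * sum((ys - my)^2))
}

# unsigned Stirling numbers of the first kind, exact in doubles for n <= 18
oracle_stirling_table <- function(n) {
  s <- matrix(0, n, n)
  s[1, 1] <- 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (k in seq_len(i + 1)) {
        s[i + 1, k] <- i * s[i, k] + if (k > 1) s[i, k - 1] else 0
      }
    }
  }
  s
}

oracle_ewens <- function(theta, n) {
  s <- oracle_stirling_table(n)[n, ]
  w <- s * theta^seq_len(n)
  w / sum(w)
}

# Chinese-restaurant-process sample of the number of alleles K
oracle_crp_k <- function(theta, n, reps) {
  k <- integer(reps)
  for (r in seq_len(reps)) {
    k[r] <- sum(stats::runif(n) < theta / (theta + 0:(n - 1)))
  }
  k
}

tiny_aln <- function(seqs, ids = NULL) {
  tibble::tibble(
    id = ids %||% paste0("s", seq_along(seqs)),
    sequence = seqs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

uniform_popmap <- function(aln, population = "pop1") {
  tibble::tibble(sample_id = aln$id, population = population)
}

random_aln <- function(n, len) {
  tiny_aln(replicate(n, paste0(sample(c("A", "C", "G", "T"), len, TRUE),
                               collapse = "")))
}
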