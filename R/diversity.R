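# Diversity and neutrality statistics for one sample of aligned sequences.
# All sequence-based statistics share the site-deletion policy so S, k, Pi and
# the haplotype counts refer to the same effective sites.

#' Number of segregating (polymorphic) sites
#'
#' Counts retained alignment columns with at least two distinct bases after
#' applying the deletion policy.
#'
#' @param aln Alignment tibble; at least two sequences.
#' @param policy Site-deletion policy, see [apply_deletion_policy()].
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln, policy = "complete") {
  aln <- validate_alignment(aln)
  if (nrow(aln) < 2) {
    abort("segregating sites need at least 2 sequences", class = "mothwaves_input_error")
  }
  aln <- apply_deletion_policy(aln, policy)
  mat <- alignment_matrix(aln)
  sum(apply(mat, 2, function(col) length(unique(col)) > 1))
}

#' Mean number of pairwise nucleotide differences (k)
#'
#' Average Hamming distance over all n(n-1)/2 unordered sequence pairs on the
#' retained sites. Internally collapses to unique sequences, so it is fast for
#' large low-diversity samples while remaining exactly the brute-force value.
#'
#' @inheritParams segregating_sites
#' @return Mean pairwise differences per sequence (not per site).
#' @export
mean_pairwise_differences <- function(aln, policy = "complete") {
  aln <- validate_alignment(aln)
  n <- nrow(aln)
  if (n < 2) {
    abort("mean pairwise differences need at least 2 sequences",
          class = "mothwaves_input_error")
  }
  aln <- apply_deletion_policy(aln, policy)
  tab <- table(factor(aln$sequence, levels = unique(aln$sequence)))
  uniq <- names(tab)
  cnt <- as.numeric(tab)
  d <- hamming_matrix(uniq)
  # sum over unordered pairs: between-haplotype pairs only (within = 0 diff)
  tot <- 0
  for (i in seq_along(uniq)) {
    for (j in seq_len(i - 1L)) {
      tot <- tot + cnt[i] * cnt[j] * d[i, j]
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Haplotype (gene) diversity
#'
#' Unbiased estimator `Hd = (n/(n-1)) * (1 - sum(p_i^2))` from a vector of
#' haplotype counts: the probability that two randomly drawn individuals carry
#' different haplotypes, bias-corrected for sample size.
#'
#' @param counts Vector of positive haplotype counts (or a `hap_table`).
#' @return Haplotype diversity in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(98, 74, 33, 2, 2, rep(1, 11)))
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "hap_table")) counts <- hap_counts(counts)
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(counts <= 0)) {
    abort("haplotype counts must be positive", class = "mothwaves_input_error")
  }
  n <- sum(counts)
  if (n < 2) {
    abort("haplotype diversity needs a sample of at least 2", class = "mothwaves_input_error")
  }
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Share of the sample carried by the m most frequent haplotypes
#'
#' @param ht A `hap_table` or a vector of haplotype counts.
#' @param m Number of top haplotypes to pool.
#' @return Percentage of the total sample (0-100).
#' @export
major_haplotype_fraction <- function(ht, m) {
  counts <- if (inherits(ht, "hap_table")) hap_counts(ht) else as.numeric(ht)
  if (m > length(counts)) {
    abort("m exceeds the number of haplotypes", class = "mothwaves_input_error")
  }
  100 * sum(sort(counts, decreasing = TRUE)[seq_len(m)]) / sum(counts)
}

#' Tajima's neutrality-test constants
#'
#' The standard constants `a1, a2, b1, b2, c1, c2, e1, e2` derived from the
#' sample size, used to normalize the difference between the diversity-based
#' and segregating-sites-based estimates of the population mutation rate.
#'
#' @param n Sample size (number of sequences), at least 4.
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 4) abort("Tajima's D needs n >= 4", class = "mothwaves_input_error")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))`: negative values indicate an
#' excess of rare variants, the signature of recent population expansion.
#' No p-value is computed (see the methods vignette); `S = 0` leaves the
#' statistic undefined and returns `NA` with a warning.
#'
#' @param S Number of segregating sites.
#' @param k Mean pairwise differences per sequence.
#' @param n Sample size, at least 4.
#' @return Tajima's D (or `NA_real_` when undefined).
#' @export
tajimas_d <- function(S, k, n) {
  cst <- tajima_constants(n)
  if (S == 0) {
    warn("Tajima's D is undefined when S = 0", class = "mothwaves_undefined_stat")
    return(NA_real_)
  }
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Per-population and pooled diversity summary
#'
#' Runs the full battery (n, effective sites, S, h, Hd, k, Pi, Tajima's D,
#' Fu's Fs) for the pooled sample and, when a population map is supplied, for
#' each population with at least `min_n` sequences.
#'
#' @param aln Alignment tibble.
#' @param popmap Optional population map (`sample_id`, `population`).
#' @param policy Site-deletion policy.
#' @param min_n Minimum per-population sample size to attempt statistics.
#' @return A tibble, one row per population plus a `"pooled"` row.
#' @export
diversity_stats <- function(aln, popmap = NULL, policy = "complete", min_n = 4) {
  aln <- validate_alignment(aln)
  groups <- list(pooled = aln)
  if (!is.null(popmap)) {
    popmap <- validate_popmap(popmap)
    idx <- split(popmap$sample_id, popmap$population)
    for (p in names(idx)) {
      groups[[p]] <- aln[aln$id %in% idx[[p]], , drop = FALSE]
    }
  }
  purrr::imap(groups, function(sub, label) {
    n <- nrow(sub)
    if (n < max(2, min_n)) {
      return(tibble(population = label, n = n, effective_length = NA_integer_,
                    S = NA_integer_, h = NA_integer_, Hd = NA_real_,
                    k = NA_real_, Pi = NA_real_, D = NA_real_, Fs = NA_real_))
    }
    red <- apply_deletion_policy(sub, policy)
    eff <- attr(red, "effective_length")
    S <- segregating_sites(sub, policy)
    k <- mean_pairwise_differences(sub, policy)
    cnts <- as.numeric(table(red$sequence))
    h <- length(cnts)
    Hd <- haplotype_diversity(cnts)
    D <- if (S > 0) tajimas_d(S, k, n) else NA_real_
    Fs <- if (k > 0) suppressWarnings(fus_fs(k, n, h)) else NA_real_
    tibble(population = label, n = n, effective_length = eff,
           S = as.integer(S), h = as.integer(h), Hd = Hd,
           k = k, Pi = k / eff, D = D, Fs = Fs)
  }) |>
    purrr::list_rbind()
}
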