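# Hudson-type pairwise Fst: 1 - Hw/Hb, where Hw is the unweighted mean of the
# two within-population mean pairwise differences and Hb the mean
# between-population pairwise difference, all on the sites retained by the
# deletion policy applied to the combined alignment. Within-population means
# are plug-in (with-replacement over haplotype frequencies, i.e. divided by
# n^2 rather than n(n-1)): this makes Fst exactly 0 for two samples of
# identical haplotype composition, at the price of a small positive
# finite-sample offset (~(1/nA + 1/nB)/2) under panmixia. Negative estimates
# are reported as computed.

#' Pairwise Fst between two populations of aligned sequences
#'
#' @param alnA,alnB Alignment tibbles for the two populations (each with at
#'   least 2 sequences). Sequences must share one alignment length.
#' @param policy Site-deletion policy applied to the combined alignment so
#'   both populations are compared on common sites.
#' @return Hudson-type Fst (`1 - Hw/Hb`), possibly negative; exactly 0 for
#'   two samples of identical haplotype composition (plug-in within-means,
#'   see the methods vignette), and when both populations are monomorphic
#'   and identical (`Hw = Hb = 0`).
#' @export
pairwise_fst <- function(alnA, alnB, policy = "complete") {
  alnA <- validate_alignment(alnA)
  alnB <- validate_alignment(alnB)
  if (nrow(alnA) < 2 || nrow(alnB) < 2) {
    abort("each population needs at least 2 sequences", class = "mothwaves_input_error")
  }
  comb <- tibble(
    id = c(paste0("A_", alnA$id), paste0("B_", alnB$id)),
    sequence = c(alnA$sequence, alnB$sequence)
  )
  comb <- apply_deletion_policy(comb, policy)
  nA <- nrow(alnA)
  seqA <- comb$sequence[seq_len(nA)]
  seqB <- comb$sequence[-seq_len(nA)]
  hw <- (mean_pairs_within(seqA) + mean_pairs_within(seqB)) / 2
  hb <- mean_pairs_between(seqA, seqB)
  if (hb == 0) {
    return(0) # identical monomorphic populations
  }
  1 - hw / hb
}

mean_pairs_within <- function(seqs) {
  n <- length(seqs)
  tab <- table(factor(seqs, levels = unique(seqs)))
  uniq <- names(tab)
  cnt <- as.numeric(tab)
  d <- hamming_matrix(uniq)
  tot <- 0
  for (i in seq_along(uniq)) {
    for (j in seq_len(i - 1L)) tot <- tot + cnt[i] * cnt[j] * d[i, j]
  }
  2 * tot / n^2 # plug-in mean over ordered pairs (with replacement)
}

mean_pairs_between <- function(seqsA, seqsB) {
  tabA <- table(factor(seqsA, levels = unique(seqsA)))
  tabB <- table(factor(seqsB, levels = unique(seqsB)))
  uA <- names(tabA); uB <- names(tabB)
  d <- hamming_matrix(c(uA, uB))
  tot <- 0
  for (i in seq_along(uA)) {
    for (j in seq_along(uB)) {
      tot <- tot + as.numeric(tabA[i]) * as.numeric(tabB[j]) * d[i, length(uA) + j]
    }
  }
  tot / (length(seqsA) * length(seqsB))
}

#' Pairwise Fst matrix over all populations
#'
#' @param aln Alignment tibble covering all samples.
#' @param popmap Population map (`sample_id`, `population`).
#' @param policy Site-deletion policy (applied per population pair on the
#'   combined pair alignment).
#' @param min_n Populations with fewer sequences are dropped with a warning.
#' @return An object of class `fst_matrix`: populations (in first-appearance
#'   order), the symmetric value matrix (diagonal `NA`), and the method tag.
#' @export
fst_matrix <- function(aln, popmap, policy = "complete", min_n = 2) {
  aln <- validate_alignment(aln)
  popmap <- validate_popmap(popmap)
  dat <- dplyr::left_join(aln, popmap[, c("sample_id", "population")],
                          by = c(id = "sample_id"))
  if (any(is.na(dat$population))) {
    abort("some alignment ids are missing from the population map",
          class = "mothwaves_mapping_error")
  }
  pops <- unique(dat$population)
  sizes <- table(dat$population)[pops]
  drop <- pops[sizes < min_n]
  if (length(drop) > 0) {
    warn(paste0("dropping populations with < ", min_n, " sequences: ",
                paste(drop, collapse = ", ")))
    pops <- setdiff(pops, drop)
  }
  m <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1L)) {
      sub_i <- dat[dat$population == pops[i], c("id", "sequence")]
      sub_j <- dat[dat$population == pops[j], c("id", "sequence")]
      m[i, j] <- m[j, i] <- pairwise_fst(sub_i, sub_j, policy)
    }
  }
  structure(
    list(populations = pops, values = m, method = "hudson_plugin_1-Hw/Hb",
         sizes = as.integer(sizes[pops])),
    class = "fst_matrix"
  )
}

#' Permutation test for pairwise Fst
#'
#' Permutes population labels across the two samples to build the null
#' distribution of Fst under panmixia.
#'
#' @inheritParams pairwise_fst
#' @param n_perm Number of label permutations.
#' @return Tibble with the observed Fst, the permutation p-value
#'   (`P(null >= observed)`), and the 97.5th percentile of the null.
#' @export
fst_permutation_test <- function(alnA, alnB, n_perm = 999, policy = "complete") {
  obs <- pairwise_fst(alnA, alnB, policy)
  pool <- c(alnA$sequence, alnB$sequence)
  nA <- nrow(alnA)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), nA)
    a <- tibble(id = paste0("a", seq_len(nA)), sequence = pool[idx])
    b <- tibble(id = paste0("b", seq_len(length(pool) - nA)), sequence = pool[-idx])
    pairwise_fst(a, b, policy)
  }, numeric(1))
  tibble(
    fst = obs,
    p_value = (1 + sum(null >= obs)) / (n_perm + 1),
    null_q975 = unname(stats::quantile(null, 0.975)),
    n_perm = n_perm
  )
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> method:", x$method, "\n")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
tidy.fst_matrix <- function(x, ...) {
  idx <- which(lower.tri(x$values), arr.ind = TRUE)
  tibble(
    population_a = x$populations[idx[, "col"]],
    population_b = x$populations[idx[, "row"]],
    fst = x$values[idx]
  )
}

#' @export
glance.fst_matrix <- function(x, ...) {
  v <- x$values[lower.tri(x$values)]
  tibble(n_populations = length(x$populations),
         mean_fst = mean(v), max_fst = max(v), min_fst = min(v),
         method = x$method)
}

#' @export
autoplot.fst_matrix <- function(object, ...) {
  d <- tidy(object)
  d$population_a <- factor(d$population_a, levels = object$populations)
  d$population_b <- factor(d$population_b, levels = object$populations)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$population_a, y = .data$population_b,
                                  fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$fst)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Fst") +
    ggplot2::theme_minimal()
}

#' Write an Fst matrix as a lower-triangle TSV
#'
#' Mirrors the conventional lower-triangle presentation of pairwise Fst
#' tables (populations with sample sizes on the rows, `x` on the diagonal).
#'
#' @param x An `fst_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fst_tsv <- function(x, path) {
  stopifnot(inherits(x, "fst_matrix"))
  p <- length(x$populations)
  out <- matrix("", p, p)
  for (i in seq_len(p)) {
    out[i, i] <- "x"
    for (j in seq_len(i - 1L)) out[i, j] <- sprintf("%.4f", x$values[i, j])
  }
  df <- data.frame(
    population = sprintf("%s (%d)", x$populations, x$sizes),
    out, check.names = FALSE
  )
  names(df) <- c("population", x$populations)
  readr::write_tsv(df, path)
  invisible(path)
}
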