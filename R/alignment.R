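# Alignment and population-map input. Sequences live in a plain tibble
# (id, sequence) so everything downstream chains with dplyr; the alignment
# length is recoverable from any row because equal lengths are enforced here.

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Read an aligned FASTA file
#'
#' Reads a plain (wrapped or unwrapped) FASTA file of aligned, equal-length
#' nucleotide sequences. Sequences are upper-cased and validated against the
#' alphabet `A, C, G, T, N, -`; `N` and `-` are treated as missing data by the
#' site-deletion policies applied downstream.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, one row per record, in
#'   file order. The common sequence length is available via [aln_length()].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
#' read_alignment(fa)
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "mothwaves_input_error")
  }
  recs <- tryCatch(
    suppressWarnings(ape::read.FASTA(path)), # warns (returns NULL) on empty files
    error = function(e) abort(
      paste0("could not parse FASTA file: ", conditionMessage(e)),
      class = "mothwaves_input_error"
    )
  )
  if (length(recs) == 0) {
    abort("FASTA file contains no records", class = "mothwaves_input_error")
  }
  seqs <- toupper(vapply(as.character(recs), paste0, character(1), collapse = ""))
  aln <- tibble(id = names(recs), sequence = unname(seqs))
  validate_alignment(aln)
}

#' Validate an alignment tibble
#'
#' Checks the invariants every alignment consumer relies on: non-empty, unique
#' ids, equal positive sequence lengths, and characters restricted to
#' `A, C, G, T, N, -`.
#'
#' @param aln A data frame with columns `id` and `sequence`.
#' @return The validated alignment as a tibble (invisibly unchanged content).
#' @export
validate_alignment <- function(aln) {
  if (!is.data.frame(aln) || !all(c("id", "sequence") %in% names(aln))) {
    abort("alignment must be a data frame with columns `id` and `sequence`",
          class = "mothwaves_input_error")
  }
  aln <- as_tibble(aln)[, c("id", "sequence")]
  if (nrow(aln) == 0) {
    abort("alignment has no sequences", class = "mothwaves_input_error")
  }
  if (anyDuplicated(aln$id)) {
    abort("alignment ids are not unique", class = "mothwaves_input_error")
  }
  aln$sequence <- toupper(aln$sequence)
  lens <- nchar(aln$sequence)
  if (any(lens != lens[1]) || lens[1] == 0) {
    abort(
      paste0("sequences are not aligned to equal positive length (saw lengths ",
             paste(sort(unique(lens)), collapse = ", "), ")"),
      class = "mothwaves_alignment_error"
    )
  }
  chars <- unique(strsplit(paste0(aln$sequence, collapse = ""), "")[[1]])
  bad <- setdiff(chars, ALN_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("sequences contain characters outside {A,C,G,T,N,-}: ",
                 paste(bad, collapse = ", ")),
          class = "mothwaves_input_error")
  }
  aln
}

#' Alignment length in base pairs
#'
#' @param aln An alignment tibble from [read_alignment()].
#' @return Integer length common to all sequences.
#' @export
aln_length <- function(aln) {
  aln <- validate_alignment(aln)
  nchar(aln$sequence[1])
}

#' Write an alignment tibble to FASTA
#'
#' @param aln An alignment tibble (`id`, `sequence`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  aln <- validate_alignment(aln)
  writeLines(paste0(">", aln$id, "\n", aln$sequence), path)
  invisible(path)
}

#' Read a population-assignment map
#'
#' Reads a CSV with header `sample_id,population,locality,year,phase` mapping
#' every sequence id to the population it was sampled from. Phases follow the
#' outbreak cycle: rising, peak, decline, troughs.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `sample_id`, `population`, `locality`,
#'   `year`, `phase`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("population map not found: ", path), class = "mothwaves_input_error")
  }
  pm <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_popmap(pm)
}

#' Validate a population map
#'
#' @param popmap A data frame with at least `sample_id` and `population`.
#' @return The validated tibble.
#' @export
validate_popmap <- function(popmap) {
  need <- c("sample_id", "population")
  if (!is.data.frame(popmap) || !all(need %in% names(popmap))) {
    abort("population map needs columns `sample_id` and `population`",
          class = "mothwaves_input_error")
  }
  popmap <- as_tibble(popmap)
  if (anyDuplicated(popmap$sample_id)) {
    abort("population map has duplicated sample ids", class = "mothwaves_input_error")
  }
  known <- c("rising", "peak", "decline", "troughs")
  if ("phase" %in% names(popmap)) {
    bad <- setdiff(unique(stats::na.omit(popmap$phase)), known)
    if (length(bad) > 0) {
      abort(paste0("unknown population phase(s): ", paste(bad, collapse = ", ")),
            class = "mothwaves_input_error")
    }
  }
  popmap
}

#' Apply a missing-site deletion policy to an alignment
#'
#' Complete deletion (the default throughout the package) drops every
#' alignment column that carries `N` or `-` in any sequence, so haplotype
#' collapsing and the diversity statistics all see the same effective sites.
#'
#' @param aln An alignment tibble.
#' @param policy `"complete"` (drop columns with any missing data) or
#'   `"none"` (keep all columns).
#' @return The alignment restricted to retained columns, with attribute
#'   `effective_length` giving the number of retained sites.
#' @export
apply_deletion_policy <- function(aln, policy = c("complete", "none")) {
  policy <- match.arg(policy)
  aln <- validate_alignment(aln)
  mat <- alignment_matrix(aln)
  if (policy == "complete") {
    keep <- !apply(mat == "N" | mat == "-", 2, any)
    mat <- mat[, keep, drop = FALSE]
    aln$sequence <- unname(apply(mat, 1, paste0, collapse = ""))
    if (ncol(mat) == 0) {
      abort("complete deletion removed every site; no columns left",
            class = "mothwaves_input_error")
    }
  }
  attr(aln, "effective_length") <- ncol(mat)
  aln
}

# character matrix (rows = sequences, cols = sites)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  rownames(m) <- aln$id
  m
}
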