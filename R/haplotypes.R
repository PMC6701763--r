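# Haplotype tables: distinct sequence variants with per-population counts.
# This is the central data model of the population-genetics arm; the printed
# per-locality counts of the West Siberian survey ship as a packaged fixture.

#' Construct a haplotype table
#'
#' Low-level constructor; most users get haplotype tables from
#' [collapse_haplotypes()] or [load_table1_fixture()].
#'
#' @param haplotypes Tibble with columns `name`, `sequence` (may be `NA` for
#'   counts-only tables), `total_count`.
#' @param counts Tibble with columns `name`, `population`, `count` (positive
#'   entries only).
#' @return An object of class `hap_table`.
#' @export
new_hap_table <- function(haplotypes, counts) {
  haplotypes <- as_tibble(haplotypes)
  counts <- as_tibble(counts)
  stopifnot(all(c("name", "sequence", "total_count") %in% names(haplotypes)),
            all(c("name", "population", "count") %in% names(counts)))
  if (anyDuplicated(haplotypes$name)) {
    abort("haplotype names are not unique", class = "mothwaves_input_error")
  }
  rs <- counts |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  chk <- dplyr::left_join(haplotypes, rs, by = "name")
  chk$total[is.na(chk$total)] <- 0L
  if (any(chk$total_count != chk$total)) {
    abort("per-haplotype total_count does not match the count matrix row sums",
          class = "mothwaves_input_error")
  }
  structure(
    list(
      haplotypes = haplotypes,
      counts = counts,
      n = sum(counts$count)
    ),
    class = "hap_table"
  )
}

#' Collapse an alignment into a haplotype table
#'
#' Identical sequences (after the site-deletion policy, so statistics and
#' haplotype counts are computed on the same effective sites) share one
#' haplotype. Haplotypes are named `H1, H2, ...` in descending total-count
#' order, ties broken by first occurrence in input order, which makes the
#' naming invariant under record shuffling whenever counts are distinct.
#'
#' @param aln Alignment tibble from [read_alignment()].
#' @param popmap Population map with `sample_id`, `population`; every
#'   alignment id must be mapped.
#' @param policy Site-deletion policy passed to [apply_deletion_policy()].
#' @param names Optional named character vector mapping default names
#'   (`H1`, ...) to preferred labels (e.g. a published Roman-numeral scheme).
#' @return A `hap_table` whose haplotype sequences are the collapsed
#'   (policy-reduced) sequences.
#' @export
collapse_haplotypes <- function(aln, popmap, policy = "complete", names = NULL) {
  aln <- apply_deletion_policy(aln, policy)
  popmap <- validate_popmap(popmap)
  unmapped <- setdiff(aln$id, popmap$sample_id)
  if (length(unmapped) > 0) {
    abort(paste0("alignment ids missing from the population map: ",
                 paste(head(unmapped, 5), collapse = ", "),
                 if (length(unmapped) > 5) ", ..."),
          class = "mothwaves_mapping_error")
  }
  dat <- dplyr::left_join(aln, popmap[, c("sample_id", "population")],
                          by = c(id = "sample_id"))
  # first-occurrence order then descending count
  first_seen <- match(unique(dat$sequence), dat$sequence)
  uniq <- tibble(sequence = unique(dat$sequence), first = first_seen)
  uniq$total_count <- as.integer(table(factor(dat$sequence, levels = uniq$sequence)))
  uniq <- uniq[order(-uniq$total_count, uniq$first), ]
  uniq$name <- paste0("H", seq_len(nrow(uniq)))
  if (!is.null(names)) {
    hit <- uniq$name %in% base::names(names)
    uniq$name[hit] <- unname(names[uniq$name[hit]])
  }
  dat$name <- uniq$name[match(dat$sequence, uniq$sequence)]
  counts <- dat |>
    dplyr::count(.data$name, .data$population, name = "count") |>
    dplyr::arrange(match(.data$name, uniq$name), .data$population)
  new_hap_table(
    haplotypes = uniq[, c("name", "sequence", "total_count")],
    counts = counts
  )
}

#' Re-expand a haplotype table into per-individual sequences
#'
#' Inverse of [collapse_haplotypes()] up to ids: emits one record per sampled
#' individual, with synthetic ids, plus the matching population map. Requires
#' a table with sequences.
#'
#' @param ht A `hap_table` with sequences.
#' @return List with `alignment` and `popmap` tibbles.
#' @export
expand_haplotypes <- function(ht) {
  stopifnot(inherits(ht, "hap_table"))
  require_sequences(ht)
  rows <- ht$counts[rep(seq_len(nrow(ht$counts)), ht$counts$count), ]
  seqs <- ht$haplotypes$sequence[match(rows$name, ht$haplotypes$name)]
  ids <- sprintf("s%04d", seq_len(nrow(rows)))
  list(
    alignment = tibble(id = ids, sequence = seqs),
    popmap = tibble(sample_id = ids, population = rows$population)
  )
}

require_sequences <- function(ht) {
  if (any(is.na(ht$haplotypes$sequence))) {
    abort("this haplotype table carries counts only (no sequences); the requested operation needs sequences",
          class = "mothwaves_input_error")
  }
  invisible(ht)
}

#' Total haplotype counts
#'
#' @param ht A `hap_table`.
#' @return Named integer vector of total counts in table order.
#' @export
hap_counts <- function(ht) {
  stopifnot(inherits(ht, "hap_table"))
  setNames(ht$haplotypes$total_count, ht$haplotypes$name)
}

#' Load the packaged West Siberian COI haplotype survey
#'
#' Per-locality haplotype counts for the 2015-2016 West Siberian gypsy moth
#' survey: 220 specimens from 18 localities grouped into 6 populations
#' (Chulym, Chany, Omsk, Ishim, Tyumen, Trans-Ural), 16 distinct haplotypes.
#' The table carries counts only (the survey published no sequences), so
#' sequence-requiring statistics reject it with a clear error.
#'
#' @return A `hap_table` aggregated to populations, with the per-locality
#'   records attached as attribute `localities`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "west_siberia_coi_haplotypes.csv",
                      package = "mothwaves", mustWork = TRUE)
  loc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  counts <- loc |>
    dplyr::group_by(.data$haplotype, .data$population) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  totals <- counts |>
    dplyr::group_by(.data$haplotype) |>
    dplyr::summarise(total_count = sum(.data$count), .groups = "drop")
  first <- match(totals$haplotype, loc$haplotype)
  ord <- order(-totals$total_count, first)
  haplotypes <- tibble(
    name = totals$haplotype[ord],
    sequence = NA_character_,
    total_count = totals$total_count[ord]
  )
  counts <- counts |>
    dplyr::rename(name = "haplotype") |>
    dplyr::arrange(match(.data$name, haplotypes$name), .data$population)
  ht <- new_hap_table(haplotypes, counts)
  attr(ht, "localities") <- loc
  ht
}

#' @export
print.hap_table <- function(x, ...) {
  has_seq <- !any(is.na(x$haplotypes$sequence))
  cat("<hap_table> ", nrow(x$haplotypes), " haplotypes, ", x$n, " samples, ",
      length(unique(x$counts$population)), " populations",
      if (!has_seq) " (counts only)", "\n", sep = "")
  print(x$haplotypes, ...)
  invisible(x)
}

#' @export
tidy.hap_table <- function(x, ...) {
  dplyr::left_join(x$counts,
                   x$haplotypes[, c("name", "total_count")],
                   by = "name") |>
    dplyr::rename(haplotype = "name")
}

#' @export
glance.hap_table <- function(x, ...) {
  tibble(
    n = x$n,
    h = nrow(x$haplotypes),
    n_populations = length(unique(x$counts$population)),
    has_sequences = !any(is.na(x$haplotypes$sequence))
  )
}

#' @export
autoplot.hap_table <- function(object, ...) {
  d <- tidy(object)
  d$haplotype <- factor(d$haplotype, levels = object$haplotypes$name)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$population, y = .data$count,
                                  fill = .data$haplotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "specimens", fill = "haplotype") +
    ggplot2::theme_minimal()
}
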