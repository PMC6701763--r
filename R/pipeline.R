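# End-to-end runs. Each run_*() chains the module functions, writes
# TSV/JSON/GML results into an output directory together with a provenance
# record (config + seed + package version) sufficient to reproduce the
# deterministic outputs byte-identically, and returns its results invisibly.

write_provenance <- function(out_dir, step, config) {
  rec <- list(
    step = step,
    package = "mothwaves",
    version = as.character(utils::packageVersion("mothwaves")),
    config = config
  )
  jsonlite::write_json(rec, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the population-genetics arm end to end
#'
#' Reads an alignment and population map (or takes a counts-only haplotype
#' table), collapses haplotypes, and writes the diversity summary, the
#' haplotype table, and the pairwise Fst matrix. With a counts-only table,
#' only count-based statistics (n, h, Hd, major-haplotype share) are
#' computed; sequence-requiring statistics are reported as unavailable.
#'
#' @param fasta Path to an aligned FASTA file (or `NULL` when `table` given).
#' @param popmap_csv Path to the population map CSV (with `fasta`).
#' @param table A counts-only `hap_table` alternative to `fasta`.
#' @param out_dir Output directory (created if missing).
#' @param policy Site-deletion policy.
#' @param top_m Number of top haplotypes for the major-share statistic.
#' @return Invisibly, a list with `haplotypes`, `diversity`, `fst` (or the
#'   counts-only summary).
#' @export
run_popgen <- function(fasta = NULL, popmap_csv = NULL, table = NULL,
                       out_dir, policy = "complete", top_m = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fasta) && is.null(table)) {
    abort("provide either a FASTA path or a hap_table", class = "mothwaves_input_error")
  }
  if (!is.null(table)) {
    stopifnot(inherits(table, "hap_table"))
    counts <- hap_counts(table)
    summary <- tibble(
      n = table$n, h = length(counts),
      Hd = haplotype_diversity(counts),
      major_share_pct = major_haplotype_fraction(counts, min(top_m, length(counts))),
      S = NA_integer_, k = NA_real_, Pi = NA_real_, D = NA_real_, Fs = NA_real_,
      note = "counts-only table: sequence-based statistics unavailable"
    )
    readr::write_tsv(summary, file.path(out_dir, "diversity.tsv"))
    readr::write_tsv(tidy(table), file.path(out_dir, "haplotypes.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "diversity.json"),
                         auto_unbox = TRUE, digits = NA)
    write_provenance(out_dir, "popgen",
                    list(input = "hap_table", policy = policy, top_m = top_m))
    return(invisible(list(haplotypes = table, diversity = summary, fst = NULL)))
  }
  aln <- read_alignment(fasta)
  popmap <- read_popmap(popmap_csv)
  ht <- collapse_haplotypes(aln, popmap, policy)
  div <- diversity_stats(aln, popmap, policy)
  div$major_share_pct <- NA_real_
  div$major_share_pct[div$population == "pooled"] <-
    major_haplotype_fraction(ht, min(top_m, nrow(ht$haplotypes)))
  fst <- fst_matrix(aln, popmap, policy)
  readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))
  readr::write_tsv(tidy(ht), file.path(out_dir, "haplotypes.tsv"))
  write_fst_tsv(fst, file.path(out_dir, "fst.tsv"))
  jsonlite::write_json(div, file.path(out_dir, "diversity.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(out_dir, "popgen",
                  list(fasta = fasta, popmap = popmap_csv, policy = policy,
                       top_m = top_m))
  invisible(list(haplotypes = ht, diversity = div, fst = fst))
}

#' Run the parsimony-network arm end to end
#'
#' @inheritParams run_popgen
#' @param alpha Parsimony probability for the connection limit.
#' @return Invisibly, the `parsimony_network`.
#' @export
run_network <- function(fasta, popmap_csv, out_dir, alpha = 0.95,
                        policy = "complete") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(fasta)
  popmap <- read_popmap(popmap_csv)
  ht <- collapse_haplotypes(aln, popmap, policy)
  net <- build_network(ht, alpha = alpha)
  export_network(net, file.path(out_dir, "network.gml"), "gml")
  export_network(net, file.path(out_dir, "network"), "tsv")
  write_provenance(out_dir, "network",
                  list(fasta = fasta, popmap = popmap_csv, alpha = alpha,
                       policy = policy, max_steps = net$limit$max_steps))
  invisible(net)
}

#' Run the travelling-wave arm end to end
#'
#' Writes the per-region cyclicity table (`f_max`, peak, `L = 1/f_max`), the
#' pairwise cross-correlation matrix (values/t above the diagonal, lags
#' below), and a JSON report.
#'
#' @param timeseries_csv Long CSV `year,region,hectares`.
#' @param out_dir Output directory.
#' @param axis_order Optional region ordering along the geographic axis.
#' @param max_lag,pad_to,alpha Passed to [wave_report()].
#' @return Invisibly, the `wave_report`.
#' @export
run_waves <- function(timeseries_csv, out_dir, axis_order = NULL,
                      max_lag = 10, pad_to = 256, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_outbreak_panel(timeseries_csv)
  rep <- wave_report(panel, axis_order, max_lag, pad_to, alpha)
  readr::write_tsv(rep$spectra, file.path(out_dir, "cyclicity.tsv"))
  mat <- as.data.frame(rep$matrix)
  mat <- cbind(region = rownames(rep$matrix), mat)
  readr::write_tsv(mat, file.path(out_dir, "cross_correlation.tsv"))
  jsonlite::write_json(
    list(spectra = rep$spectra, pairs = rep$pairs, monotone = rep$monotone),
    file.path(out_dir, "wave_report.json"), auto_unbox = TRUE, digits = NA
  )
  write_provenance(out_dir, "waves",
                  list(timeseries = timeseries_csv, axis_order = axis_order,
                       max_lag = max_lag, pad_to = pad_to, alpha = alpha))
  invisible(rep)
}

#' Generate fixture files with the synthetic-data generators
#'
#' @param kind `"haplotypes"` or `"outbreaks"`.
#' @param out_dir Output directory.
#' @param seed Integer seed (forwarded to the generator).
#' @param ... Further generator arguments, see [simulate_haplotypes()] and
#'   [simulate_outbreaks()].
#' @return Invisibly, the generator's return value.
#' @export
run_simulate <- function(kind = c("haplotypes", "outbreaks"), out_dir,
                         seed = 1, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "haplotypes") {
    sim <- simulate_haplotypes(seed = seed, ...)
    write_alignment(sim$alignment, file.path(out_dir, "alignment.fasta"))
    readr::write_csv(sim$popmap, file.path(out_dir, "popmap.csv"))
    jsonlite::write_json(sim$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    sim <- simulate_outbreaks(seed = seed, ...)
    readr::write_csv(sim$panel[, c("year", "region", "hectares")],
                     file.path(out_dir, "outbreaks.csv"))
    jsonlite::write_json(sim$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_provenance(out_dir, paste0("simulate_", kind),
                  c(list(seed = seed), list(...)))
  invisible(sim)
}
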