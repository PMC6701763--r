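# Seeded generators for both analysis arms. The haplotype generator plants a
# star genealogy (a founder plus variants a known number of mutational steps
# away) under the infinite-sites approximation, so the segregating-site count
# and the haplotype spectrum are exactly known; the outbreak generator plants
# a raised-cosine outbreak pulse train with a fixed per-region propagation
# delay, lognormal noise and a reporting floor, so troughs are exactly zero.
# Both are pure functions of (config, seed).

#' Simulate a star-genealogy haplotype sample
#'
#' Defaults mimic the West Siberian COI survey: 220 samples over 6 demes with
#' the sample sizes of the six studied populations, three dominant haplotypes
#' (counts 98, 74, 33 at 0-2 steps from the founder), two doubletons and 11
#' singletons 1-2 steps out — the count spectrum of the published survey.
#'
#' @param n_samples Total sample size.
#' @param seq_length Alignment length in bp (default 590, the COI fragment).
#' @param founder_spectrum Data frame with columns `count` and `steps`
#'   (mutational distance from the founder; the founder row has `steps = 0`).
#'   Counts (plus singletons) must sum to `n_samples`.
#' @param n_singletons Number of additional singleton haplotypes.
#' @param singleton_steps Steps-from-founder values the singletons draw from.
#' @param n_demes Number of demes (populations).
#' @param deme_sizes Integer vector of deme sample sizes (defaults to the
#'   six survey sizes 50, 21, 58, 15, 64, 12 when `n_samples = 220` and
#'   `n_demes = 6`, otherwise a near-even split).
#' @param migration_mode `"panmictic"` (individuals randomly shuffled across
#'   demes: all demes draw from one pool) or `"isolated"` (each deme drifts
#'   independently by Wright-Fisher resampling of the planted haplotype
#'   frequencies for `drift_generations` generations, deme size = effective
#'   size).
#' @param drift_generations Generations of drift in isolated mode.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List with `alignment` (tibble `id`, `sequence`), `popmap` (tibble
#'   `sample_id`, `population`, `locality`, `year`, `phase`), and `manifest`
#'   (planted truth: haplotype spectrum with sequences and steps, planted
#'   segregating sites, mode, seed).
#' @export
simulate_haplotypes <- function(n_samples = 220,
                                seq_length = 590,
                                founder_spectrum = data.frame(
                                  count = c(98, 74, 33, 2, 2),
                                  steps = c(0, 1, 2, 1, 2)
                                ),
                                n_singletons = 11,
                                singleton_steps = 1:2,
                                n_demes = 6,
                                deme_sizes = NULL,
                                migration_mode = c("panmictic", "isolated"),
                                drift_generations = 0,
                                seed = 1) {
  migration_mode <- match.arg(migration_mode)
  founder_spectrum <- as.data.frame(founder_spectrum)
  stopifnot(all(c("count", "steps") %in% names(founder_spectrum)),
            all(founder_spectrum$count > 0), all(founder_spectrum$steps >= 0))
  set.seed(seed)
  sing_steps <- if (n_singletons > 0) {
    sample(rep(singleton_steps, length.out = n_singletons))
  } else integer(0)
  spectrum <- rbind(
    founder_spectrum[, c("count", "steps")],
    if (n_singletons > 0) data.frame(count = rep(1L, n_singletons), steps = sing_steps)
  )
  if (sum(spectrum$count) != n_samples) {
    abort(paste0("haplotype counts (", sum(spectrum$count),
                 ") must sum to n_samples (", n_samples, ")"),
          class = "mothwaves_config_error")
  }
  total_steps <- sum(spectrum$steps)
  if (total_steps > seq_length) {
    abort("seq_length is smaller than the total number of planted mutations",
          class = "mothwaves_config_error")
  }
  bases <- c("A", "C", "G", "T")
  founder <- sample(bases, seq_length, replace = TRUE)
  # infinite-sites: every mutation hits its own site, no back-mutation
  mut_sites <- sample.int(seq_length, total_steps)
  seqs <- character(nrow(spectrum))
  used <- 0
  for (i in seq_len(nrow(spectrum))) {
    s <- founder
    st <- spectrum$steps[i]
    if (st > 0) {
      sites <- mut_sites[used + seq_len(st)]
      used <- used + st
      for (pos in sites) s[pos] <- sample(setdiff(bases, s[pos]), 1)
    }
    seqs[i] <- paste0(s, collapse = "")
  }
  spectrum$sequence <- seqs
  spectrum$name <- paste0("H", seq_len(nrow(spectrum)))

  if (is.null(deme_sizes)) {
    deme_sizes <- if (n_samples == 220 && n_demes == 6) {
      c(50L, 21L, 58L, 15L, 64L, 12L)
    } else {
      sz <- rep(n_samples %/% n_demes, n_demes)
      sz[seq_len(n_samples %% n_demes)] <- sz[seq_len(n_samples %% n_demes)] + 1L
      sz
    }
  }
  stopifnot(length(deme_sizes) == n_demes, sum(deme_sizes) == n_samples)
  demes <- paste0("deme", seq_len(n_demes))

  if (migration_mode == "panmictic") {
    hap_of <- rep(seq_len(nrow(spectrum)), spectrum$count)
    hap_of <- sample(hap_of) # random shuffle across demes = one pool
    deme_of <- rep(demes, deme_sizes)
  } else {
    freq0 <- spectrum$count / n_samples
    per_deme <- lapply(seq_len(n_demes), function(d) {
      cnt <- as.vector(rmultinom(1, deme_sizes[d], freq0))
      for (g in seq_len(drift_generations)) {
        if (sum(cnt > 0) == 1) break
        cnt <- as.vector(rmultinom(1, deme_sizes[d], cnt / sum(cnt)))
      }
      rep(seq_len(nrow(spectrum)), cnt)
    })
    hap_of <- unlist(per_deme)
    deme_of <- rep(demes, deme_sizes)
  }
  ids <- sprintf("sim%04d", seq_len(n_samples))
  alignment <- tibble(id = ids, sequence = spectrum$sequence[hap_of])
  popmap <- tibble(
    sample_id = ids, population = deme_of, locality = deme_of,
    year = 2015L, phase = NA_character_
  )
  realized <- table(factor(hap_of, levels = seq_len(nrow(spectrum))))
  manifest <- list(
    planted_spectrum = as_tibble(spectrum[, c("name", "count", "steps", "sequence")]),
    realized_counts = setNames(as.integer(realized), spectrum$name),
    planted_S = total_steps,
    planted_Hd = haplotype_diversity(spectrum$count),
    seq_length = seq_length,
    migration_mode = migration_mode,
    drift_generations = drift_generations,
    deme_sizes = setNames(as.integer(deme_sizes), demes),
    seed = seed
  )
  list(alignment = alignment, popmap = popmap, manifest = manifest)
}

#' Simulate a travelling-wave outbreak panel
#'
#' Region `r` (0-based), year `t` gets
#' `max(0, A * pulse(t - r * delay) * noise - floor)` where `pulse` is a
#' raised cosine of the configured period (so inter-outbreak troughs are
#' exactly zero) and `noise` is lognormal. Defaults state the studied world:
#' 6 regions, 25 years of records, an 11-year cycle, a one-year delay per
#' region along the axis.
#'
#' @param n_regions Number of regions along the geographic axis.
#' @param n_years Length of each series (years).
#' @param period_years Outbreak cycle length.
#' @param delay_per_region Propagation delay between adjacent regions (years).
#' @param amplitude Peak outbreak area (hectares).
#' @param noise_sigma Lognormal sigma of the multiplicative noise.
#' @param zero_floor Reporting floor (hectares) subtracted before clamping
#'   at zero.
#' @param start_year First calendar year of the records.
#' @param seed Integer seed.
#' @return List with `panel` (tibble `region`, `year`, `hectares`) and
#'   `manifest` (true period, per-region delays, per-pair lags, seed).
#' @export
simulate_outbreaks <- function(n_regions = 6, n_years = 25, period_years = 11,
                               delay_per_region = 1, amplitude = 5e4,
                               noise_sigma = 0.3, zero_floor = 2500,
                               start_year = 1991L, seed = 1) {
  stopifnot(n_regions >= 1, n_years >= 3)
  set.seed(seed)
  regions <- sprintf("region%02d", seq_len(n_regions))
  years <- start_year + seq_len(n_years) - 1L
  pulse <- function(t) (1 + cos(2 * pi * t / period_years)) / 2
  panel <- purrr::list_rbind(purrr::map(seq_len(n_regions), function(r) {
    t <- seq_len(n_years)
    clean <- amplitude * pulse(t - (r - 1) * delay_per_region)
    noisy <- clean * stats::rlnorm(n_years, meanlog = -noise_sigma^2 / 2,
                                   sdlog = noise_sigma)
    tibble(region = regions[r], year = years,
           hectares = pmax(0, noisy - zero_floor))
  }))
  delays <- setNames((seq_len(n_regions) - 1) * delay_per_region, regions)
  pair_lags <- outer(delays, delays, function(a, b) b - a)
  manifest <- list(
    period_years = period_years,
    delays = delays,
    pair_lags = pair_lags, # lag of column region relative to row region
    amplitude = amplitude, noise_sigma = noise_sigma,
    zero_floor = zero_floor, seed = seed
  )
  list(panel = validate_outbreak_panel(panel), manifest = manifest)
}
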