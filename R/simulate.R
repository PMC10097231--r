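#' Configuration for the synthetic hexaploid SSR generator
#'
#' Defaults emulate the study design the analysis targets: nine SSR loci with
#' 8-21 alleles each on a 2-bp (dinucleotide) size grid starting near 96 bp,
#' two cultivar groups of 14 and 6 accessions with group-structured allele
#' frequencies, ploidy 6, and sub-bp fragment sizing jitter.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus length-2 range of allele pool sizes per locus.
#' @param size_start,size_step allele size grid origin and step in bp.
#' @param accessions_per_group integer vector, one entry per group.
#' @param concentration Dirichlet concentration of group allele frequencies;
#'   small values give differentiated groups, large values homogeneous ones.
#' @param crosses list of `list(parent_a=, parent_b=, n_offspring=)` pedigree
#'   crosses (accession ids from the simulated groups).
#' @param size_jitter_sd Gaussian sizing jitter sd in bp.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 9, alleles_per_locus = c(8, 21),
                       size_start = 96, size_step = 2,
                       accessions_per_group = c(14, 6), concentration = 0.5,
                       crosses = list(), size_jitter_sd = 0.2, seed = 1) {
  stopifnot(n_loci >= 1, size_step >= 2, concentration > 0,
            all(accessions_per_group >= 1), size_jitter_sd >= 0,
            length(alleles_per_locus) == 2, alleles_per_locus[1] >= 1)
  structure(list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 size_start = size_start, size_step = size_step,
                 accessions_per_group = accessions_per_group,
                 concentration = concentration, crosses = crosses,
                 size_jitter_sd = size_jitter_sd, ploidy = 6L, seed = seed),
            class = "sim_config")
}

#' Simulate a marker panel with per-locus allele pools
#'
#' Loci are named `SIM001`, `SIM002`, ... with placeholder primers; each locus
#' gets an allele pool of grid-aligned sizes (all sharing parity when the step
#' is 2), with pool sizes drawn from the configured range.
#'
#' @param cfg a [sim_config].
#' @return List: `panel` (a [marker_panel]) and `pools` (named list of allele
#'   size vectors).
#' @export
simulate_panel <- function(cfg) {
  set.seed(cfg$seed)
  loci <- sprintf("SIM%03d", seq_len(cfg$n_loci))
  dyes <- rep(c("6-FAM", "HEX", "ATTO550"), length.out = cfg$n_loci)
  pools <- lapply(seq_len(cfg$n_loci), function(l) {
    choices <- seq(cfg$alleles_per_locus[1], cfg$alleles_per_locus[2])
    n_all <- choices[sample.int(length(choices), 1)]
    start <- cfg$size_start + cfg$size_step * sample.int(40, 1)
    start + cfg$size_step * sort(sample.int(2 * n_all, n_all)) # within a 2x window
  })
  names(pools) <- loci
  panel <- marker_panel(data.frame(
    locus = loci,
    forward_primer = vapply(seq_len(cfg$n_loci), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), ""),
    reverse_primer = vapply(seq_len(cfg$n_loci), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), ""),
    dye = dyes, annealing_temp_c = 58L,
    reference = "synthetic", stringsAsFactors = FALSE))
  list(panel = panel, pools = pools)
}

rdirichlet1 <- function(n_cat, concentration) {
  g <- stats::rgamma(n_cat, shape = concentration)
  while (sum(g) == 0) g <- stats::rgamma(n_cat, shape = concentration)
  g / sum(g)
}

#' Simulate group-structured hexaploid genotype profiles
#'
#' Per group and locus, allele frequencies are drawn from a symmetric
#' Dirichlet over the locus pool; each accession then receives six
#' independent allele copies from its group's frequencies and is scored as
#' the distinct-allele set (dosage discarded, as in dominant scoring). Under
#' this model an allele at copy frequency f is carried by a fraction
#' 1 - (1 - f)^6 of accessions.
#'
#' @param cfg a [sim_config].
#' @param sim output of [simulate_panel] (regenerated from `cfg` when `NULL`).
#' @param group_freqs optional pre-built frequency list (group -> locus ->
#'   numeric vector over the pool), bypassing the Dirichlet draw.
#' @return List of [genotype_profile], groups named `G1`, `G2`, ...
#' @export
simulate_groups <- function(cfg, sim = NULL, group_freqs = NULL) {
  if (is.null(sim)) sim <- simulate_panel(cfg)
  set.seed(cfg$seed + 1L)
  profiles <- list()
  for (g in seq_along(cfg$accessions_per_group)) {
    gname <- paste0("G", g)
    freqs <- if (!is.null(group_freqs)) {
      group_freqs[[gname]]
    } else {
      lapply(sim$pools, function(pool) rdirichlet1(length(pool), cfg$concentration))
    }
    for (a in seq_len(cfg$accessions_per_group[g])) {
      calls <- lapply(seq_along(sim$pools), function(l) {
        copies <- sample(sim$pools[[l]], cfg$ploidy, replace = TRUE,
                         prob = freqs[[l]])
        sort(unique(copies))
      })
      names(calls) <- names(sim$pools)
      id <- sprintf("%s_%02d", gname, a)
      profiles[[id]] <- genotype_profile(id, gname, calls)
    }
  }
  unname(profiles)
}

#' Simulate offspring of a pedigree cross
#'
#' Balanced hexaploid gamete model: each offspring receives, per locus, three
#' allele copies sampled without replacement from a six-copy expansion of
#' parent A's allele set (the sorted distinct alleles cycled to six copies)
#' plus three from parent B's, then collapses to the distinct set. Offspring
#' alleles are therefore always a subset of the parental union. A locus
#' missing in either parent is missing in the offspring.
#'
#' @param parent_a,parent_b [genotype_profile] parents.
#' @param n_offspring number of offspring.
#' @param seed RNG seed.
#' @return List of [genotype_profile] with group `"hybrid"` and pedigree
#'   metadata.
#' @export
simulate_cross <- function(parent_a, parent_b, n_offspring, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- intersect(names(parent_a$calls), names(parent_b$calls))
  expand6 <- function(sizes) rep(sizes, length.out = 6L)
  lapply(seq_len(n_offspring), function(o) {
    calls <- lapply(loci, function(l) {
      ga <- sample(expand6(parent_a$calls[[l]]), 3L)
      gb <- sample(expand6(parent_b$calls[[l]]), 3L)
      sort(unique(c(ga, gb)))
    })
    names(calls) <- loci
    id <- sprintf("%sx%s_%02d", parent_a$accession_id, parent_b$accession_id, o)
    genotype_profile(id, "hybrid", calls,
                     metadata = list(pedigree = paste(parent_a$accession_id, "x",
                                                      parent_b$accession_id),
                                     parents = c(parent_a$accession_id,
                                                 parent_b$accession_id)))
  })
}

#' Add fragment-sizing jitter to true allele sizes
#'
#' Emulates between-run capillary sizing error: every allele observation gets
#' independent Gaussian jitter. Feeding the raw sizes of each accession-locus
#' call back through [bin_fragment_sizes] recovers the true integer sizes for
#' jitter sd up to about 0.3 bp on a 2-bp grid.
#'
#' @param profiles list of [genotype_profile].
#' @param jitter_sd Gaussian sd in bp (>= 0).
#' @param seed RNG seed.
#' @return Data frame: `accession`, `group`, `locus`, `true_size`, `raw_size`.
#' @export
add_size_noise <- function(profiles, jitter_sd, seed = NULL) {
  stopifnot(jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (p in profiles) {
    for (l in names(p$calls)) {
      sizes <- p$calls[[l]]
      rows[[length(rows) + 1L]] <- data.frame(
        accession = p$accession_id, group = p$group, locus = l,
        true_size = sizes,
        raw_size = sizes + stats::rnorm(length(sizes), sd = jitter_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild genotype profiles from jittered raw sizes
#'
#' Pools the raw sizes of each locus across accessions (the standard way
#' allele bins are defined across sequencer runs), bins them once with
#' [bin_fragment_sizes], and maps every observation back to its integer
#' allele.
#'
#' @param raw data frame from [add_size_noise].
#' @param min_step binning step, see [bin_fragment_sizes].
#' @return List of [genotype_profile] with binned integer calls.
#' @export
rebin_profiles <- function(raw, min_step = 2) {
  raw$bin <- NA_integer_
  for (l in unique(raw$locus)) {
    i <- raw$locus == l
    raw$bin[i] <- as.integer(bin_fragment_sizes(raw$raw_size[i], min_step))
  }
  out <- lapply(split(raw, raw$accession), function(d) {
    calls <- lapply(split(d, d$locus), function(dl) sort(unique(dl$bin)))
    genotype_profile(d$accession[1], d$group[1], calls)
  })
  unname(out[unique(raw$accession)])
}
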