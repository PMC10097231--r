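#' Carrier allele frequencies for one accession group
#'
#' For dominant-scored polyploid data the allele frequency p_i is the carrier
#' percentage: the share of accessions in the group carrying the allele among
#' those scored (non-missing) at the locus. Dosage never enters.
#'
#' @param profiles list of [genotype_profile].
#' @param group a group label, or a vector of labels to pool (e.g. both
#'   cultivar groups for a published-style pooled table).
#' @param panel optional [marker_panel] restricting/ordering loci.
#' @return A `frequency_slice` data frame with columns `locus`, `allele`, `p`
#'   (percent in (0, 100]); attributes `n_group` (accessions pooled) and
#'   `group`.
#' @export
allele_frequencies <- function(profiles, group, panel = NULL) {
  grp <- profile_groups(profiles)
  sel <- profiles[grp %in% group]
  if (!length(sel)) stop("no accessions in group ", paste(group, collapse = "+"))
  loci <- all_loci(sel, panel)
  rows <- list()
  for (l in loci) {
    calls <- lapply(sel, function(p) p$calls[[l]])
    scored <- !vapply(calls, is.null, logical(1))
    n <- sum(scored)
    if (n == 0L) next
    tallies <- table(unlist(calls[scored]))
    rows[[l]] <- data.frame(locus = l,
                            allele = as.integer(names(tallies)),
                            p = 100 * as.integer(tallies) / n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_group = length(sel), group = paste(group, collapse = "+"),
            class = c("frequency_slice", "data.frame"))
}

#' Observed heterozygosity for dosage-unknown polyploids
#'
#' The fraction of accessions in a group whose allele set at a locus contains
#' at least two distinct members. With unknown dosage this is the only
#' observable heterozygosity: an accession showing a single band may carry up
#' to six copies of it, so "homozygous" here means "single distinct allele".
#'
#' @param profiles list of [genotype_profile].
#' @param group group label(s).
#' @param locus locus name.
#' @return Fraction in \[0, 1\], or `NA` if no accession was scored.
#' @export
observed_heterozygosity <- function(profiles, group, locus) {
  grp <- profile_groups(profiles)
  calls <- lapply(profiles[grp %in% group], function(p) p$calls[[locus]])
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(NA_real_)
  mean(vapply(calls, length, integer(1)) >= 2L)
}

#' Dominant-marker polymorphism information content
#'
#' Per-band informativeness for presence/absence data: each band with carrier
#' fraction f contributes 2 f (1 - f); the locus PIC is the mean over its
#' bands. Bounded by 0.5, attained at f = 0.5.
#'
#' @param frequencies carrier fractions in (0, 1\] (one per band of a locus).
#' @return PIC value in \[0, 0.5\].
#' @export
pic_dominant <- function(frequencies) {
  if (!length(frequencies)) stop("no band frequencies supplied")
  if (any(frequencies <= 0 | frequencies > 1)) {
    stop("band frequencies must be fractions in (0, 1]")
  }
  mean(2 * frequencies * (1 - frequencies))
}

#' Per-locus, per-group diversity summary
#'
#' For every locus and group: allele count, allele size range, observed
#' heterozygosity, dominant-marker PIC and the maximal number of distinct
#' alleles seen in a single genotype — the row layout of published SSR
#' characterization tables.
#'
#' @param profiles list of [genotype_profile].
#' @param groups character vector of group labels to summarize.
#' @param panel optional [marker_panel].
#' @return A `locus_summary_table` data frame; feed to [locus_summary_means]
#'   for the "Average" row.
#' @export
locus_summary_table <- function(profiles, groups, panel = NULL) {
  rows <- list()
  for (g in groups) {
    freq <- allele_frequencies(profiles, g, panel)
    grp_prof <- profiles[profile_groups(profiles) %in% g]
    for (l in unique(freq$locus)) {
      fl <- freq[freq$locus == l, ]
      sizes <- vapply(grp_prof, function(p) length(p$calls[[l]]) %||% 0L, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus = l,
        size_min = min(fl$allele), size_max = max(fl$allele),
        allele_number = nrow(fl),
        ho = observed_heterozygosity(profiles, g, l),
        pic = pic_dominant(fl$p / 100),
        max_alleles = max(sizes),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("locus_summary_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify alleles as common, unique and rare between two groups
#'
#' An allele is *common* when carried in both groups, *unique* when carried in
#' exactly one (the genetic individuality of that group), and *rare* when its
#' carrier frequency is at most `rare_threshold` percent in every group that
#' carries it.
#'
#' Two inputs are supported. Given two [allele_frequencies] slices, the
#' partition is computed by set membership over distinct (locus, allele)
#' pairs. Given the bundled `"table2"` fixture (an `allele_class_table` whose
#' printed columns already are the partition), the printed categories are kept
#' and only the rare rule is applied to the printed frequencies; this
#' preserves the published counts verbatim even where the table double-lists
#' an allele.
#'
#' @param x an [allele_frequencies] slice for group A, or an
#'   `allele_class_table` fixture.
#' @param y an [allele_frequencies] slice for group B (ignored for a fixture).
#' @param rare_threshold rare cutoff in percent (default 10).
#' @return An `allele_classification`: list with `table` (per-allele rows:
#'   `locus`, `allele`, `category`, `rare`, frequency columns) and `counts`
#'   (per category: n and percentage of the pooled total at 1 decimal).
#' @export
classify_alleles <- function(x, y = NULL, rare_threshold = 10) {
  if (inherits(x, "allele_class_table")) {
    tab <- data.frame(locus = x$locus, allele = x$allele, category = x$category,
                      p_i = x$p_i, rare = x$p_i <= rare_threshold,
                      printed_rare = x$printed_rare, stringsAsFactors = FALSE)
  } else {
    if (is.null(y)) stop("supply two frequency slices, or a classified fixture table")
    key <- function(d) paste(d$locus, d$allele)
    in_a <- key(x); in_b <- key(y)
    pool <- unique(rbind(x[, c("locus", "allele")], y[, c("locus", "allele")]))
    pool <- pool[order(pool$locus, pool$allele), ]
    k <- paste(pool$locus, pool$allele)
    pa <- x$p[match(k, in_a)]
    pb <- y$p[match(k, in_b)]
    category <- ifelse(!is.na(pa) & !is.na(pb), "common",
                       ifelse(!is.na(pa), "unique_a", "unique_b"))
    rare <- apply(cbind(pa, pb), 1L, function(v) all(v[!is.na(v)] <= rare_threshold))
    tab <- data.frame(locus = pool$locus, allele = pool$allele, category = category,
                      p_a = pa, p_b = pb, rare = rare, stringsAsFactors = FALSE)
    rownames(tab) <- NULL
  }
  n <- table(tab$category)
  counts <- data.frame(category = names(n), n = as.integer(n),
                       pct = round_half_up(100 * as.integer(n) / nrow(tab), 1),
                       stringsAsFactors = FALSE)
  structure(list(table = tab, counts = counts, total = nrow(tab),
                 rare_threshold = rare_threshold),
            class = "allele_classification")
}

#' @export
print.allele_classification <- function(x, ...) {
  cat("Allele classification:", x$total, "alleles, rare threshold p_i <=",
      x$rare_threshold, "%\n")
  print(x$counts, row.names = FALSE)
  cat("rare:", sum(x$table$rare), "alleles\n")
  invisible(x)
}

#' Homozygous loci per accession
#'
#' Lists, per accession of a group, the loci at which exactly one distinct
#' allele was observed (the dosage-unknown reading of homozygosity), ranked by
#' count. Accessions with an empty list display only heterozygous loci.
#'
#' @param profiles list of [genotype_profile].
#' @param group group label(s).
#' @return Data frame `accession`, `n_homozygous`, `loci` (semicolon-joined),
#'   ordered by decreasing count.
#' @export
homozygosity_report <- function(profiles, group) {
  sel <- profiles[profile_groups(profiles) %in% group]
  rows <- lapply(sel, function(p) {
    single <- names(p$calls)[vapply(p$calls, length, integer(1)) == 1L]
    data.frame(accession = p$accession_id, n_homozygous = length(single),
               loci = paste(single, collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_homozygous, out$accession), , drop = FALSE]
}
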