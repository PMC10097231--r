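#' Load a bundled reference fixture
#'
#' The package bundles transcriptions of the published per-locus summaries for
#' the Lithuanian plum germplasm study: `"table1"` (LT-origin vs reference
#' cultivar locus summaries), `"table2"` (allele sizes and carrier frequencies
#' with their common/unique columns and rare-allele bolding), `"table3"`
#' (hybrids vs parental forms) and `"table4"` (the nine-locus ECPGR marker
#' panel). Transcription is verbatim, typographic quirks included: one
#' BPPCT007 allele (134 bp) is printed in both the common and the LT-unique
#' column, and the printed bold (rare) flags do not everywhere agree with the
#' stated p_i <= 10 rule. The `printed_rare` column stores the bolding as
#' printed so analyses can be compared against it.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return `"table1"`/`"table3"`: a `locus_summary_table` data frame;
#'   `"table2"`: an `allele_class_table` data frame with columns `locus`,
#'   `allele`, `category`, `p_i`, `printed_rare`; `"table4"`: a
#'   [marker_panel].
#' @export
load_fixture <- function(name) {
  path <- function(f) system.file("extdata", f, package = "plumprint", mustWork = TRUE)
  switch(name,
    table1 = {
      x <- utils::read.csv(path("table1_locus_summary.csv"), stringsAsFactors = FALSE)
      class(x) <- c("locus_summary_table", "data.frame")
      x
    },
    table2 = {
      x <- utils::read.csv(path("table2_allele_frequencies.csv"), stringsAsFactors = FALSE)
      stopifnot(all(x$category %in% c("common", "unique_lt", "unique_ref")),
                all(x$p_i > 0 & x$p_i <= 100))
      class(x) <- c("allele_class_table", "data.frame")
      attr(x, "group_sizes") <- c("LT-origin" = 14L, "R-Plum" = 6L, pooled = 20L)
      x
    },
    table3 = {
      x <- utils::read.csv(path("table3_locus_summary.csv"), stringsAsFactors = FALSE)
      x$max_alleles <- NA_integer_
      class(x) <- c("locus_summary_table", "data.frame")
      x
    },
    table4 = marker_panel(utils::read.csv(path("table4_marker_panel.csv"),
                                          stringsAsFactors = FALSE)),
    stop("unknown fixture '", name, "'; expected table1, table2, table3 or table4")
  )
}

#' Column means of a locus summary table
#'
#' Per-group means of allele number, observed heterozygosity, PIC and (when
#' present) maximal alleles per genotype, rounded half-up to 2 decimals the
#' way published summary rows are.
#'
#' @param x a `locus_summary_table` (see [load_fixture] or
#'   [locus_summary_table]).
#' @return Data frame with one row per group.
#' @export
locus_summary_means <- function(x) {
  out <- do.call(rbind, lapply(split(x, x$group), function(g) {
    data.frame(group = g$group[1],
               allele_number = round_half_up(mean(g$allele_number), 2),
               ho = round_half_up(mean(g$ho), 2),
               pic = round_half_up(mean(g$pic), 3),
               max_alleles = if ("max_alleles" %in% names(g) && !anyNA(g$max_alleles))
                 round_half_up(mean(g$max_alleles), 2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# round-half-up (printed tables do not use banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
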