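#' Accession pairs not resolved by a locus subset
#'
#' Fingerprinting reads "separated" as pairwise profile inequality: two
#' accessions are unresolved by a set of loci when their allele sets agree at
#' every locus in the set. A missing call compares as a wildcard — a locus one
#' accession lacks cannot prove the pair distinct.
#'
#' @param profiles list of [genotype_profile].
#' @param loci character vector of locus names (nonempty).
#' @return Data frame with columns `a`, `b`: the unresolved accession pairs.
#' @export
profiles_distinct <- function(profiles, loci) {
  stopifnot(length(loci) >= 1L)
  ids <- profile_ids(profiles)
  n <- length(profiles)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (!any(vapply(loci, function(l) {
          a <- profiles[[i]]$calls[[l]]
          b <- profiles[[j]]$calls[[l]]
          !is.null(a) && !is.null(b) && !identical(a, b)
        }, logical(1)))) {
          rows[[length(rows) + 1L]] <- data.frame(a = ids[i], b = ids[j],
                                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Greedy minimal discriminating marker set
#'
#' The published procedure: start from the most informative locus by PIC and
#' keep adding loci in decreasing PIC order (ties broken alphabetically) until
#' every pair of genotypes is distinguishable. If the full panel never
#' resolves all pairs (duplicate profiles), all loci are returned with
#' `resolved = FALSE`.
#'
#' @param profiles list of [genotype_profile] (at least one).
#' @param pic named numeric vector of per-locus PIC values; computed from the
#'   pooled carrier frequencies of `profiles` when `NULL`.
#' @return List with `selected` (ordered loci), `unresolved_per_step`
#'   (pair counts after each addition), `resolved` flag and `pic_order`.
#' @export
greedy_minimal_set <- function(profiles, pic = NULL) {
  loci <- all_loci(profiles)
  if (is.null(pic)) {
    freq <- allele_frequencies(profiles, unique(profile_groups(profiles)))
    pic <- vapply(split(freq$p / 100, freq$locus), pic_dominant, numeric(1))
  }
  if (!all(loci %in% names(pic))) stop("PIC values missing for some loci")
  ord <- loci[order(-pic[loci], loci)]
  if (length(profiles) < 2L) {
    return(list(selected = character(0), unresolved_per_step = integer(0),
                resolved = TRUE, pic_order = ord))
  }
  selected <- character(0)
  steps <- integer(0)
  for (l in ord) {
    selected <- c(selected, l)
    unresolved <- nrow(profiles_distinct(profiles, selected))
    steps <- c(steps, unresolved)
    if (unresolved == 0L) {
      return(list(selected = selected, unresolved_per_step = steps,
                  resolved = TRUE, pic_order = ord))
    }
  }
  list(selected = selected, unresolved_per_step = steps, resolved = FALSE,
       pic_order = ord)
}

#' Exhaustive minimal discriminating marker set
#'
#' Enumeration oracle for [greedy_minimal_set]: subsets are tried by
#' increasing size, then lexicographically over alphabetized locus names; the
#' first fully discriminating subset is returned. Refuses panels above 15 loci
#' (2^L enumeration).
#'
#' @param profiles list of [genotype_profile].
#' @return List with `selected` and `resolved`; `resolved = FALSE` (with all
#'   loci) when even the full panel leaves duplicate profiles.
#' @export
exhaustive_minimal_set <- function(profiles) {
  loci <- sort(all_loci(profiles))
  if (length(loci) > 15L) {
    stop("more than 15 loci: exhaustive enumeration refused, use greedy_minimal_set")
  }
  if (length(profiles) < 2L) return(list(selected = character(0), resolved = TRUE))
  if (nrow(profiles_distinct(profiles, loci)) > 0L) {
    return(list(selected = loci, resolved = FALSE))
  }
  for (size in seq_along(loci)) {
    subsets <- utils::combn(loci, size, simplify = FALSE)
    for (s in subsets) {
      if (nrow(profiles_distinct(profiles, s)) == 0L) {
        return(list(selected = s, resolved = TRUE))
      }
    }
  }
  list(selected = loci, resolved = TRUE)
}
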