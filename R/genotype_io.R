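#' Construct a marker panel
#'
#' A marker panel describes the SSR loci used for fingerprinting: locus name,
#' primer pair, fluorescent dye and annealing temperature. The bundled
#' nine-locus ECPGR plum panel is available through [load_fixture]`("table4")`.
#'
#' @param loci data frame with columns `locus`, `forward_primer`,
#'   `reverse_primer`, `dye`, `annealing_temp_c` and optionally `reference`.
#' @return A `marker_panel` object (a validated data frame).
#' @export
marker_panel <- function(loci) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("locus", "forward_primer", "reverse_primer", "dye", "annealing_temp_c")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols)) {
    stop("marker panel lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"reference" %in% names(loci)) loci$reference <- ""
  if (anyDuplicated(loci$locus)) stop("duplicate locus names in panel")
  loci$annealing_temp_c <- as.integer(loci$annealing_temp_c)
  if (any(loci$annealing_temp_c < 40 | loci$annealing_temp_c > 72)) {
    stop("annealing temperatures must lie in [40, 72] degrees C")
  }
  for (col in c("forward_primer", "reverse_primer")) {
    p <- toupper(loci[[col]])
    if (any(!nzchar(p)) || any(grepl("[^ACGT]", p))) {
      stop("primer sequences must be nonempty ACGT strings (column ", col, ")")
    }
    loci[[col]] <- p
  }
  class(loci) <- c("marker_panel", "data.frame")
  loci
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("SSR marker panel:", nrow(x), "loci\n")
  print.data.frame(x[, c("locus", "dye", "annealing_temp_c")], row.names = FALSE)
  invisible(x)
}

#' Construct a genotype profile
#'
#' One accession's dominant-scored SSR calls. Because dosage is unknown in
#' polyploids, a call is the *set* of distinct allele fragment sizes observed
#' at a locus: between 1 and 6 sizes for a hexaploid, or absent for a missing
#' locus.
#'
#' @param accession_id accession label.
#' @param group group label (e.g. `"LT-origin"`, `"R-Plum"`, `"hybrid"`).
#' @param calls named list, one element per scored locus, each a vector of
#'   distinct positive integer allele sizes in bp.
#' @param metadata optional named list (skin colour, pedigree, ...).
#' @return A `genotype_profile` object.
#' @export
genotype_profile <- function(accession_id, group, calls, metadata = list()) {
  stopifnot(is.character(accession_id), length(accession_id) == 1L)
  calls <- lapply(calls, function(x) sort(unique(as.integer(x))))
  for (locus in names(calls)) {
    sizes <- calls[[locus]]
    if (length(sizes) < 1L || length(sizes) > 6L) {
      stop("accession '", accession_id, "', locus '", locus,
           "': a call must contain 1-6 distinct allele sizes, got ", length(sizes))
    }
    if (any(is.na(sizes)) || any(sizes <= 0L) || any(sizes >= 1000L)) {
      stop("accession '", accession_id, "', locus '", locus,
           "': allele sizes must be positive integers below 1000 bp")
    }
  }
  structure(list(accession_id = accession_id, group = as.character(group),
                 calls = calls, metadata = metadata),
            class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("<genotype_profile>", x$accession_id, "[", x$group, "]",
      length(x$calls), "loci\n")
  invisible(x)
}

profile_groups <- function(profiles) {
  vapply(profiles, function(p) p$group, character(1))
}

profile_ids <- function(profiles) {
  vapply(profiles, function(p) p$accession_id, character(1))
}

all_loci <- function(profiles, panel = NULL) {
  if (!is.null(panel)) return(panel$locus)
  unique(unlist(lapply(profiles, function(p) names(p$calls))))
}

#' Read a genotype table
#'
#' Reads a TSV (or CSV) genotype table with header
#' `accession<TAB>group<TAB><locus1><TAB>...`; each locus cell holds a
#' `/`-separated list of allele sizes in bp, an empty cell meaning a missing
#' locus. Duplicated sizes within a cell collapse to one (dosage is never
#' inferred).
#'
#' @param path path to the table.
#' @param panel optional [marker_panel]; columns not naming a panel locus are
#'   rejected.
#' @param sep field separator, `"\t"` by default.
#' @return List of [genotype_profile] objects.
#' @export
read_genotype_table <- function(path, panel = NULL, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || !identical(tolower(names(tab)[1:2]), c("accession", "group"))) {
    stop("genotype table must start with 'accession' and 'group' columns")
  }
  loci <- names(tab)[-(1:2)]
  if (!is.null(panel)) {
    bad <- setdiff(loci, panel$locus)
    if (length(bad)) stop("loci not in panel: ", paste(bad, collapse = ", "))
    known_groups <- NULL
  }
  lapply(seq_len(nrow(tab)), function(i) {
    calls <- list()
    for (locus in loci) {
      cell <- trimws(tab[i, locus])
      if (!nzchar(cell)) next
      parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
      sizes <- suppressWarnings(as.integer(trimws(parts)))
      if (anyNA(sizes)) {
        stop("non-numeric allele size in row ", i, ", column '", locus, "': ", cell)
      }
      sizes <- sort(unique(sizes))
      if (length(sizes) > 6L) {
        stop("accession '", tab$accession[i], "', locus '", locus,
             "': more than 6 distinct allele sizes")
      }
      calls[[locus]] <- sizes
    }
    genotype_profile(tab$accession[i], tab$group[i], calls)
  })
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table]: one row per accession, allele sets as
#' `/`-joined ascending sizes, empty cell for a missing locus.
#'
#' @param profiles list of [genotype_profile].
#' @param path output path.
#' @param panel optional [marker_panel] fixing the column order.
#' @export
write_genotype_table <- function(profiles, path, panel = NULL) {
  loci <- all_loci(profiles, panel)
  rows <- lapply(profiles, function(p) {
    cells <- vapply(loci, function(l) {
      if (is.null(p$calls[[l]])) "" else paste(p$calls[[l]], collapse = "/")
    }, character(1))
    c(p$accession_id, p$group, cells)
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("accession", "group", loci)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bin raw fragment sizes into integer alleles
#'
#' Capillary sizing returns fractional base-pair estimates that jitter between
#' runs and instruments (shifts of a few bp are routine between platforms).
#' Raw sizes — typically pooled per locus across the runs being binned — are
#' clustered by constrained single linkage: neighbours closer than
#' `min_step / 2` merge (true alleles sit at least `min_step` apart, so half
#' the spacing is the natural decision boundary), but never into a cluster
#' spanning `min_step` or more, which keeps adjacent-allele clouds from
#' chaining together. Each cluster is labeled with its rounded median.
#'
#' @param raw_sizes numeric vector of raw fractional sizes (bp).
#' @param min_step minimal spacing between true alleles in bp (default 2, the
#'   dinucleotide repeat unit).
#' @return Named numeric vector mapping each raw size to its integer bin; the
#'   mapping is monotone non-decreasing.
#' @export
bin_fragment_sizes <- function(raw_sizes, min_step = 2) {
  stopifnot(min_step >= 1)
  if (length(raw_sizes) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(raw_sizes <= 0)) stop("raw sizes must be positive")
  s <- sort(unique(raw_sizes))
  # clusters as index ranges over s; merge smallest adjacent gap first
  lo <- seq_along(s); hi <- seq_along(s)
  blocked <- FALSE
  repeat {
    if (length(lo) < 2L) break
    gaps <- s[lo[-1]] - s[hi[-length(hi)]]
    eligible <- which(gaps < min_step / 2)
    if (!length(eligible)) break
    merged_any <- FALSE
    for (j in eligible[order(gaps[eligible])]) {
      if (s[hi[j + 1L]] - s[lo[j]] < min_step) {
        lo <- lo[-(j + 1L)]; hi <- hi[-j]
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) { blocked <- TRUE; break }
  }
  if (blocked) {
    warning("raw sizes denser than min_step: possible over-merged or split bins")
  }
  cluster_of <- findInterval(raw_sizes, s[lo])
  labels <- vapply(seq_along(lo), function(j) {
    floor(stats::median(raw_sizes[cluster_of == j]) + 0.5)  # round half up
  }, numeric(1))
  stats::setNames(labels[cluster_of], as.character(raw_sizes))
}

#' Recode genotype profiles as a binary allele-presence matrix
#'
#' Dominant 0/1 recoding: one column per observed (locus, allele size) pair,
#' ordered by panel locus order then ascending size; cell 1 iff the accession
#' carries the allele, `NA` across a locus the accession was not scored at.
#' Monomorphic columns (present in every scored accession) are flagged in the
#' `monomorphic` attribute, not dropped.
#'
#' @param profiles list of [genotype_profile].
#' @param panel optional [marker_panel] fixing locus order.
#' @return An `allele_matrix`: integer matrix with attributes `locus` and
#'   `size` (per column) and `monomorphic`.
#' @export
to_binary_matrix <- function(profiles, panel = NULL) {
  stopifnot(length(profiles) >= 1L)
  loci <- all_loci(profiles, panel)
  cols <- do.call(rbind, lapply(loci, function(l) {
    sizes <- sort(unique(unlist(lapply(profiles, function(p) p$calls[[l]]))))
    if (!length(sizes)) return(NULL)
    data.frame(locus = l, size = sizes, stringsAsFactors = FALSE)
  }))
  ids <- profile_ids(profiles)
  m <- matrix(NA_integer_, nrow = length(profiles), ncol = nrow(cols),
              dimnames = list(ids, paste0(cols$locus, ":", cols$size)))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    for (l in intersect(loci, names(p$calls))) {
      j <- which(cols$locus == l)
      m[i, j] <- as.integer(cols$size[j] %in% p$calls[[l]])
    }
  }
  mono <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    all(v[!is.na(v)] == 1L)
  }, logical(1))
  structure(m, locus = cols$locus, size = cols$size, monomorphic = mono,
            group = profile_groups(profiles), class = c("allele_matrix", "matrix"))
}

#' Write profiles in STRUCTURE raw format (ploidy 6)
#'
#' Each accession occupies six rows; per locus the observed distinct allele
#' sizes fill the first slots once each in ascending order and the remaining
#' slots carry the missing code -9 (dosage being unknown, absent copies are
#' treated as missing data). A header row of locus names is written first.
#'
#' @param profiles list of [genotype_profile].
#' @param path output path.
#' @param panel optional [marker_panel] fixing locus order.
#' @export
write_structure_format <- function(profiles, path, panel = NULL) {
  loci <- all_loci(profiles, panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(loci, collapse = " "), con)
  for (p in profiles) {
    slots <- lapply(loci, function(l) {
      sizes <- p$calls[[l]]
      if (is.null(sizes)) rep(-9L, 6L) else c(sizes, rep(-9L, 6L - length(sizes)))
    })
    block <- do.call(cbind, slots)
    for (r in 1:6) {
      writeLines(paste(c(p$accession_id, block[r, ]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a STRUCTURE raw format file written by [write_structure_format]
#'
#' @param path path to the file.
#' @return A `structure_data` object: see [structure_data].
#' @export
read_structure_format <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  if (length(body) %% 6L != 0L) stop("body line count not a multiple of 6")
  fields <- strsplit(trimws(body), "\\s+")
  ids <- vapply(fields, `[`, character(1), 1L)
  acc <- unique(ids)
  slot_list <- lapply(fields, function(f) as.integer(f[-1]))
  n <- length(acc)
  slots <- array(NA_integer_, dim = c(n, length(loci), 6L),
                 dimnames = list(acc, loci, NULL))
  for (i in seq_len(n)) {
    rows <- which(ids == acc[i])
    if (length(rows) != 6L) stop("accession '", acc[i], "' does not span 6 rows")
    for (r in 1:6) slots[i, , r] <- slot_list[[rows[r]]]
  }
  structure_data_from_slots(slots)
}
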