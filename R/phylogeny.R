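#' Pairwise distances between binary band profiles
#'
#' Distances on a dominant 0/1 allele-presence matrix. With per-pair counts
#' a (shared presence), b and c (mismatches) and d (shared absence) over the
#' columns both accessions were scored at:
#' Dice `1 - 2a/(2a+b+c)` (the default for dominant marker data), Jaccard
#' `1 - a/(a+b+c)`, simple matching `(b+c)/(a+b+c+d)`. Columns with a missing
#' call in either accession are pairwise-deleted.
#'
#' @param m an [to_binary_matrix] allele matrix (0/1/NA).
#' @param metric `"dice"`, `"jaccard"` or `"simple_matching"`.
#' @return A [stats::dist] with attribute `metric`; entries in \[0, 1\].
#' @export
pairwise_distance <- function(m, metric = c("dice", "jaccard", "simple_matching")) {
  metric <- match.arg(metric)
  stopifnot(nrow(m) >= 2L)
  w <- !is.na(m)
  m0 <- m
  m0[!w] <- 0L
  storage.mode(m0) <- "double"
  storage.mode(w) <- "double"
  a <- m0 %*% t(m0)                 # shared presences over comparable columns
  ri <- m0 %*% t(w)                 # presences of i over columns comparable with j
  n_comp <- w %*% t(w)              # comparable column count
  if (any(n_comp[upper.tri(n_comp)] == 0)) {
    stop("some accession pair shares no comparable columns")
  }
  b <- ri - a
  c_ <- t(ri) - a
  d <- switch(metric,
    dice = {
      denom <- 2 * a + b + c_
      out <- 1 - 2 * a / denom
      out[denom == 0] <- 0
      out
    },
    jaccard = {
      denom <- a + b + c_
      out <- 1 - a / denom
      out[denom == 0] <- 0
      out
    },
    simple_matching = (b + c_) / n_comp
  )
  diag(d) <- 0
  dd <- stats::as.dist(d)
  attr(dd, "metric") <- metric
  dd
}

#' UPGMA dendrogram
#'
#' Size-weighted average-linkage clustering of a distance matrix; each merge
#' creates a node at half the merge distance, so the result is ultrametric.
#' Ties between equally close pairs are broken toward the lexicographically
#' lowest leaf-label pair, making the topology reproducible.
#'
#' @param d a [stats::dist] (e.g. from [pairwise_distance]).
#' @return An ultrametric [ape::phylo] tree.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  ord <- order(rownames(m))
  hc <- stats::hclust(stats::as.dist(m[ord, ord, drop = FALSE]), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for a UPGMA tree
#'
#' Resamples characters of the binary band matrix with replacement (columns
#' by default — each allele is one character; `unit = "locus"` resamples whole
#' locus blocks), rebuilds the UPGMA tree per replicate, and scores each
#' internal node of the reference tree by the percentage of replicate trees
#' containing its clade. All supports are retained in the returned tree;
#' rendered output conventionally suppresses values below `show_min`.
#'
#' @param m an [to_binary_matrix] allele matrix.
#' @param replicates number of bootstrap replicates (published analyses use
#'   1000).
#' @param seed RNG seed for reproducibility.
#' @param metric distance metric, see [pairwise_distance].
#' @param unit `"column"` or `"locus"` resampling unit.
#' @param show_min display threshold in percent recorded alongside (default 30).
#' @return List: `tree` (reference [ape::phylo] with `node.label` = support
#'   percentages), `support` (numeric per internal node), `replicates`,
#'   `show_min`.
#' @export
bootstrap_support <- function(m, replicates = 1000, seed = NULL,
                              metric = "dice", unit = c("column", "locus"),
                              show_min = 30) {
  unit <- match.arg(unit)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  ref <- upgma(pairwise_distance(m, metric))
  loci <- attr(m, "locus")
  boot_trees <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- if (unit == "column") {
      sample.int(ncol(m), ncol(m), replace = TRUE)
    } else {
      unlist(lapply(sample(unique(loci), length(unique(loci)), replace = TRUE),
                    function(l) which(loci == l)))
    }
    mb <- m[, cols, drop = FALSE]
    attr(mb, "locus") <- loci[cols]
    boot_trees[[b]] <- upgma(pairwise_distance(mb, metric))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boot_trees, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / replicates
  ref$node.label <- formatC(support, format = "fg")
  list(tree = ref, support = support, replicates = replicates, show_min = show_min)
}

#' Write a tree as Newick
#'
#' Branch lengths are node-height differences; internal-node support labels
#' (if present) are written as node labels readable by standard viewers.
#'
#' @param tree an [ape::phylo] tree, or the list returned by
#'   [bootstrap_support].
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo") && inherits(tree$tree, "phylo")) {
    tree <- tree$tree
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Cophenetic distances of an ultrametric tree
#'
#' @param tree an [ape::phylo] tree.
#' @return Symmetric matrix of leaf-to-leaf path distances.
#' @export
cophenetic_distances <- function(tree) {
  stats::cophenetic(tree)
}
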