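# shared builders for small in-code fixtures

mkprof <- function(id, group, calls) genotype_profile(id, group, calls)

# random dominant-scored profiles over n_loci loci with small allele pools;
# independent of the simulate module so it can serve as its cross-check
random_profiles <- function(n, n_loci = 5, pool_size = 4, group = "G",
                            base = 100) {
  loci <- paste0("L", seq_len(n_loci))
  lapply(seq_len(n), function(i) {
    calls <- lapply(seq_len(n_loci), function(l) {
      pool <- base + l * 20 + 2 * seq_len(pool_size)
      sort(unique(sample(pool, sample(1:6, 1), replace = TRUE)))
    })
    names(calls) <- loci
    genotype_profile(sprintf("%s%03d", group, i), group, calls)
  })
}

# two groups drawing from disjoint allele pools at every locus
disjoint_group_profiles <- function(n_per_group = 8, n_loci = 6) {
  loci <- paste0("L", seq_len(n_loci))
  mk <- function(gname, base, n) {
    lapply(seq_len(n), function(i) {
      calls <- lapply(seq_len(n_loci), function(l) {
        pool <- base + l * 40 + c(0, 2, 4, 6, 8)
        sort(unique(sample(pool, 6, replace = TRUE)))
      })
      names(calls) <- loci
      genotype_profile(sprintf("%s%02d", gname, i), gname, calls)
    })
  }
  c(mk("A", 100, n_per_group), mk("B", 400, n_per_group))
}

# brute-force unresolved-pair oracle: compares serialized per-locus calls
oracle_unresolved_pairs <- function(profiles, loci) {
  ids <- vapply(profiles, function(p) p$accession_id, character(1))
  sig <- function(p, l) {
    v <- p$calls[[l]]
    if (is.null(v)) NA_character_ else paste(v, collapse = ",")
  }
  out <- list()
  for (i in seq_along(profiles)) {
    for (j in seq_along(profiles)) {
      if (i >= j) next
      distinct <- FALSE
      for (l in loci) {
        a <- sig(profiles[[i]], l); b <- sig(profiles[[j]], l)
        if (!is.na(a) && !is.na(b) && a != b) distinct <- TRUE
      }
      if (!distinct) out[[length(out) + 1L]] <- c(ids[i], ids[j])
    }
  }
  out
}

# naive O(n^3) UPGMA returning the cophenetic matrix, as an independent oracle
oracle_upgma_cophenetic <- function(d) {
  m <- as.matrix(d)
  labs <- rownames(m)
  clusters <- as.list(labs)
  heights <- stats::setNames(rep(0, length(labs)), labs)
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  cd <- m
  while (length(clusters) > 1L) {
    best <- c(1L, 2L); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- cd[i, j]
      if (dij < bestd - 1e-12) { bestd <- dij; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    h <- bestd / 2
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- 2 * h
    }
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    newrow <- (ni * cd[i, ] + nj * cd[j, ]) / (ni + nj)
    keep <- setdiff(seq_along(clusters), c(i, j))
    cd <- rbind(cd[keep, keep, drop = FALSE], newrow[keep])
    cd <- cbind(cd, c(newrow[keep], 0))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
  }
  coph
}
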