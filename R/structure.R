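#' Build ploidy-6 admixture-model input from genotype profiles
#'
#' Lays each accession out over six allele slots per locus: the observed
#' distinct allele sizes fill the first slots once each in ascending order and
#' remaining slots are missing (the -9 convention). Loci with no observed
#' allele in any accession are dropped with a warning.
#'
#' @param profiles list of [genotype_profile].
#' @param panel optional [marker_panel] fixing locus order.
#' @return A `structure_data` object: accessions, loci, integer slot codes
#'   (0 = missing) and per-locus allele code books.
#' @export
structure_data <- function(profiles, panel = NULL) {
  loci <- all_loci(profiles, panel)
  ids <- profile_ids(profiles)
  slots <- array(-9L, dim = c(length(ids), length(loci), 6L),
                 dimnames = list(ids, loci, NULL))
  for (i in seq_along(profiles)) {
    for (l in intersect(loci, names(profiles[[i]]$calls))) {
      sizes <- profiles[[i]]$calls[[l]]
      slots[i, l, seq_along(sizes)] <- sizes
    }
  }
  structure_data_from_slots(slots)
}

# slots: n x L x 6 integer array of allele sizes, -9 = missing
structure_data_from_slots <- function(slots) {
  loci <- dimnames(slots)[[2]]
  keep <- vapply(seq_along(loci), function(l) any(slots[, l, ] != -9L), logical(1))
  if (!all(keep)) {
    warning("dropping all-missing loci: ", paste(loci[!keep], collapse = ", "))
    slots <- slots[, keep, , drop = FALSE]
    loci <- loci[keep]
  }
  books <- lapply(seq_along(loci), function(l) {
    sort(unique(as.vector(slots[, l, ])[as.vector(slots[, l, ]) != -9L]))
  })
  names(books) <- loci
  n <- dim(slots)[1]
  codes <- matrix(0L, nrow = n, ncol = length(loci) * 6L)
  for (l in seq_along(loci)) {
    for (s in 1:6) {
      v <- slots[, l, s]
      codes[, (l - 1L) * 6L + s] <- ifelse(v == -9L, 0L, match(v, books[[l]]))
    }
  }
  structure(list(accessions = dimnames(slots)[[1]], loci = loci,
                 codes = codes, n_alleles = vapply(books, length, integer(1)),
                 code_books = books, slots = slots),
            class = "structure_data")
}

#' @export
print.structure_data <- function(x, ...) {
  cat("<structure_data>", length(x$accessions), "accessions x", length(x$loci),
      "loci (ploidy-6 slots,", sum(x$codes == 0L), "missing)\n")
  invisible(x)
}

#' Fit the admixture model by Gibbs sampling
#'
#' STRUCTURE-style Bayesian clustering for dominant ploidy-6 data: each
#' non-missing allele slot is an independent allele copy drawn from one of K
#' clusters; cluster allele frequencies P have a Dirichlet(1) prior per locus
#' and admixture proportions Q a symmetric Dirichlet(1) prior per accession
#' (alpha fixed, not inferred). Missing slots are skipped in every likelihood
#' term. The reported `lnP` is the STRUCTURE-style model evidence estimate
#' `mean - var/2` of the post-burn-in data log-likelihood trace (the quantity
#' Evanno's delta-K is defined on); the raw posterior mean is kept as
#' `lnP_mean`. A fixed seed yields bit-identical output.
#'
#' @param data a [structure_data] object.
#' @param K number of clusters (>= 1); values above the accession count are
#'   permitted with a warning.
#' @param burn_in burn-in sweeps (desk-scale default 2000; published
#'   STRUCTURE analyses use 200000).
#' @param iterations post-burn-in sweeps (desk-scale default 5000; published
#'   runs use 500000).
#' @param seed RNG seed.
#' @return A `structure_run`: list with `K`, `seed`, `lnP`, `Q` (posterior
#'   mean accession x K admixture matrix, rows summing to 1), `P` (posterior
#'   mean cluster x allele frequencies, one block per locus), `loglik_trace`
#'   and the run settings.
#' @export
gibbs_fit <- function(data, K, burn_in = 2000, iterations = 5000, seed = NULL) {
  stopifnot(inherits(data, "structure_data"), K >= 1, iterations > 0, burn_in >= 0)
  if (K > length(data$accessions)) {
    warning("K exceeds the number of accessions")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- gibbs_admixture(data$codes, data$n_alleles, as.integer(K),
                         as.integer(burn_in), as.integer(iterations))
  Q <- fit$Q
  rownames(Q) <- data$accessions
  colnames(Q) <- paste0("cluster", seq_len(K))
  trace <- as.numeric(fit$loglik)
  post <- trace[(burn_in + 1):(burn_in + iterations)]
  lnP <- mean(post) - stats::var(post) / 2
  structure(list(K = K, seed = seed, burn_in = burn_in, iterations = iterations,
                 lnP = lnP, lnP_mean = fit$lnP, Q = Q, P = fit$P,
                 loglik_trace = trace),
            class = "structure_run")
}

#' @export
print.structure_run <- function(x, ...) {
  cat("<structure_run> K =", x$K, " lnP =", format(x$lnP), "\n")
  invisible(x)
}

#' Run a grid of admixture fits over K
#'
#' Independent [gibbs_fit] runs for each K in a range (published protocol:
#' K = 1..20, ten runs each). Seeds derive deterministically as
#' `seed_base * 1000 + K * 100 + run`.
#'
#' @param data a [structure_data] object.
#' @param k_range integer vector of K values.
#' @param runs_per_k independent runs per K.
#' @param burn_in,iterations sweep counts passed to [gibbs_fit].
#' @param seed_base base seed for the deterministic per-run derivation.
#' @param verbose log progress to stderr.
#' @return List of `structure_run` objects (each also carries `run`).
#' @export
run_grid <- function(data, k_range = 1:6, runs_per_k = 5, burn_in = 2000,
                     iterations = 5000, seed_base = 1, verbose = FALSE) {
  runs <- list()
  for (K in k_range) {
    for (r in seq_len(runs_per_k)) {
      seed <- seed_base * 1000 + K * 100 + r
      if (verbose) message("gibbs_fit K=", K, " run=", r, " seed=", seed)
      fit <- gibbs_fit(data, K, burn_in, iterations, seed = seed)
      fit$run <- r
      runs[[length(runs) + 1L]] <- fit
    }
  }
  runs
}

#' Summarize a run grid as a data frame
#'
#' @param runs list of `structure_run` objects.
#' @return Data frame with columns `K`, `run`, `seed`, `lnP`.
#' @export
run_grid_table <- function(runs) {
  do.call(rbind, lapply(runs, function(r) {
    data.frame(K = r$K, run = r$run %||% NA_integer_,
               seed = r$seed %||% NA_integer_, lnP = r$lnP)
  }))
}

#' Evanno delta-K estimator
#'
#' From replicate runs over consecutive K: L(K) is the mean lnP, L'(K) its
#' first difference, |L''(K)| the absolute second difference, and
#' delta-K(K) = mean|L''(K)| / sd(L(K) replicates). The K maximizing delta-K
#' (defined only for interior K with at least two runs) suggests the number of
#' genetic groups.
#'
#' @param runs list of `structure_run` objects (at least three consecutive K,
#'   two runs each).
#' @return An `evanno_result`: data frame per K (`K`, `n_runs`, `mean_lnP`,
#'   `sd_lnP`, `lprime`, `lsecond_abs`, `delta_k`) with attribute `best_k`
#'   (K values ranked by decreasing delta-K).
#' @export
evanno_delta_k <- function(runs) {
  tab <- run_grid_table(runs)
  ks <- sort(unique(tab$K))
  if (length(ks) < 3L || any(diff(ks) != 1L)) {
    stop("need at least 3 consecutive K values")
  }
  agg <- do.call(rbind, lapply(ks, function(k) {
    v <- tab$lnP[tab$K == k]
    data.frame(K = k, n_runs = length(v), mean_lnP = mean(v),
               sd_lnP = stats::sd(v))
  }))
  if (any(agg$n_runs < 2L)) stop("need at least 2 runs per K")
  L <- agg$mean_lnP
  agg$lprime <- c(NA, diff(L))
  agg$lsecond_abs <- c(NA, abs(diff(L, differences = 2)), NA)
  agg$delta_k <- agg$lsecond_abs / agg$sd_lnP
  if (any(agg$sd_lnP == 0 & !is.na(agg$lsecond_abs))) {
    warning("zero lnP standard deviation at some K; delta-K reported as Inf")
  }
  interior <- which(!is.na(agg$delta_k))
  ranked <- agg$K[interior][order(-agg$delta_k[interior])]
  structure(agg, best_k = ranked, class = c("evanno_result", "data.frame"))
}

#' Align and average Q matrices across runs at one K
#'
#' Cluster labels are arbitrary per run; labels are aligned to the first run
#' by greedy column matching on Q correlation, then averaged (rows
#' renormalized to sum to 1).
#'
#' @param runs list of `structure_run` objects sharing one K.
#' @return List: `Q` (aligned mean matrix), `assignments` (per run, the
#'   column permutation applied).
#' @export
align_and_average_q <- function(runs) {
  stopifnot(length(runs) >= 1L)
  K <- runs[[1]]$K
  if (!all(vapply(runs, function(r) r$K, numeric(1)) == K)) {
    stop("runs must share one K")
  }
  ref <- runs[[1]]$Q
  perms <- list(seq_len(K))
  qsum <- ref
  for (r in seq_along(runs)[-1]) {
    Q <- runs[[r]]$Q
    perm <- rep(NA_integer_, K)
    if (K == 1L) {
      perm <- 1L
    } else {
      cors <- suppressWarnings(stats::cor(ref, Q))
      cors[is.na(cors)] <- -Inf
      free_ref <- seq_len(K); free_run <- seq_len(K)
      while (length(free_ref)) {
        sub <- cors[free_ref, free_run, drop = FALSE]
        idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        perm[free_ref[idx[1]]] <- free_run[idx[2]]
        free_ref <- free_ref[-idx[1]]; free_run <- free_run[-idx[2]]
      }
    }
    perms[[r]] <- perm
    qsum <- qsum + Q[, perm, drop = FALSE]
  }
  Qm <- qsum / length(runs)
  Qm <- Qm / rowSums(Qm)
  list(Q = Qm, assignments = perms)
}

#' Plain-text bar plot of an admixture Q matrix
#'
#' @param Q accession x cluster matrix with rows summing to 1.
#' @param width bar width in characters.
#' @return Character vector, one bar line per accession.
#' @export
format_q_bars <- function(Q, width = 40) {
  glyphs <- c(LETTERS, letters)
  vapply(seq_len(nrow(Q)), function(i) {
    counts <- round(Q[i, ] * width)
    while (sum(counts) > width) counts[which.max(counts)] <- counts[which.max(counts)] - 1
    while (sum(counts) < width) counts[which.max(Q[i, ])] <- counts[which.max(Q[i, ])] + 1
    bar <- paste(rep(glyphs[seq_len(ncol(Q))], counts), collapse = "")
    sprintf("%-12s |%s|", rownames(Q)[i], bar)
  }, character(1))
}
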