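#' Build a pipeline configuration
#'
#' Collects every stage's parameters and seeds. Exactly one input source is
#' used: a genotype table (`input`), a bundled fixture name (`fixture`,
#' currently `"table2"` for the allele-classification stage alone), or a
#' simulation configuration (`sim`). `preset = "full"` mirrors the published
#' protocol (1000 bootstrap replicates, K = 1..20, 10 runs, burn-in 200000,
#' 500000 iterations); `preset = "desk"` scales the Bayesian stage down for
#' interactive work.
#'
#' @param input path to a genotype TSV, or `NULL`.
#' @param fixture bundled fixture name, or `NULL`.
#' @param sim a [sim_config], or `NULL`.
#' @param groups group labels to analyze (`NULL` = all observed groups).
#' @param rare_threshold rare-allele cutoff in percent, in (0, 100].
#' @param metric distance metric for [pairwise_distance].
#' @param bootstrap list with `replicates` and `seed`.
#' @param structure list with `k_min`, `k_max`, `runs`, `burn_in`,
#'   `iterations`, `seed`.
#' @param preset `"desk"` or `"full"` defaults for the unset stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, fixture = NULL, sim = NULL,
                            groups = NULL, rare_threshold = 10,
                            metric = "dice", bootstrap = NULL,
                            structure = NULL, preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (rare_threshold <= 0 || rare_threshold > 100) {
    stop("rare_threshold must lie in (0, 100]")
  }
  defaults <- if (preset == "full") {
    list(bootstrap = list(replicates = 1000, seed = 42),
         structure = list(k_min = 1, k_max = 20, runs = 10,
                          burn_in = 200000, iterations = 500000, seed = 7))
  } else {
    list(bootstrap = list(replicates = 200, seed = 42),
         structure = list(k_min = 1, k_max = 4, runs = 3,
                          burn_in = 500, iterations = 1000, seed = 7))
  }
  cfg <- list(input = input, fixture = fixture, sim = sim, groups = groups,
              rare_threshold = rare_threshold, metric = metric,
              bootstrap = utils::modifyList(defaults$bootstrap, bootstrap %||% list()),
              structure = utils::modifyList(defaults$structure, structure %||% list()),
              preset = preset)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full fingerprinting pipeline
#'
#' Orchestrates, in order: input loading (table, fixture or simulation),
#' per-locus diversity summaries, allele classification, minimal marker-set
#' selection, UPGMA tree with bootstrap supports, and the admixture run grid
#' with Evanno delta-K. Every stage logs its parameters and seeds to
#' `report.txt`; outputs are deterministic under fixed seeds. A stage failure
#' stops the pipeline with an error naming the stage.
#'
#' @param config a [pipeline_config].
#' @param outdir output directory (created if absent).
#' @return Invisibly, a named list of written file paths plus key in-memory
#'   results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("plumprint pipeline report",
                 paste("preset:", config$preset),
                 paste("config:", paste(deparse(unclass(config)), collapse = " ")))
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$fixture)) {
    cls <- stage("classification", {
      classify_alleles(load_fixture(config$fixture),
                       rare_threshold = config$rare_threshold)
    })
    path <- file.path(outdir, "classification.csv")
    utils::write.csv(cls$table, path, row.names = FALSE)
    log_lines <- c(log_lines,
                   paste("fixture mode:", config$fixture),
                   paste("alleles:", cls$total),
                   paste(sprintf("%s: %d (%.1f%%)", cls$counts$category,
                                 cls$counts$n, cls$counts$pct), collapse = "; "))
    writeLines(log_lines, file.path(outdir, "report.txt"))
    return(invisible(list(classification = path, result = cls,
                          report = file.path(outdir, "report.txt"))))
  }

  profiles <- stage("input", {
    if (!is.null(config$input)) {
      read_genotype_table(config$input)
    } else if (!is.null(config$sim)) {
      sim <- simulate_panel(config$sim)
      prof <- simulate_groups(config$sim, sim)
      for (cr in config$sim$crosses) {
        ids <- profile_ids(prof)
        prof <- c(prof, simulate_cross(prof[[match(cr$parent_a, ids)]],
                                       prof[[match(cr$parent_b, ids)]],
                                       cr$n_offspring,
                                       seed = config$sim$seed + 97L))
      }
      prof
    } else {
      stop("no input: set one of input, fixture or sim")
    }
  })
  if (!length(profiles)) stop("pipeline stage 'input' failed: empty input")
  groups <- config$groups %||% unique(profile_groups(profiles))
  log_lines <- c(log_lines, paste("accessions:", length(profiles)),
                 paste("groups:", paste(groups, collapse = ", ")))

  summary_tab <- stage("stats", locus_summary_table(profiles, groups))
  out$summary <- file.path(outdir, "summary.csv")
  utils::write.csv(summary_tab, out$summary, row.names = FALSE)

  if (length(groups) >= 2L) {
    cls <- stage("classification", {
      classify_alleles(allele_frequencies(profiles, groups[1]),
                       allele_frequencies(profiles, groups[2]),
                       rare_threshold = config$rare_threshold)
    })
    out$classification <- file.path(outdir, "classification.csv")
    utils::write.csv(cls$table, out$classification, row.names = FALSE)
  }

  minset <- stage("minset", greedy_minimal_set(profiles))
  out$minset <- file.path(outdir, "minset.json")
  jsonlite::write_json(minset[c("selected", "unresolved_per_step", "resolved")],
                       out$minset, auto_unbox = FALSE, pretty = TRUE)

  tree <- stage("tree", {
    m <- to_binary_matrix(profiles)
    bootstrap_support(m, replicates = config$bootstrap$replicates,
                      seed = config$bootstrap$seed, metric = config$metric)
  })
  out$tree <- file.path(outdir, "tree.nwk")
  write_newick(tree, out$tree)
  log_lines <- c(log_lines,
                 paste("bootstrap:", config$bootstrap$replicates, "replicates, seed",
                       config$bootstrap$seed, ", metric", config$metric))

  st <- config$structure
  runs <- stage("structure", {
    sd_obj <- structure_data(profiles)
    run_grid(sd_obj, k_range = st$k_min:st$k_max, runs_per_k = st$runs,
             burn_in = st$burn_in, iterations = st$iterations,
             seed_base = st$seed)
  })
  out$structure_runs <- file.path(outdir, "structure_runs.csv")
  utils::write.csv(run_grid_table(runs), out$structure_runs, row.names = FALSE)
  ev <- stage("evanno", evanno_delta_k(runs))
  out$evanno <- file.path(outdir, "evanno.csv")
  utils::write.csv(as.data.frame(ev), out$evanno, row.names = FALSE)
  best_k <- attr(ev, "best_k")[1]
  aligned <- align_and_average_q(Filter(function(r) r$K == best_k, runs))
  out$q_mean <- file.path(outdir, "q_mean.csv")
  utils::write.csv(aligned$Q, out$q_mean, row.names = TRUE)
  log_lines <- c(log_lines,
                 paste("structure grid: K", st$k_min, "-", st$k_max, ",", st$runs,
                       "runs, burn-in", st$burn_in, ",", st$iterations,
                       "iterations, seed base", st$seed),
                 paste("evanno best K:", best_k),
                 "", "admixture bars (best K):",
                 format_q_bars(aligned$Q))

  out$report <- file.path(outdir, "report.txt")
  writeLines(log_lines, out$report)
  out$best_k <- best_k
  out$minset_result <- minset
  invisible(out)
}
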