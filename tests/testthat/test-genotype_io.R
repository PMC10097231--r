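test_that("genotype tables parse, deduplicate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgroup\tBPPCT040\tBPPCT007",
               "Gyne\tLT-origin\t124/128/134\t130",
               "Alge\tLT-origin\t185/185/202\t",
               "Orija\tLT-origin\t124\t130/134"), path)
  prof <- read_genotype_table(path)
  expect_length(prof, 3L)
  expect_equal(prof[[1]]$calls$BPPCT040, c(124L, 128L, 134L))
  expect_equal(prof[[2]]$calls$BPPCT040, c(185L, 202L))  # duplicates collapse
  expect_null(prof[[2]]$calls$BPPCT007)                  # empty cell = missing
  out <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(prof, out)
  again <- read_genotype_table(out)
  expect_equal(lapply(again, function(p) p$calls), lapply(prof, function(p) p$calls))
  expect_equal(vapply(again, function(p) p$group, ""), rep("LT-origin", 3))
})

test_that("invalid genotype rows are rejected with locus context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgroup\tL1",
               "bad\tG\t100/102/104/106/108/110/112"), path)
  expect_error(read_genotype_table(path), "L1")
  writeLines(c("accession\tgroup\tL1", "bad\tG\t100/abc"), path)
  expect_error(read_genotype_table(path), "non-numeric")
  expect_error(genotype_profile("x", "G", list(L1 = integer(0))), "1-6")
  expect_error(genotype_profile("x", "G", list(L1 = 1200L)), "below 1000")
})

test_that("fragment-size binning merges jitter and is monotone and idempotent", {
  expect_equal(unname(bin_fragment_sizes(c(149.8, 150.1, 153.9), 2)),
               c(150, 150, 154))
  # chained linkage collapses to one bin labeled by the rounded median
  expect_equal(unname(bin_fragment_sizes(c(100.4, 101.3, 102.2), 2)),
               c(101, 101, 101))
  ints <- c(100, 104, 110, 112)
  expect_equal(unname(bin_fragment_sizes(ints, 2)), ints)          # identity
  once <- unname(bin_fragment_sizes(c(99.6, 100.2, 105.9), 2))
  expect_equal(unname(bin_fragment_sizes(once, 2)), once)          # idempotent
  set.seed(7)
  raw <- sort(runif(30, 100, 140))
  bins <- suppressWarnings(bin_fragment_sizes(raw, 2))
  expect_true(all(diff(bins[order(raw)]) >= 0))                    # monotone
  expect_length(bin_fragment_sizes(numeric(0)), 0L)
  expect_warning(bin_fragment_sizes(seq(100, 107, by = 0.9), 2), "over-merged")
})

test_that("binary recoding matches profiles and flags monomorphic columns", {
  prof <- list(mkprof("a1", "G", list(A = 100L)),
               mkprof("a2", "G", list(A = c(100L, 104L))))
  m <- to_binary_matrix(prof)
  expect_equal(colnames(m), c("A:100", "A:104"))
  expect_equal(unname(m[, "A:100"]), c(1L, 1L))
  expect_equal(unname(m[, "A:104"]), c(0L, 1L))
  expect_equal(unname(attr(m, "monomorphic")), c(TRUE, FALSE))

  # missing locus becomes NA cells excluded from frequency denominators
  prof3 <- c(prof, list(mkprof("a3", "G", list(B = 200L))))
  m3 <- to_binary_matrix(prof3)
  expect_true(all(is.na(m3["a3", c("A:100", "A:104")])))
  freq <- allele_frequencies(prof3, "G")
  expect_equal(freq$p[freq$locus == "A" & freq$allele == 100], 100)

  # column count equals distinct (locus, size) pairs
  set.seed(11)
  rp <- random_profiles(12, n_loci = 4)
  pairs <- unique(unlist(lapply(rp, function(p)
    mapply(paste, names(p$calls), p$calls, MoreArgs = list(sep = ":")))))
  expect_equal(ncol(to_binary_matrix(rp)), length(pairs))
})

test_that("frequencies from the binary matrix equal frequencies from profiles", {
  set.seed(23)
  rp <- random_profiles(15, n_loci = 4)
  freq <- allele_frequencies(rp, "G")
  m <- to_binary_matrix(rp)
  from_matrix <- 100 * colMeans(m, na.rm = TRUE)
  key <- paste0(freq$locus, ":", freq$allele)
  expect_equal(unname(from_matrix[key]), freq$p)
})

test_that("ploidy-6 layout pads with -9 and round-trips", {
  prof <- list(mkprof("x", "G", list(L1 = c(124L, 128L), L2 = 100L + 2L * (1:6))),
               mkprof("y", "G", list(L2 = 108L)))
  path <- withr::local_tempfile(fileext = ".str")
  write_structure_format(prof, path)
  lines <- strsplit(readLines(path), " ")
  # accession x: locus L1 slots are 124 128 -9 -9 -9 -9 down the 6 rows
  l1 <- vapply(lines[2:7], `[`, character(1), 2L)
  expect_equal(l1, c("124", "128", "-9", "-9", "-9", "-9"))
  l2 <- vapply(lines[2:7], `[`, character(1), 3L)
  expect_false(any(l2 == "-9"))                     # six alleles fill all slots
  # accession y misses L1 entirely: all six slots -9
  expect_equal(vapply(lines[8:13], `[`, character(1), 2L), rep("-9", 6))
  sd_rt <- read_structure_format(path)
  expect_equal(sd_rt$slots, structure_data(prof)$slots)
})

test_that("bundled fixtures are internally consistent", {
  t2 <- load_fixture("table2")
  per_locus <- table(t2$locus, t2$category)
  # common + unique counts add to the distinct total per locus and overall
  expect_equal(sum(per_locus), nrow(t2))
  expect_equal(nrow(t2), 157L)
  expect_equal(unname(colSums(per_locus)[c("common", "unique_lt", "unique_ref")]),
               c(79L, 62L, 16L))
  # first common entry for BPPCT040 as printed: 8 alleles, 116 bp at 20%
  b40 <- t2[t2$locus == "BPPCT040" & t2$category == "common", ]
  expect_equal(nrow(b40), 8L)
  expect_equal(b40$allele[1], 116L)
  expect_equal(b40$p_i[1], 20)

  t4 <- load_fixture("table4")
  expect_s3_class(t4, "marker_panel")
  expect_equal(nrow(t4), 9L)
  expect_equal(t4$annealing_temp_c[t4$locus == "CPSCT026"], 46L)
  expect_false(anyDuplicated(t4$locus) > 0)

  t3 <- load_fixture("table3")
  expect_equal(sum(t3$allele_number[t3$group == "hybrid"]), 191L)
  expect_equal(sum(t3$allele_number[t3$group == "parental"]), 109L)
  expect_error(load_fixture("table9"), "unknown fixture")
})
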