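test_that("carrier frequencies hit the observed floor and ceiling", {
  prof <- c(list(mkprof("c01", "P", list(L1 = c(100L, 102L)))),
            lapply(2:20, function(i) mkprof(sprintf("c%02d", i), "P",
                                            list(L1 = 102L))))
  freq <- allele_frequencies(prof, "P")
  expect_equal(freq$p[freq$allele == 100], 5)    # 1 of 20 carriers
  expect_equal(freq$p[freq$allele == 102], 100)  # carried by all
  expect_error(allele_frequencies(prof, "nope"), "no accessions")
})

test_that("observed heterozygosity is the multi-allele accession fraction", {
  # 2 multi-allele accessions of 6: the dosage-unknown Ho of 0.33
  prof <- c(lapply(1:2, function(i) mkprof(paste0("h", i), "R",
                                           list(L = c(100L, 104L)))),
            lapply(3:6, function(i) mkprof(paste0("h", i), "R", list(L = 100L))))
  expect_equal(round(observed_heterozygosity(prof, "R", "L"), 2), 0.33)
  # 10 of 14 gives the 0.71 pattern
  prof14 <- c(lapply(1:10, function(i) mkprof(paste0("x", i), "L",
                                              list(L = c(100L, 102L)))),
              lapply(11:14, function(i) mkprof(paste0("x", i), "L",
                                               list(L = 102L))))
  expect_equal(round(observed_heterozygosity(prof14, "L", "L"), 2), 0.71)
  expect_true(is.na(observed_heterozygosity(prof, "R", "absent")))
  # all single-allele: zero
  expect_equal(observed_heterozygosity(prof14[11:14], "L", "L"), 0)
})

test_that("dominant PIC follows 2f(1-f), bounded and symmetric", {
  expect_equal(pic_dominant(0.5), 0.5)
  expect_equal(pic_dominant(1.0), 0)
  # {0.2, 0.4}: (0.32 + 0.48) / 2; cross-checked by per-band enumeration
  bands <- c(0.2, 0.4)
  expect_equal(pic_dominant(bands), 0.40)
  expect_equal(pic_dominant(bands), mean(sapply(bands, function(f) 2 * f * (1 - f))))
  set.seed(3)
  for (i in 1:20) {
    f <- runif(sample(1:8, 1), 0.01, 1)
    v <- pic_dominant(f)
    expect_gte(v, 0); expect_lte(v, 0.5)
    expect_equal(v, pic_dominant(pmin(1, 1 - f + 1e-12)), tolerance = 1e-6)
  }
  expect_error(pic_dominant(numeric(0)), "no band")
  expect_error(pic_dominant(1.2), "fractions")
})

test_that("locus summary rows carry counts, ranges, Ho and PIC", {
  prof <- list(mkprof("solo", "G", list(L1 = c(100L, 104L, 110L))))
  tab <- locus_summary_table(prof, "G")
  expect_equal(tab$allele_number, 3L)
  expect_equal(tab$max_alleles, 3L)
  expect_equal(tab$ho, 1)
  expect_equal(c(tab$size_min, tab$size_max), c(100L, 110L))
  # allele_number equals the distinct simulated alleles actually observed
  set.seed(9)
  rp <- random_profiles(10, n_loci = 3)
  tab2 <- locus_summary_table(rp, "G")
  seen <- lapply(paste0("L", 1:3), function(l)
    unique(unlist(lapply(rp, function(p) p$calls[[l]]))))
  expect_equal(tab2$allele_number, lengths(seen))
})

test_that("set-based classification matches a brute-force oracle", {
  set.seed(5)
  for (rep in 1:10) {
    pa <- random_profiles(8, n_loci = 3, group = "A")
    pb <- random_profiles(8, n_loci = 3, group = "B")
    fa <- allele_frequencies(pa, "A"); fb <- allele_frequencies(pb, "B")
    cls <- classify_alleles(fa, fb, rare_threshold = 10)
    ka <- paste(fa$locus, fa$allele); kb <- paste(fb$locus, fb$allele)
    for (r in seq_len(nrow(cls$table))) {
      k <- paste(cls$table$locus[r], cls$table$allele[r])
      expected <- if (k %in% ka && k %in% kb) "common"
                  else if (k %in% ka) "unique_a" else "unique_b"
      expect_identical(cls$table$category[r], expected)
    }
    expect_equal(sum(cls$counts$n), length(union(ka, kb)))
    expect_equal(sum(cls$counts$pct), 100, tolerance = 0.11)
    # threshold extremes
    expect_false(any(classify_alleles(fa, fb, rare_threshold = 0)$table$rare))
    expect_true(all(classify_alleles(fa, fb, rare_threshold = 100)$table$rare))
  }
  # identical groups: everything common
  pa <- random_profiles(5, n_loci = 2, group = "A")
  fa <- allele_frequencies(pa, "A")
  fb <- fa
  expect_true(all(classify_alleles(fa, fb)$table$category == "common"))
})

test_that("rule-based rare flags on the printed table differ from its bolding where the print is inconsistent", {
  cls <- classify_alleles(load_fixture("table2"))
  tab <- cls$table
  # the p_i <= 10 rule: 9 common-rare and 49 LT-unique-rare (the printed
  # bolding says 8 and 50; one 25% allele is bolded, one 10% allele is not)
  expect_equal(sum(tab$rare & tab$category == "common"), 9L)
  expect_equal(sum(tab$rare & tab$category == "unique_lt"), 49L)
  expect_equal(sum(tab$rare & tab$category == "unique_ref"), 16L)
  disagreements <- tab[tab$rare != tab$printed_rare, ]
  expect_true(all(paste(disagreements$locus, disagreements$allele) %in%
                  c("UDP98-407 179", "PacA33 196", "UDP96-005 127", "UDP96-005 150")))
})

test_that("homozygosity report ranks accessions by single-allele locus count", {
  prof <- list(
    mkprof("Gyne", "LT", list(L1 = 100L, L2 = 102L, L3 = c(100L, 104L))),
    mkprof("Alge", "LT", list(L1 = c(100L, 102L), L2 = c(104L, 106L), L3 = c(100L, 104L))))
  rep <- homozygosity_report(prof, "LT")
  expect_equal(rep$accession, c("Gyne", "Alge"))
  expect_equal(rep$n_homozygous, c(2L, 0L))
  expect_equal(rep$loci, c("L1;L2", ""))
  # complement identity on 9-locus profiles
  set.seed(13)
  rp <- random_profiles(6, n_loci = 9)
  hz <- homozygosity_report(rp, "G")
  for (p in rp) {
    multi <- sum(vapply(p$calls, length, integer(1)) >= 2L)
    expect_equal(hz$n_homozygous[hz$accession == p$accession_id], 9L - multi)
  }
})
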