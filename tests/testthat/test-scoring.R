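test_that("short-variant qualification applies class and rarity rules", {
  expect_true(qualifyShortVariant("exonic_nonsyn", NA))      # unregistered
  expect_true(qualifyShortVariant("exonic_nonsyn", 0.005))
  expect_false(qualifyShortVariant("exonic_syn", 0))         # synonymous
  expect_false(qualifyShortVariant("exonic_nonsyn", 0.02))   # common
  expect_false(qualifyShortVariant("exonic_nonsyn", 0.01))   # boundary
  expect_true(qualifyShortVariant("stopgain", NA))
  expect_true(qualifyShortVariant("frameshift", 0.001))
  expect_false(qualifyShortVariant("intronic", NA))
  expect_false(qualifyShortVariant("splicing", NA))
})

test_that("one point per case, capped within a case", {
  v <- rbind(
    makeVariants(1, case_id = "case01", sample_id = "G1",
                 gene = "TP53", func_class = "exonic_nonsyn"),
    makeVariants(1, case_id = "case03", sample_id = "G3",
                 gene = "TP53", func_class = "stopgain"),
    # three qualifying variants in the same case: still one point
    makeVariants(3, case_id = "case02", sample_id = "G2", pos = 5:7,
                 gene = "KRAS", func_class = "exonic_nonsyn"),
    # non-carcinoma samples never contribute
    makeVariants(1, case_id = "case04", sample_id = "L4", role = "L",
                 gene = "TP53", func_class = "stopgain"))
  pts <- scoreShortVariants(v)
  expect_equal(unname(pts["TP53"]), 2L)
  expect_equal(unname(pts["KRAS"]), 1L)
  # duplicating a qualifying variant does not change points
  pts2 <- scoreShortVariants(rbind(v, v[1, ]))
  expect_identical(pts, pts2)
  expect_length(scoreShortVariants(v[0, ]), 0L)
})

test_that("copy-number qualification follows role plausibility", {
  gene <- data.frame(gene = "ERBB2", chrom = "chr17", start = 100,
                     end = 200)
  gain <- makeEvent(chrom = "chr17", start = 50, end = 500)
  loss <- makeEvent(chrom = "chr17", start = 50, end = 500,
                    event_type = "LOSS")
  none <- makeVariants(0)
  expect_true(qualifyCna(gene, "ONCOGENE", gain, none))
  expect_false(qualifyCna(gene, "ONCOGENE", loss, none))
  expect_true(qualifyCna(gene, "TSG", loss, none))
  expect_false(qualifyCna(gene, "TSG", gain, none))
  expect_true(qualifyCna(gene, "BOTH", gain, none))
  expect_true(qualifyCna(gene, "BOTH", loss, none))
  expect_false(qualifyCna(gene, "UNKNOWN", gain, none))
  # events elsewhere never qualify
  far <- makeEvent(chrom = "chr1", start = 50, end = 500)
  expect_false(qualifyCna(gene, "ONCOGENE", far, none))
})

test_that("CN-LOH is scored only with a loss-of-function variant on the retained haplotype", {
  gene <- data.frame(gene = "STK11", chrom = "chr19", start = 100,
                     end = 200)
  cnloh <- makeEvent(chrom = "chr19", start = 50, end = 500,
                     event_type = "CNLOH", affected_haplotype = 0L)
  lofRetained <- makeVariants(1, chrom = "chr19", pos = 150,
                              gene = "STK11", func_class = "stopgain",
                              phase = 1L)
  lofLost <- makeVariants(1, chrom = "chr19", pos = 150, gene = "STK11",
                          func_class = "stopgain", phase = 0L)
  missense <- makeVariants(1, chrom = "chr19", pos = 150, gene = "STK11",
                           func_class = "exonic_nonsyn", phase = 1L)
  expect_true(qualifyCna(gene, "TSG", cnloh, lofRetained))
  expect_false(qualifyCna(gene, "TSG", cnloh, lofLost))
  # unclear functional consequence: not scored
  expect_false(qualifyCna(gene, "TSG", cnloh, missense))
  expect_false(qualifyCna(gene, "TSG", cnloh, makeVariants(0)))
  # unknown affected haplotype: cannot infer the retained one
  unknown <- cnloh; unknown$affected_haplotype <- NA_integer_
  expect_false(qualifyCna(gene, "TSG", unknown, lofRetained))
  # unphased loss-of-function variant: not scored
  unphased <- lofRetained; unphased$phase <- NA_integer_
  expect_false(qualifyCna(gene, "TSG", cnloh, unphased))
  # UNKNOWN role still allows the CN-LOH arm
  expect_true(qualifyCna(gene, "UNKNOWN", cnloh, lofRetained))
})

test_that("totals add short-variant and copy-number points with ranking", {
  genes <- data.frame(gene = c("A1", "B2"), chrom = "chr1",
                      start = c(100, 5000), end = c(200, 6000),
                      role = c("ONCOGENE", "TSG"))
  v <- rbind(
    makeVariants(1, case_id = "case01", sample_id = "G1", gene = "A1",
                 pos = 150, func_class = "exonic_nonsyn"),
    makeVariants(1, case_id = "case02", sample_id = "G2", gene = "A1",
                 pos = 160, func_class = "exonic_nonsyn"))
  ev <- makeEvent(case_id = "case03", sample_id = "G3", start = 90,
                  end = 300)
  v3 <- makeVariants(1, case_id = "case03", sample_id = "G3",
                     pos = 1e6)  # registers the sample as carcinoma
  res <- scoreCohort(rbind(v, v3), ev, genes)
  a1 <- res$scores[res$scores$gene == "A1", ]
  expect_equal(a1$sv_points, 2L)
  expect_equal(a1$cna_points, 1L)
  expect_equal(a1$total, 3L)
  expect_true("A1" %in% res$candidatesByThreshold[[">=2"]])
  expect_true("A1" %in% res$candidatesByThreshold[[">=3"]])
  expect_false("A1" %in% res$candidatesByThreshold[[">=4"]])
  # empty cohort
  res0 <- scoreCohort(v[0, ], ev[0, ], genes)
  expect_length(res0$candidates, 0L)
})

test_that("candidate sets are nested across thresholds on random cohorts", {
  set.seed(12)
  genes <- data.frame(gene = paste0("G", 1:6), chrom = "chr1",
                      start = (0:5) * 1000 + 1, end = (0:5) * 1000 + 500,
                      role = sample(c("ONCOGENE", "TSG", "BOTH", "UNKNOWN"),
                                    6, replace = TRUE))
  for (rep in 1:200) {
    nv <- sample(5:25, 1)
    v <- makeVariants(nv,
      case_id = sprintf("case%02d", sample(1:5, nv, replace = TRUE)),
      gene = sample(c(genes$gene, NA), nv, replace = TRUE),
      pos = sample(6000, nv),
      func_class = sample(c("exonic_nonsyn", "exonic_syn", "stopgain",
                            "intronic"), nv, replace = TRUE),
      pop_af_eas = sample(c(NA, 0.001, 0.05), nv, replace = TRUE))
    v$sample_id <- paste0("G", substr(v$case_id, 5, 6))
    ne <- sample(0:5, 1)
    ev <- if (ne > 0) do.call(rbind, lapply(seq_len(ne), function(i)
      makeEvent(case_id = sprintf("case%02d", sample(1:5, 1)),
                start = sample(5000, 1), end = sample(5001:9000, 1),
                event_type = sample(EVENT_TYPES <- c("GAIN", "LOSS"), 1))))
      else makeEvent()[0, ]
    if (nrow(ev)) ev$sample_id <- paste0("G", substr(ev$case_id, 5, 6))
    res <- scoreCohort(v, ev, genes)
    sets <- res$candidatesByThreshold
    for (k in seq_len(length(sets) - 1))
      expect_true(all(sets[[k + 1]] %in% sets[[k]]))
  }
})

test_that("removing a case never increases a gene's total", {
  cfg <- tinyConfig(nCases = 3L, driverCasesEach = 3L, seed = 61L)
  coh <- simulateCohort(cfg)
  v <- somaticVariants(cohortVariants(coh))
  s <- cohortSegments(coh)
  ev <- callCnaEvents(s[!grepl("^Nm", s$sample_id), ], 0.4)
  ev <- assignHaplotypes(ev, cohortVariants(coh))
  genes <- geneTable(cfg)
  full <- scoreCohort(v, ev, genes)$scores
  drop <- scoreCohort(v[v$case_id != "case02", ],
                      ev[ev$case_id != "case02", ], genes)$scores
  for (g in drop$gene) {
    tFull <- full$total[full$gene == g]
    expect_lte(drop$total[drop$gene == g],
               if (length(tFull)) tFull else 0L)
  }
})

test_that("planted drivers are recovered exactly at the default threshold", {
  cfg <- simConfig(seed = 31L)
  coh <- simulateCohort(cfg)
  v <- cohortVariants(coh)
  som <- somaticVariants(v)
  s <- cohortSegments(coh)
  nm <- unique(v$sample_id[v$role == "Nm"])
  cut <- deriveCnlohCutoff(lapply(nm, function(x)
    s$minor_allele_fraction[s$sample_id == x]))
  ev <- assignHaplotypes(callCnaEvents(s[!s$sample_id %in% nm, ], cut), v)
  res <- scoreCohort(som, ev, geneTable(cfg))
  truthGenes <- truthLedger(coh[[1]])$genes
  drivers <- truthGenes$gene[truthGenes$driver]
  expect_setequal(res$candidates, drivers)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- paste0("g", 1:40)
  candidates <- paste0("g", 1:10)
  sets <- list(hitSet = paste0("g", 1:8),
               missSet = paste0("g", 30:35),
               partial = paste0("g", c(1:4, 20:23)))
  res <- enrichmentTest(candidates, sets, universe)
  # exact tail by direct combinatorial enumeration
  tailP <- function(k, K, n, N) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
  }
  expect_equal(res$p[res$set == "hitSet"], tailP(8, 8, 10, 40),
               tolerance = 1e-12)
  expect_equal(res$p[res$set == "partial"], tailP(4, 8, 10, 40),
               tolerance = 1e-12)
  # disjoint candidate and set: maximal tail (k = 0)
  expect_equal(res$p[res$set == "missSet"], 1, tolerance = 1e-12)
  expect_equal(res$q, bhAdjust(res$p))
  expect_error(enrichmentTest(candidates, sets, character(0)), "universe")
  expect_error(enrichmentTest("zz", sets, universe), "subset")
})
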