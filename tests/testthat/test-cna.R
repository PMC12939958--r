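test_that("CN-LOH cutoff derivation matches direct arithmetic", {
  # zero-variance case: cutoff equals the common value
  zero <- deriveCnlohCutoff(replicate(7, rep(0.47, 10), simplify = FALSE))
  expect_equal(cutoffValue(zero), 0.47, tolerance = 1e-12)
  p10 <- c(0.48, 0.47, 0.46, 0.47, 0.48, 0.46, 0.47)
  cut <- deriveCnlohCutoff(lapply(p10, function(x) rep(x, 5)))
  expect_equal(cutoffValue(cut), mean(p10) - 3 * sd(p10),
               tolerance = 1e-12)
  expect_equal(unname(cut@perSampleP10), p10)
  # per-sample percentile uses linear interpolation between order stats
  one <- deriveCnlohCutoff(list(a = c(0.40, 0.45, 0.50, 0.35, 0.48),
                                b = c(0.40, 0.45, 0.50, 0.35, 0.48)))
  expect_equal(unname(one@perSampleP10[1]),
               unname(quantile(c(0.40, 0.45, 0.50, 0.35, 0.48), 0.1)),
               tolerance = 1e-12)
})

test_that("cutoff derivation needs at least two normals and is permutation invariant", {
  expect_error(deriveCnlohCutoff(list(a = c(0.4, 0.5))), "at least 2")
  set.seed(2)
  samples <- lapply(1:5, function(i) runif(30, 0.35, 0.5))
  a <- cutoffValue(deriveCnlohCutoff(samples))
  b <- cutoffValue(deriveCnlohCutoff(rev(lapply(samples, sample))))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("event calls follow the rule thresholds exactly", {
  cut <- deriveCnlohCutoff(list(rep(0.44, 5), rep(0.44, 5)))
  seg <- makeSegments(6, start = (0:5) * 1000 + 1, end = (1:6) * 1000,
                      copy_ratio = c(1.2, 0.85, 1.0, 1.0, 1.1, 0.9),
                      minor_allele_fraction = c(0.48, 0.48, 0.30, 0.48,
                                                0.30, 0.30))
  ev <- callCnaEvents(seg, cut)
  byStart <- setNames(ev$event_type, ev$start)
  expect_equal(unname(byStart["1"]), "GAIN")       # ratio 1.2 > 1.1
  expect_equal(unname(byStart["1001"]), "LOSS")    # ratio 0.85 < 0.9
  expect_equal(unname(byStart["2001"]), "CNLOH")   # neutral, MAF 0.30 < 0.44
  expect_false("3001" %in% names(byStart))         # neutral, MAF 0.48
  # boundary semantics: 1.1 and 0.9 sit inside the closed neutral band,
  # and the two adjacent CN-LOH segments merge into one event
  expect_equal(unname(byStart["4001"]), "CNLOH")
  expect_equal(ev$end[ev$start == 4001], 6000)
})

test_that("adjacent same-type events merge into one", {
  cut <- 0.44
  seg <- makeSegments(3, start = c(1, 1001, 3001),
                      end = c(1000, 2000, 4000),
                      copy_ratio = c(1.3, 1.25, 1.4),
                      minor_allele_fraction = 0.48)
  ev <- callCnaEvents(seg, cut)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start, c(1, 3001))
  expect_equal(ev$end, c(2000, 4000))
})

test_that("random segment calls equal the per-segment rule oracle", {
  set.seed(11)
  n <- 500
  seg <- makeSegments(n, chrom = sample(paste0("chr", 1:5), n, TRUE),
                      start = 1, end = 10,
                      copy_ratio = runif(n, 0.5, 1.6),
                      minor_allele_fraction = runif(n, 0.1, 0.5))
  seg$start <- seq_len(n) * 100 + 1; seg$end <- seg$start + 9
  cutVal <- 0.40
  ev <- callCnaEvents(seg, cutVal)
  oracle <- character(n)
  for (i in seq_len(n)) {
    r <- seg$copy_ratio[i]; m <- seg$minor_allele_fraction[i]
    oracle[i] <- if (r > 1.1) "GAIN" else if (r < 0.9) "LOSS" else
      if (m < cutVal) "CNLOH" else NA_character_
  }
  called <- rep(NA_character_, n)
  for (j in seq_len(nrow(ev))) {
    hit <- which(seg$chrom == ev$chrom[j] & seg$start >= ev$start[j] &
                   seg$end <= ev$end[j])
    called[hit] <- ev$event_type[j]
  }
  expect_identical(called, oracle)
})

test_that("raising the gain cutoff never adds gains; CN-LOH never called at or above cutoff", {
  set.seed(3)
  n <- 200
  seg <- makeSegments(n, start = seq_len(n) * 50 + 1,
                      end = seq_len(n) * 50 + 40,
                      copy_ratio = runif(n, 0.7, 1.4),
                      minor_allele_fraction = runif(n, 0.2, 0.5))
  g1 <- callCnaEvents(seg, 0.4, gainCutoff = 1.1)
  g2 <- callCnaEvents(seg, 0.4, gainCutoff = 1.2)
  expect_lte(sum(g2$event_type == "GAIN"), sum(g1$event_type == "GAIN"))
  cn <- g1[g1$event_type == "CNLOH", ]
  for (j in seq_len(nrow(cn))) {
    hit <- seg$chrom == cn$chrom[j] & seg$start >= cn$start[j] &
      seg$end <= cn$end[j]
    expect_true(all(seg$minor_allele_fraction[hit] < 0.4))
  }
  bad <- makeSegments(1, start = 100, end = 10)
  expect_error(callCnaEvents(bad, 0.4), "malformed")
})

test_that("haplotype assignment votes with phased allele fractions", {
  ev <- makeEvent(event_type = "CNLOH", start = 1, end = 1e4)
  v <- makeVariants(10, pos = seq(100, 1000, 100), phase = 0L,
                    alt_reads = 20L)  # VAF 0.2 on haplotype 0
  out <- assignHaplotype(ev, v)
  expect_equal(out$affected_haplotype, 0L)  # haplotype 0 lost
  # gain: elevated fraction marks the gained haplotype
  evG <- makeEvent(event_type = "GAIN", start = 1, end = 1e4)
  vG <- makeVariants(8, pos = seq(100, 800, 100), phase = 1L,
                     alt_reads = 58L)
  expect_equal(assignHaplotype(evG, vG)$affected_haplotype, 1L)
  # no informative variants -> unknown
  expect_true(is.na(assignHaplotype(ev, v[0, ])$affected_haplotype))
  vTie <- makeVariants(2, pos = c(10, 20), phase = c(0L, 1L),
                       alt_reads = 20L)
  expect_true(is.na(assignHaplotype(ev, vTie)$affected_haplotype))
})

test_that("planted haplotypes are recovered from simulated phase, with and without switch errors", {
  for (rate in c(0, 0.1)) {
    cfg <- tinyConfig(nCases = 1L, nGermline = 3000L, nCnaPrivate = 3L,
                      phaseSwitchRate = rate, seed = 77L,
                      nDriverGenes = 0L, nPassengerGenes = 0L)
    cb <- simulateCase(cfg, 1L)
    truth <- truthLedger(cb)$segments
    v <- variants(cb); s <- segments(cb)
    ev <- callCnaEvents(s[!grepl("^Nm", s$sample_id), ], 0.40)
    ev <- assignHaplotypes(ev, v)
    truth$sample_id <- paste0(truth$sample_id, 1L)
    m <- merge(truth, ev, by = c("chrom", "start", "sample_id"),
               suffixes = c(".t", ".c"))
    m <- m[m$event_type.t == m$event_type.c, ]
    ok <- m$affected_haplotype.t == m$affected_haplotype.c
    expect_gte(mean(ok, na.rm = TRUE), if (rate == 0) 0.99 else 0.9)
  }
})

test_that("mutual events require same type and reciprocal overlap", {
  a <- makeEvent(sample_id = "L1", start = 1, end = 1000)
  b <- makeEvent(sample_id = "G1", start = 1, end = 1000)
  expect_equal(nrow(mutualEvents(a, b)), 1L)
  bLoss <- b; bLoss$event_type <- "LOSS"
  expect_equal(nrow(mutualEvents(a, bLoss)), 0L)
  bShift <- b; bShift$start <- 900; bShift$end <- 1900
  expect_equal(nrow(mutualEvents(a, bShift)), 0L)  # ~10% reciprocal
  expect_equal(nrow(mutualEvents(a, bShift, minReciprocalOverlap = 0.05)),
               1L)
  bOther <- b; bOther$case_id <- "case02"
  expect_error(mutualEvents(a, bOther), "same case")
})

test_that("shared trunk events are recovered as mutual between lesions", {
  cfg <- tinyConfig(nCases = 1L, topologyType = "TYPE1", nCnaShared = 2L,
                    seed = 19L, nDriverGenes = 0L, nPassengerGenes = 0L)
  cb <- simulateCase(cfg, 1L)
  s <- segments(cb)
  ev <- callCnaEvents(s[grepl("^(L|G)", s$sample_id), ], 0.40)
  mut <- mutualEvents(ev[ev$sample_id == "L1", ], ev[ev$sample_id == "G1", ])
  truth <- truthLedger(cb)$segments
  shared <- unique(truth[truth$shared, c("chrom", "start", "end")])
  expect_equal(nrow(mut), nrow(shared))
  expect_setequal(paste(mut$chrom, mut$start_a), paste(shared$chrom, shared$start))
})
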