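test_that("same configuration reproduces the cohort byte-for-byte", {
  cfg <- tinyConfig(seed = 7L)
  a <- simulateCase(cfg, 1L)
  b <- simulateCase(cfg, 1L)
  expect_identical(variants(a), variants(b))
  expect_identical(segments(a), segments(b))
  expect_identical(truthLedger(a), truthLedger(b))
  d1 <- tempfile(); d2 <- tempfile()
  writeCohort(list(a), d1, cfg)
  writeCohort(list(b), d2, cfg)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("germline variants appear in every sample including the reference", {
  cb <- simulateCase(tinyConfig(seed = 3L), 1L)
  v <- variants(cb)
  truth <- truthLedger(cb)$variants
  germKeys <- paste(truth$chrom, truth$pos)[truth$branch == "germline"]
  nm <- v[v$role == "Nm", ]
  expect_setequal(paste(nm$chrom, nm$pos), germKeys)
  for (r in c("N", "L", "G"))
    expect_true(all(germKeys %in%
                      paste(v$chrom[v$role == r], v$pos[v$role == r])))
})

test_that("every emitted variant and segment is labeled in the truth ledger", {
  cb <- simulateCase(tinyConfig(seed = 9L), 2L)
  v <- variants(cb)
  truth <- truthLedger(cb)
  vKeys <- unique(paste(v$chrom, v$pos, v$ref, v$alt))
  tKeys <- paste(truth$variants$chrom, truth$variants$pos,
                 truth$variants$ref, truth$variants$alt)
  expect_setequal(vKeys, tKeys)
  expect_false(anyDuplicated(tKeys) > 0)
})

test_that("branch sharing respects the planted topology", {
  for (tt in c("TYPE1", "TYPE2", "TYPE3")) {
    cfg <- tinyConfig(topologyType = tt, seed = 17L,
                      nDriverGenes = 0L, nPassengerGenes = 0L)
    cb <- simulateCase(cfg, 1L)
    som <- somaticVariants(variants(cb))
    key <- paste(som$chrom, som$pos)
    pat <- vapply(split(som$role, key), function(r)
      paste(sort(unique(r)), collapse = "+"), character(1))
    forbidden <- switch(tt, TYPE1 = c("G+N", "L+N"),
                        TYPE2 = c("G+L", "G+N"),
                        TYPE3 = c("G+L", "L+N"))
    expect_false(any(pat %in% forbidden), label = tt)
    expected <- switch(tt, TYPE1 = "G+L", TYPE2 = "L+N", TYPE3 = "G+N")
    expect_gte(sum(pat == expected), cfg@nShared - 2L)
  }
})

test_that("zero planted shift leaves shared VAF expectations equal", {
  cfg <- tinyConfig(topologyType = "TYPE1", vafShift = 0, nShared = 400L,
                    nTrunk = 0L, meanDepth = 4000, seed = 23L,
                    nDriverGenes = 0L, nPassengerGenes = 0L)
  cb <- simulateCase(cfg, 1L)
  som <- somaticVariants(variants(cb))
  sc <- sharedVafComparison(som)
  # high depth: mean difference collapses toward the planted 0
  expect_lt(abs(sc$meanDifference), 0.005)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(meanDepth = 0), "meanDepth")
  expect_error(simConfig(nTrunk = -1L), "negative")
  expect_error(simConfig(topologyType = "TYPE9"), "topologyType")
  expect_error(simConfig(sbs1Weight = 1.2), "\\[0,1\\]")
  expect_error(simulateCase(simConfig(nCases = 2L), 3L), "out of range")
})

test_that("simulated spectra follow the mixture contract", {
  cfg <- tinyConfig(sbs1Weight = 1, seed = 5L)
  sp <- simulateSpectrum(cfg, 1000L)
  expect_equal(sum(sp), 1000)
  ref <- syntheticSignatureMatrix()
  expect_true(all(sp[ref[, "SBS1like"] == 0] == 0))
  expect_identical(simulateSpectrum(cfg, 0L),
                   setNames(numeric(96), contextLabels96()))
  expect_identical(simulateSpectrum(cfg, 500L), simulateSpectrum(cfg, 500L))
})

test_that("segment tables are well-formed and events are carved exactly", {
  cb <- simulateCase(tinyConfig(seed = 31L), 1L)
  s <- segments(cb)
  expect_true(all(s$start <= s$end))
  expect_true(all(s$minor_allele_fraction <= 0.5))
  expect_true(all(s$copy_ratio >= 0))
  # per sample, segments tile each chromosome without overlap
  one <- s[s$sample_id == s$sample_id[1] & s$chrom == "chr1", ]
  one <- one[order(one$start), ]
  expect_true(all(diff(one$start) > 0))
  expect_true(all(utils::head(one$end, -1) + 1 == one$start[-1]))
  # each true event is one emitted segment with matching interval
  truth <- truthLedger(cb)$segments
  for (i in seq_len(nrow(truth))) {
    sid <- paste0(truth$sample_id[i], 1L)
    hit <- s[s$sample_id == sid & s$chrom == truth$chrom[i] &
               s$start == truth$start[i] & s$end == truth$end[i], ]
    expect_equal(nrow(hit), 1L)
  }
})
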