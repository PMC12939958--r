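#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class] with the package's default study
#' conditions: seven 4-sample cases (myometrium `Nm`, normal gland `N`,
#' precursor lesion `L`, carcinoma `G`) on a 22 x 10 Mb artificial
#' diploid genome, Type-1-predominant topologies (the precursor and
#' carcinoma share a branch in five of seven cases), 100x mean depth,
#' lesion purity 0.4 (expected clonal heterozygous VAF 0.2), a +0.06
#' expected VAF shift of shared variants in the carcinoma, a clock-like
#' CpG C>T substitution spectrum at weight 0.7, and five planted driver
#' genes against 200 passenger genes.
#'
#' @param nCases,topologyType,nGermline,nTrunk,nShared,nPrivate see
#'   [SimConfig-class]; `topologyType` is recycled over cases.
#' @param meanDepth,purity,vafShift,nCnaPrivate,nCnaShared,cnlohMaf see
#'   [SimConfig-class].
#' @param sbs1Weight,ratioNoiseSd,mafNoiseWidth,segmentsPerChrom,nChrom,chromLength
#'   see [SimConfig-class].
#' @param phaseSwitchRate,nDriverGenes,driverCasesEach,nPassengerGenes,seed
#'   see [SimConfig-class].
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nCases = 2L, seed = 5L)
#' cfg
#' @export
simConfig <- function(nCases = 7L,
                      topologyType = c("TYPE1", "TYPE1", "TYPE1",
                                       "TYPE2", "TYPE3"),
                      nGermline = 100L,
                      nTrunk = 30L,
                      nShared = 50L,
                      nPrivate = 10L,
                      meanDepth = 100,
                      purity = c(N = 0.4, L = 0.4, G = 0.4),
                      vafShift = 0.06,
                      nCnaPrivate = 2L,
                      nCnaShared = 1L,
                      cnlohMaf = 0.30,
                      sbs1Weight = 0.7,
                      ratioNoiseSd = 0.03,
                      mafNoiseWidth = 0.06,
                      segmentsPerChrom = 4L,
                      nChrom = 22L,
                      chromLength = 1e7,
                      phaseSwitchRate = 0,
                      nDriverGenes = 5L,
                      driverCasesEach = 3L,
                      nPassengerGenes = 200L,
                      seed = 1L) {
  new("SimConfig",
      nCases = as.integer(nCases),
      topologyType = as.character(topologyType),
      nGermline = as.integer(nGermline),
      nTrunk = as.integer(nTrunk),
      nShared = as.integer(nShared),
      nPrivate = as.integer(nPrivate),
      meanDepth = as.numeric(meanDepth),
      purity = purity,
      vafShift = as.numeric(vafShift),
      nCnaPrivate = as.integer(nCnaPrivate),
      nCnaShared = as.integer(nCnaShared),
      cnlohMaf = as.numeric(cnlohMaf),
      sbs1Weight = as.numeric(sbs1Weight),
      ratioNoiseSd = as.numeric(ratioNoiseSd),
      mafNoiseWidth = as.numeric(mafNoiseWidth),
      segmentsPerChrom = as.integer(segmentsPerChrom),
      nChrom = as.integer(nChrom),
      chromLength = as.numeric(chromLength),
      phaseSwitchRate = as.numeric(phaseSwitchRate),
      nDriverGenes = as.integer(nDriverGenes),
      driverCasesEach = as.integer(driverCasesEach),
      nPassengerGenes = as.integer(nPassengerGenes),
      seed = as.integer(seed))
}

# allelic-imbalance levels used for non-CN-LOH events
.LOSS_MAF <- 0.35
.GAIN_MAF <- 0.42

.caseTopologies <- function(config) {
  rep(config@topologyType, length.out = config@nCases)
}

.sharedPair <- function(topology) {
  switch(topology,
         TYPE1 = c("L", "G"),
         TYPE2 = c("N", "L"),
         TYPE3 = c("N", "G"),
         stop("unknown topology: ", topology, call. = FALSE))
}

#' The deterministic synthetic gene model
#'
#' Genes are fixed intervals on the artificial genome (10 genes of
#' 100 kb per chromosome, evenly spaced) with deterministic roles.
#' The first `nDriverGenes` slots (spread over chromosomes) are planted
#' drivers with a mechanism cycling over short-variant recurrence,
#' oncogene gain, tumor-suppressor loss, CN-LOH with a loss-of-function
#' variant on the retained haplotype, and a mixed variant/loss pattern;
#' roles are chosen so each mechanism is biologically plausible under
#' the scoring rules. The next `nPassengerGenes` are passengers, half of
#' which receive one qualifying variant in exactly one case.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns gene, chrom, start, end, role,
#'   driver, mechanism.
#' @export
geneTable <- function(config) {
  nPer <- 10L
  width <- 1e5
  idx <- seq_len(config@nChrom * nPer)
  chrom <- paste0("chr", rep(seq_len(config@nChrom), each = nPer))
  offset <- rep(seq_len(nPer) - 1L, config@nChrom)
  start <- offset * floor(config@chromLength / nPer) + 5e5 + 1
  genes <- data.frame(gene = sprintf("G%03d", idx), chrom = chrom,
                      start = start, end = start + width - 1,
                      stringsAsFactors = FALSE)
  n <- nrow(genes)
  nDrv <- min(config@nDriverGenes, n)
  # spread drivers across chromosomes so planted CNA events rarely collide
  drvIdx <- (seq_len(nDrv) - 1L) * 13L %% n + 1L
  drvIdx <- unique(drvIdx)[seq_len(nDrv)]
  mech <- rep(c("sv", "gain", "loss", "cnloh_lof", "mixed"),
              length.out = nDrv)
  roleFor <- c(sv = "TSG", gain = "ONCOGENE", loss = "TSG",
               cnloh_lof = "TSG", mixed = "BOTH")
  genes$driver <- FALSE
  genes$mechanism <- NA_character_
  genes$role <- rep(c("ONCOGENE", "TSG", "UNKNOWN", "BOTH"),
                    length.out = n)
  genes$driver[drvIdx] <- TRUE
  genes$mechanism[drvIdx] <- mech
  genes$role[drvIdx] <- roleFor[mech]
  rest <- setdiff(seq_len(n), drvIdx)
  nPass <- min(config@nPassengerGenes, length(rest))
  passIdx <- rest[seq_len(nPass)]
  genes$mechanism[passIdx] <- "passenger"
  genes
}

.driverCases <- function(config, d) {
  ((d - 1L) + seq_len(min(config@driverCasesEach, config@nCases)) - 1L) %%
    config@nCases + 1L
}

.passengerCase <- function(config, p) {
  # half the passengers qualify in exactly one case, the rest in none
  slot <- (p - 1L) %% (2L * config@nCases) + 1L
  if (slot <= config@nCases) slot else NA_integer_
}

.segmentGrid <- function(config) {
  w <- floor(config@chromLength / config@segmentsPerChrom)
  starts <- (seq_len(config@segmentsPerChrom) - 1L) * w + 1
  ends <- c(starts[-1L] - 1, config@chromLength)
  data.frame(chrom = paste0("chr", rep(seq_len(config@nChrom),
                                       each = config@segmentsPerChrom)),
             start = rep(starts, config@nChrom),
             end = rep(ends, config@nChrom),
             stringsAsFactors = FALSE)
}

# intergenic windows (one per gene slot) where background copy-number
# events are placed; they never touch a gene body, so only planted
# driver events can generate gene-level copy-number evidence
.gapIntervals <- function(config) {
  nPer <- 10L
  spacing <- floor(config@chromLength / nPer)
  gapStart <- (seq_len(nPer) - 1L) * spacing + 6.2e5 + 1
  gapEnd <- pmin((seq_len(nPer) - 1L) * spacing + 14.8e5,
                 config@chromLength)
  data.frame(chrom = paste0("chr", rep(seq_len(config@nChrom), each = nPer)),
             start = rep(gapStart, config@nChrom),
             end = rep(gapEnd, config@nChrom),
             stringsAsFactors = FALSE)
}

# split the neutral segment grid around a sample's event intervals so
# each event is exactly one segment
.carveSegments <- function(grid, events) {
  if (!nrow(events)) {
    grid$event_type <- NA_character_
    return(grid)
  }
  out <- list()
  for (ch in unique(grid$chrom)) {
    g <- grid[grid$chrom == ch, , drop = FALSE]
    ev <- events[events$chrom == ch, , drop = FALSE]
    if (!nrow(ev)) {
      g$event_type <- NA_character_
      out[[ch]] <- g
      next
    }
    gi <- IRanges::IRanges(g$start, g$end)
    ei <- IRanges::IRanges(ev$start, ev$end)
    neutral <- IRanges::setdiff(gi, ei)
    res <- data.frame(
      chrom = ch,
      start = c(IRanges::start(neutral), ev$start),
      end = c(IRanges::end(neutral), ev$end),
      event_type = c(rep(NA_character_, length(neutral)), ev$event_type),
      stringsAsFactors = FALSE)
    out[[ch]] <- res[order(res$start), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# draw n substitution classes from the SBS1like/flat mixture and emit
# ref, alt and reference-strand trinucleotide context (purine strand
# with probability 1/2, exercising strand normalization downstream)
.drawSnvAlleles <- function(n, weight) {
  ctx <- contextLabels96()
  ref <- syntheticSignatureMatrix()
  p <- weight * ref[, "SBS1like"] + (1 - weight) * ref[, "FLAT"]
  cls <- sample.int(96L, n, replace = TRUE, prob = p)
  lab <- ctx[cls]
  l <- substr(lab, 1, 1); rf <- substr(lab, 3, 3)
  al <- substr(lab, 5, 5); r <- substr(lab, 7, 7)
  tri <- paste0(l, rf, r)
  flip <- runif(n) < 0.5
  out <- data.frame(ref = rf, alt = al, context = tri,
                    stringsAsFactors = FALSE)
  if (any(flip)) {
    out$ref[flip] <- unname(.COMPLEMENT[rf[flip]])
    out$alt[flip] <- unname(.COMPLEMENT[al[flip]])
    out$context[flip] <- .revcomp(tri[flip])
  }
  out
}

.randomPositions <- function(n, config) {
  chrom <- paste0("chr", sample.int(config@nChrom, n, replace = TRUE))
  pos <- sample.int(config@chromLength, n, replace = TRUE)
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    chrom[dup] <- paste0("chr", sample.int(config@nChrom, sum(dup),
                                           replace = TRUE))
    pos[dup] <- sample.int(config@chromLength, sum(dup), replace = TRUE)
    key <- paste(chrom, pos)
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

# expected VAF of one variant row given the events of its sample
.eventAdjustedVaf <- function(baseVaf, phase, isGermHet, events, chrom, pos,
                              config) {
  if (!nrow(events)) return(baseVaf)
  hit <- which(events$chrom == chrom & events$start <= pos &
                 events$end >= pos)
  if (!length(hit)) return(baseVaf)
  ev <- events[hit[1L], ]
  if (!isGermHet || is.na(phase)) return(baseVaf)
  dev <- switch(ev$event_type, CNLOH = config@cnlohMaf,
                LOSS = .LOSS_MAF, GAIN = .GAIN_MAF)
  if (ev$event_type %in% c("CNLOH", "LOSS")) {
    if (phase == ev$haplotype) dev else 1 - dev
  } else {
    if (phase == ev$haplotype) 1 - dev else dev
  }
}

#' Simulate one matched four-sample case
#'
#' Emits the full variant and segment tables of one patient (roles `Nm`,
#' `N`, `L`, `G`) plus a truth ledger. Germline variants appear in all
#' four samples at expected VAF 0.5 (heterozygous, phased) or 1.0
#' (homozygous). Somatic variants are placed on the trunk (all lesions),
#' the topology-defining shared branch (`TYPE1` = L+G, `TYPE2` = N+L,
#' `TYPE3` = N+G) and lesion-private branches; for `TYPE1` cases the
#' shared variants' expected VAF in the carcinoma exceeds the precursor
#' by `vafShift`. Observed alt-read counts are binomial at
#' Poisson-distributed depth. Copy-number events (gain, loss,
#' copy-neutral LOH) are carved into the segment grid — background
#' events inside intergenic windows, planted driver events over the
#' gene body — overwriting copy ratios (Gaussian noise) and minor
#' allele fractions (bounded uniform noise) and skewing the VAFs of
#' overlapping phased heterozygous germline variants according to the
#' affected haplotype.
#' Planted driver and passenger alterations (see [geneTable()]) make
#' scoring recovery well-posed: background somatic variants never meet
#' the driver-scoring qualification rules by construction.
#'
#' @param config a [SimConfig-class].
#' @param caseIndex integer in `1:nCases`.
#' @return a [CaseBundle-class].
#' @examples
#' cb <- simulateCase(simConfig(seed = 3L), 1L)
#' cb
#' @export
simulateCase <- function(config, caseIndex) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  caseIndex <- as.integer(caseIndex)
  if (caseIndex < 1L || caseIndex > config@nCases)
    stop("caseIndex out of range 1..nCases", call. = FALSE)
  set.seed(config@seed + caseIndex * 1000L)
  topology <- .caseTopologies(config)[caseIndex]
  caseIdStr <- sprintf("case%02d", caseIndex)
  genes <- geneTable(config)
  grid <- .segmentGrid(config)

  ## ---- plant copy-number events ------------------------------------
  evRows <- list()
  gaps <- .gapIntervals(config)
  gapOrder <- sample.int(nrow(gaps))
  gapCursor <- 0L
  takeGap <- function() {
    gapCursor <<- gapCursor + 1L
    if (gapCursor > length(gapOrder))
      stop("not enough intergenic windows for the requested events",
           call. = FALSE)
    gaps[gapOrder[gapCursor], ]
  }
  addEvent <- function(samples, type, seg, hap, shared, gene = NA_character_) {
    for (s in samples)
      evRows[[length(evRows) + 1L]] <<- data.frame(
        sample_id = s, chrom = seg$chrom, start = seg$start, end = seg$end,
        event_type = type, haplotype = hap, shared = shared, gene = gene,
        stringsAsFactors = FALSE)
  }
  if (topology == "TYPE1" && config@nCnaShared > 0L) {
    types <- rep(c("GAIN", "LOSS", "CNLOH"),
                 length.out = config@nCnaShared)
    for (k in seq_len(config@nCnaShared))
      addEvent(c("L", "G"), types[k], takeGap(),
               sample(0:1, 1L), TRUE)
  }
  for (s in c("L", "G")) {
    if (config@nCnaPrivate > 0L) {
      types <- rep(c("LOSS", "GAIN", "CNLOH"),
                   length.out = config@nCnaPrivate)
      for (k in seq_len(config@nCnaPrivate))
        addEvent(s, types[k], takeGap(), sample(0:1, 1L), FALSE)
    }
  }

  ## ---- planted driver / passenger alterations ----------------------
  drivers <- genes[genes$driver, , drop = FALSE]
  plantSv <- list()  # gene, func_class, expVaf, phase (NA = random)
  addPlantSv <- function(gene, funcClass, expVaf, phase = NA_integer_) {
    plantSv[[length(plantSv) + 1L]] <<- data.frame(
      gene = gene, func_class = funcClass, expVaf = expVaf,
      phase = phase, stringsAsFactors = FALSE)
  }
  geneSegment <- function(g) {
    genes[genes$gene == g, c("chrom", "start", "end")]
  }
  if (nrow(drivers)) {
    for (d in seq_len(nrow(drivers))) {
      plantedIn <- .driverCases(config, d)
      if (!caseIndex %in% plantedIn) next
      g <- drivers$gene[d]
      occ <- match(caseIndex, plantedIn)
      mech <- drivers$mechanism[d]
      if (mech == "mixed") mech <- if (occ == 1L) "sv" else "loss"
      switch(mech,
        sv = addPlantSv(g, "exonic_nonsyn", config@purity[["G"]] / 2),
        gain = addEvent("G", "GAIN", geneSegment(g), sample(0:1, 1L),
                        FALSE, g),
        loss = addEvent("G", "LOSS", geneSegment(g), sample(0:1, 1L),
                        FALSE, g),
        cnloh_lof = {
          lost <- sample(0:1, 1L)
          addEvent("G", "CNLOH", geneSegment(g), lost, FALSE, g)
          addPlantSv(g, "stopgain", 1 - config@cnlohMaf,
                     phase = 1L - lost)
        })
    }
  }
  passengers <- genes$gene[!genes$driver &
                             !is.na(genes$mechanism) &
                             genes$mechanism == "passenger"]
  for (p in seq_along(passengers)) {
    if (identical(.passengerCase(config, p), caseIndex))
      addPlantSv(passengers[p], "exonic_nonsyn", config@purity[["G"]] / 2)
  }
  events <- if (length(evRows)) do.call(rbind, evRows) else
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric(),
               event_type = character(), haplotype = integer(),
               shared = logical(), gene = character(),
               stringsAsFactors = FALSE)

  ## ---- variant catalog ---------------------------------------------
  pair <- .sharedPair(topology)
  branchDefs <- list(
    germline = c("Nm", "N", "L", "G"),
    trunk = c("N", "L", "G"),
    shared = pair,
    private_N = "N", private_L = "L", private_G = "G")
  nOf <- c(germline = config@nGermline, trunk = config@nTrunk,
           shared = config@nShared, private_N = config@nPrivate,
           private_L = config@nPrivate, private_G = config@nPrivate)
  cat0 <- rep(names(nOf), nOf)
  nBg <- length(cat0)
  nPl <- length(plantSv)
  pos <- .randomPositions(nBg + nPl, config)
  alleles <- .drawSnvAlleles(nBg + nPl, config@sbs1Weight)
  vcat <- data.frame(chrom = pos$chrom, pos = pos$pos,
                     ref = alleles$ref, alt = alleles$alt,
                     context = alleles$context,
                     branch = c(cat0, rep("planted", nPl)),
                     stringsAsFactors = FALSE)
  # germline zygosity and haplotype phase of the alt allele
  isGerm <- vcat$branch == "germline"
  vcat$germHom <- isGerm & runif(nBg + nPl) < 0.2
  vcat$phase <- ifelse(vcat$germHom, NA_integer_,
                       sample(0:1, nBg + nPl, replace = TRUE))
  # gene assignment and background functional classes
  vg <- GenomicRanges::GRanges(vcat$chrom,
                               IRanges::IRanges(vcat$pos, vcat$pos))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  ol <- GenomicRanges::findOverlaps(vg, gg, select = "first")
  vcat$gene <- ifelse(is.na(ol), NA_character_, genes$gene[ol])
  inGene <- !is.na(vcat$gene)
  bgClasses <- c("intronic", "UTR", "exonic_syn", "exonic_nonsyn")
  bgProb <- c(0.72, 0.08, 0.10, 0.10)
  vcat$func_class <- "intergenic"
  vcat$func_class[inGene] <- sample(bgClasses, sum(inGene), replace = TRUE,
                                    prob = bgProb)
  # background exonic nonsynonymous variants are population-frequent so
  # they never meet the rarity rule of the scoring system
  vcat$pop_af_eas <- NA_real_
  vcat$pop_af_eas[vcat$func_class == "exonic_nonsyn"] <- 0.05
  vcat$plantedMech <- NA_character_
  vcat$expVafOverride <- NA_real_
  if (nPl) {
    pl <- do.call(rbind, plantSv)
    idx <- nBg + seq_len(nPl)
    vcat$gene[idx] <- pl$gene
    vcat$func_class[idx] <- pl$func_class
    vcat$pop_af_eas[idx] <- NA_real_
    vcat$expVafOverride[idx] <- pl$expVaf
    vcat$plantedMech[idx] <- "planted"
    vcat$phase[idx] <- ifelse(is.na(pl$phase), vcat$phase[idx], pl$phase)
    # planted variants sit inside their gene's interval
    grow <- genes[match(pl$gene, genes$gene), ]
    vcat$chrom[idx] <- grow$chrom
    vcat$pos[idx] <- grow$start + sample.int(1e5, nPl, replace = TRUE) - 1L
  }

  ## ---- emit per-sample variant rows --------------------------------
  rows <- list()
  for (s in SAMPLE_ROLES) {
    present <- vapply(seq_len(nrow(vcat)), function(i) {
      b <- vcat$branch[i]
      if (b == "planted") s == "G" else s %in% branchDefs[[b]]
    }, logical(1))
    sub <- vcat[present, , drop = FALSE]
    if (!nrow(sub)) next
    sevents <- events[events$sample_id == s, , drop = FALSE]
    expVaf <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      if (sub$branch[i] == "germline") {
        base <- if (sub$germHom[i]) 1 else 0.5
        expVaf[i] <- .eventAdjustedVaf(base, sub$phase[i],
                                       !sub$germHom[i], sevents,
                                       sub$chrom[i], sub$pos[i], config)
      } else if (!is.na(sub$expVafOverride[i])) {
        expVaf[i] <- sub$expVafOverride[i]
      } else {
        base <- config@purity[[s]] / 2
        # every variant mutual to L and G (trunk, and the shared branch
        # of TYPE1 cases) rides higher in the carcinoma by vafShift
        if (s == "G" && (sub$branch[i] == "trunk" ||
                         (sub$branch[i] == "shared" && topology == "TYPE1")))
          base <- base + config@vafShift
        expVaf[i] <- min(1, max(0, base))
      }
    }
    depth <- pmax(1L, rpois(nrow(sub), config@meanDepth))
    altReads <- rbinom(nrow(sub), depth, expVaf)
    phase <- sub$phase
    if (config@phaseSwitchRate > 0) {
      flip <- !is.na(phase) & runif(nrow(sub)) < config@phaseSwitchRate
      phase[flip] <- 1L - phase[flip]
    }
    rows[[s]] <- data.frame(
      case_id = caseIdStr, sample_id = paste0(s, caseIndex), role = s,
      chrom = sub$chrom, pos = sub$pos, ref = sub$ref, alt = sub$alt,
      depth = depth, alt_reads = altReads,
      vaf = round(altReads / depth, 6),
      gene = sub$gene, func_class = sub$func_class,
      pop_af_eas = sub$pop_af_eas, phase = phase,
      context = sub$context,
      mean_base_quality = round(pmin(40, pmax(15, rnorm(nrow(sub), 32, 3))), 1),
      stringsAsFactors = FALSE)
  }
  variantTable <- do.call(rbind, rows)
  rownames(variantTable) <- NULL

  ## ---- emit per-sample segments ------------------------------------
  segRows <- list()
  for (s in SAMPLE_ROLES) {
    sevents <- events[events$sample_id == s, , drop = FALSE]
    seg <- .carveSegments(grid, sevents)
    n <- nrow(seg)
    width <- seg$end - seg$start + 1
    # noise shrinks with segment length (probe averaging); the nominal
    # SD / width apply at the 100 kb reference scale
    ratioSd <- config@ratioNoiseSd * sqrt(pmin(1e5 / width, 25))
    sampleMafWidth <- config@mafNoiseWidth * runif(1, 0.7, 1.5)
    seg$copy_ratio <- 1 + rnorm(n, 0, ratioSd)
    seg$minor_allele_fraction <- 0.5 - runif(n, 0, sampleMafWidth)
    isEv <- !is.na(seg$event_type)
    for (j in which(isEv)) {
      type <- seg$event_type[j]
      if (type == "GAIN") {
        seg$copy_ratio[j] <- runif(1, 1.2, 1.5) +
          rnorm(1, 0, ratioSd[j])
        maf <- .GAIN_MAF
      } else if (type == "LOSS") {
        seg$copy_ratio[j] <- runif(1, 0.6, 0.85) +
          rnorm(1, 0, ratioSd[j])
        maf <- .LOSS_MAF
      } else {
        seg$copy_ratio[j] <- 1 + rnorm(1, 0, ratioSd[j])
        maf <- config@cnlohMaf
      }
      seg$minor_allele_fraction[j] <- pmin(0.5, pmax(0, maf +
        runif(1, -config@mafNoiseWidth / 4, config@mafNoiseWidth / 4)))
    }
    segRows[[s]] <- data.frame(
      case_id = caseIdStr, sample_id = paste0(s, caseIndex),
      chrom = seg$chrom, start = seg$start, end = seg$end,
      copy_ratio = round(pmax(0, seg$copy_ratio), 5),
      minor_allele_fraction = round(seg$minor_allele_fraction, 5),
      n_probes = pmax(10L, as.integer(round(width / 1e4))),
      stringsAsFactors = FALSE)
  }
  segmentTable <- do.call(rbind, segRows)
  rownames(segmentTable) <- NULL

  ## ---- truth ledger ------------------------------------------------
  truthVariants <- data.frame(
    case_id = caseIdStr, chrom = vcat$chrom, pos = vcat$pos,
    ref = vcat$ref, alt = vcat$alt,
    branch = ifelse(vcat$branch == "planted", "private_G", vcat$branch),
    planted = !is.na(vcat$plantedMech),
    gene = vcat$gene, stringsAsFactors = FALSE)
  truthSegments <- cbind(case_id = caseIdStr, events,
                         stringsAsFactors = FALSE)
  names(truthSegments)[names(truthSegments) == "haplotype"] <-
    "affected_haplotype"
  truthGenes <- data.frame(
    case_id = caseIdStr, gene = genes$gene, role = genes$role,
    driver = genes$driver, mechanism = genes$mechanism,
    stringsAsFactors = FALSE)
  new("CaseBundle", caseId = caseIdStr, topology = topology,
      variants = variantTable, segments = segmentTable,
      truth = list(variants = truthVariants, segments = truthSegments,
                   genes = truthGenes))
}

#' Simulate a cohort of matched cases
#'
#' Runs [simulateCase()] for every case of the configuration. The
#' configuration seed fixes the entire cohort byte-for-byte.
#'
#' @param config a [SimConfig-class].
#' @return list of [CaseBundle-class], one per case.
#' @export
simulateCohort <- function(config) {
  lapply(seq_len(config@nCases), function(i) simulateCase(config, i))
}

#' Bind cohort tables across cases
#'
#' @param cohort list of [CaseBundle-class].
#' @return a single data.frame in the corresponding table dialect.
#' @export
cohortVariants <- function(cohort) {
  do.call(rbind, lapply(cohort, variants))
}

#' @rdname cohortVariants
#' @export
cohortSegments <- function(cohort) {
  do.call(rbind, lapply(cohort, segments))
}

#' Write a simulated cohort to a directory
#'
#' Emits `variants.tsv`, `segments.tsv`, `gene_roles.tsv` and the truth
#' ledger (`truth_variants.tsv`, `truth_segments.tsv`,
#' `truth_cases.tsv`, `truth_genes.tsv`).
#'
#' @param cohort list of [CaseBundle-class].
#' @param dir output directory (created if needed).
#' @param config the [SimConfig-class] that produced the cohort.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVariantTable(cohortVariants(cohort), file.path(dir, "variants.tsv"))
  writeSegmentTable(cohortSegments(cohort), file.path(dir, "segments.tsv"))
  genes <- geneTable(config)
  .writeTsv(genes[, c("gene", "chrom", "start", "end", "role")],
            file.path(dir, "gene_roles.tsv"))
  .writeTsv(do.call(rbind, lapply(cohort, function(cb) truthLedger(cb)$variants)),
            file.path(dir, "truth_variants.tsv"))
  .writeTsv(do.call(rbind, lapply(cohort, function(cb) truthLedger(cb)$segments)),
            file.path(dir, "truth_segments.tsv"))
  .writeTsv(data.frame(case_id = vapply(cohort, caseId, character(1)),
                       topology = vapply(cohort, topologyTruth, character(1))),
            file.path(dir, "truth_cases.tsv"))
  .writeTsv(do.call(rbind, lapply(cohort, function(cb) truthLedger(cb)$genes)),
            file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}

#' Simulate a 96-context substitution spectrum
#'
#' Draws `nSnvs` substitutions multinomially from the mixture
#' `sbs1Weight x SBS1like + (1 - sbs1Weight) x flat` over the 96
#' trinucleotide-context classes.
#'
#' @param config a [SimConfig-class] (uses `sbs1Weight` and `seed`).
#' @param nSnvs number of substitutions to draw.
#' @return named numeric vector of 96 counts summing to `nSnvs`.
#' @export
simulateSpectrum <- function(config, nSnvs) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nSnvs <- as.integer(nSnvs)
  if (nSnvs < 0L) stop("nSnvs must be >= 0", call. = FALSE)
  ref <- syntheticSignatureMatrix()
  p <- config@sbs1Weight * ref[, "SBS1like"] +
    (1 - config@sbs1Weight) * ref[, "FLAT"]
  counts <- stats::setNames(numeric(96L), contextLabels96())
  if (nSnvs == 0L) return(counts)
  set.seed(config@seed + 777L)
  counts[] <- as.numeric(rmultinom(1L, nSnvs, p))
  counts
}
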