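#' @import methods
#' @importFrom stats quantile sd rbinom rpois rnorm runif rmultinom
#'   kruskal.test wilcox.test p.adjust phyper setNames
NULL

SAMPLE_ROLES <- c("Nm", "N", "L", "G")
TOPOLOGY_TYPES <- c("TYPE1", "TYPE2", "TYPE3")
FUNC_CLASSES <- c("exonic_nonsyn", "exonic_syn", "stopgain", "frameshift",
                  "nonframeshift", "splicing", "intronic", "intergenic", "UTR")
EXONIC_CLASSES <- c("exonic_nonsyn", "exonic_syn", "stopgain", "frameshift",
                    "nonframeshift")
LOF_CLASSES <- c("stopgain", "frameshift", "splicing")
GENE_ROLES <- c("ONCOGENE", "TSG", "BOTH", "UNKNOWN")
EVENT_TYPES <- c("GAIN", "LOSS", "CNLOH")

#' Simulation configuration for matched-lesion cohorts
#'
#' Holds every knob of the clonal-evolution simulator: cohort size, the
#' planted branching topology of each case, branch mutation counts, read
#' depth and lesion purity (which set the expected variant allele
#' fractions), copy-number event counts and their allelic-imbalance
#' levels, the single-base-substitution spectrum mixture weight, and the
#' master seed. The defaults describe a desk-scale cohort: seven cases of
#' four microdissected samples each (myometrium reference `Nm`, normal
#' gland `N`, precursor lesion `L`, carcinoma `G`) on an artificial
#' diploid genome of 22 chromosomes x 10 Mb.
#'
#' @slot nCases integer, number of matched cases.
#' @slot topologyType character, planted branching pattern per case
#'   (`TYPE1` = L and G share a branch; `TYPE2` = N and L; `TYPE3` = N
#'   and G). Recycled across cases.
#' @slot nGermline integer, germline variants per case (present in all
#'   four samples).
#' @slot nTrunk,nShared,nPrivate integers, somatic variants on the trunk
#'   (all lesions), the topology-defining shared branch, and each
#'   lesion-private branch.
#' @slot meanDepth numeric, mean sequencing depth (reads); per-site depth
#'   is Poisson.
#' @slot purity named numeric, tumor-cell fraction per lesion role
#'   (`N`, `L`, `G`); expected heterozygous clonal VAF is purity / 2.
#' @slot vafShift numeric, additive expected VAF increment of shared
#'   variants in G relative to L (TYPE1 cases).
#' @slot nCnaPrivate integer, private copy-number events per lesion (L
#'   and G; normal glands carry none).
#' @slot nCnaShared integer, copy-number events shared by L and G
#'   (planted for TYPE1 cases only).
#' @slot cnlohMaf numeric, expected minor allele fraction inside
#'   copy-neutral LOH segments.
#' @slot sbs1Weight numeric in \[0,1\], fraction of SNVs drawn from the
#'   clock-like CpG C>T profile (remainder flat over 96 contexts).
#' @slot ratioNoiseSd numeric, Gaussian noise SD on segment copy ratios.
#' @slot mafNoiseWidth numeric, width of the uniform downward noise on
#'   neutral minor allele fractions (neutral MAF = 0.5 minus
#'   U(0, width); bounded, so the normal-derived CN-LOH cutoff sits
#'   below essentially all neutral segments).
#' @slot segmentsPerChrom,nChrom integers and @slot chromLength numeric:
#'   the segment grid and artificial genome geometry.
#' @slot phaseSwitchRate numeric, probability that an emitted haplotype
#'   phase label is flipped (emulating phasing switch errors).
#' @slot nDriverGenes,driverCasesEach,nPassengerGenes integers, planted
#'   candidate-driver structure used by the scoring-recovery analyses.
#' @slot seed integer master seed; fixes all output byte-for-byte.
#'
#' @seealso [simulateCase()], [simulateCohort()]
#' @export
setClass("SimConfig", representation(
  nCases = "integer",
  topologyType = "character",
  nGermline = "integer",
  nTrunk = "integer",
  nShared = "integer",
  nPrivate = "integer",
  meanDepth = "numeric",
  purity = "numeric",
  vafShift = "numeric",
  nCnaPrivate = "integer",
  nCnaShared = "integer",
  cnlohMaf = "numeric",
  sbs1Weight = "numeric",
  ratioNoiseSd = "numeric",
  mafNoiseWidth = "numeric",
  segmentsPerChrom = "integer",
  nChrom = "integer",
  chromLength = "numeric",
  phaseSwitchRate = "numeric",
  nDriverGenes = "integer",
  driverCasesEach = "integer",
  nPassengerGenes = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(nCases = object@nCases, nGermline = object@nGermline,
              nTrunk = object@nTrunk, nShared = object@nShared,
              nPrivate = object@nPrivate, nCnaPrivate = object@nCnaPrivate,
              nCnaShared = object@nCnaShared,
              nDriverGenes = object@nDriverGenes,
              nPassengerGenes = object@nPassengerGenes)
  if (any(counts < 0L))
    msg <- c(msg, paste0("negative count: ",
                         paste(names(counts)[counts < 0L], collapse = ", ")))
  if (object@nCases < 1L) msg <- c(msg, "nCases must be >= 1")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  fr <- c(object@purity, object@vafShift, object@cnlohMaf, object@sbs1Weight,
          object@phaseSwitchRate)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "purity, vafShift, cnlohMaf, sbs1Weight, phaseSwitchRate must lie in [0,1]")
  if (!all(object@topologyType %in% TOPOLOGY_TYPES))
    msg <- c(msg, paste0("topologyType must be one of ",
                         paste(TOPOLOGY_TYPES, collapse = "/")))
  if (!all(c("N", "L", "G") %in% names(object@purity)))
    msg <- c(msg, "purity must be named with N, L, G")
  if (is.na(object@seed) || abs(object@seed) >= 2^31 - 2e6)
    msg <- c(msg, "seed must be a 32-bit integer")
  if (length(msg)) msg else TRUE
})

#' One simulated matched case with its truth ledger
#'
#' Container for the four-sample bundle of a single simulated patient:
#' the per-sample variant table, the per-sample segment table, and the
#' truth ledger recording what was planted (branch label of every
#' variant, true type and affected haplotype of every copy-number
#' segment, planted-driver flags, and the case topology).
#'
#' @slot caseId character scalar.
#' @slot topology planted topology type.
#' @slot variants data.frame in the package variant-table dialect (see
#'   [readVariantTable()]).
#' @slot segments data.frame in the segment-table dialect.
#' @slot truth named list of data.frames: `variants` (branch labels),
#'   `segments` (true events), `genes` (driver flags and mechanisms).
#' @seealso [simulateCase()]
#' @export
setClass("CaseBundle", representation(
  caseId = "character",
  topology = "character",
  variants = "data.frame",
  segments = "data.frame",
  truth = "list"
))

setValidity("CaseBundle", function(object) {
  msg <- character()
  if (length(object@caseId) != 1L) msg <- c(msg, "caseId must be scalar")
  if (!object@topology %in% TOPOLOGY_TYPES)
    msg <- c(msg, "unknown topology")
  need <- c("variants", "segments", "genes")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, "truth ledger must contain variants, segments, genes")
  if (length(msg)) msg else TRUE
})

#' Copy-neutral LOH minor-allele-fraction cutoff
#'
#' The decision threshold below which a copy-neutral segment's minor
#' allele fraction is considered deviated (allelic imbalance without
#' total copy change). Derived from normal reference samples as the mean
#' minus three standard deviations of the per-sample 10th percentiles of
#' their minor allele fractions.
#'
#' @slot value numeric threshold in \[0, 0.5\].
#' @slot nNormals integer, normal samples used.
#' @slot perSampleP10 named numeric, the per-sample 10th percentiles.
#' @seealso [deriveCnlohCutoff()]
#' @export
setClass("CnlohCutoff", representation(
  value = "numeric",
  nNormals = "integer",
  perSampleP10 = "numeric"
))

setValidity("CnlohCutoff", function(object) {
  msg <- character()
  if (length(object@value) != 1L || object@value < 0 || object@value > 0.5)
    msg <- c(msg, "cutoff value must lie in [0, 0.5]")
  if (object@nNormals < 2L) msg <- c(msg, "at least 2 normal samples required")
  if (length(object@perSampleP10) != object@nNormals)
    msg <- c(msg, "perSampleP10 length must equal nNormals")
  if (length(msg)) msg else TRUE
})

#' Binary character matrix for lesion phylogenetics
#'
#' Presence/absence matrix of somatic variants (or copy-number events)
#' across the samples of one case. Rows are taxa (sample roles), columns
#' are characters. The myometrium reference `Nm` is the all-absent
#' outgroup after germline subtraction.
#'
#' @slot taxa character, ordered sample labels.
#' @slot mat integer 0/1 matrix, taxa x characters.
#' @slot characterIds character, one id per column (variant keys or
#'   event labels).
#' @slot informative logical per character: TRUE when the character is
#'   parsimony-relevant (neither all-absent nor all-present across taxa).
#' @seealso [buildCharacterMatrix()], [parsimonyTree()]
#' @export
setClass("BinaryCharacterMatrix", representation(
  taxa = "character",
  mat = "matrix",
  characterIds = "character",
  informative = "logical"
))

setValidity("BinaryCharacterMatrix", function(object) {
  msg <- character()
  if (nrow(object@mat) != length(object@taxa))
    msg <- c(msg, "matrix rows must match taxa")
  if (ncol(object@mat) != length(object@characterIds))
    msg <- c(msg, "matrix columns must match characterIds")
  if (length(object@informative) != ncol(object@mat))
    msg <- c(msg, "informative flag must match characters")
  if (ncol(object@mat) && !all(object@mat %in% c(0L, 1L)))
    msg <- c(msg, "matrix entries must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Parsimony tree over the lesion samples of one case
#'
#' Result of the exhaustive maximum-parsimony search: the (or a)
#' minimum-score unrooted topology, rooted at the myometrium reference
#' for display, with per-branch character-change counts and the total
#' parsimony score. When several topologies tie at the minimum the tie
#' is recorded and topology classification reports `UNRESOLVED`.
#'
#' @slot tree an [ape::phylo] rooted at `Nm` (or a tip taxon) or NULL-like
#'   empty list when no characters were available.
#' @slot taxa character, tip labels.
#' @slot score numeric, total parsimony score (minimum changes).
#' @slot branchCounts named numeric, characters assigned to each branch;
#'   names are the tip sets below the branch (e.g. `"L+G"`).
#' @slot nTied integer, number of topologies attaining the minimum score.
#' @slot tiedSplits character, the defining splits of all tied topologies.
#' @slot nCharacters integer, characters scored.
#' @seealso [parsimonyTree()], [classifyTopology()]
#' @export
setClass("LesionTree", representation(
  tree = "ANY",
  taxa = "character",
  score = "numeric",
  branchCounts = "numeric",
  nTied = "integer",
  tiedSplits = "character",
  nCharacters = "integer"
))

#' Signature refitting result
#'
#' Non-negative least squares exposures of a 96-context substitution
#' spectrum against a reference signature matrix, with proportions and
#' the L2 reconstruction residual.
#'
#' @slot exposures named non-negative numeric, one per reference
#'   signature (counts attributed).
#' @slot proportions named numeric summing to 1 (all-NA when the
#'   spectrum was empty).
#' @slot residual numeric, L2 norm of spectrum minus reconstruction.
#' @slot degenerate logical, TRUE for an all-zero input spectrum.
#' @seealso [fitExposures()]
#' @export
setClass("SignatureExposure", representation(
  exposures = "numeric",
  proportions = "numeric",
  residual = "numeric",
  degenerate = "logical"
))

setValidity("SignatureExposure", function(object) {
  msg <- character()
  if (any(object@exposures < -1e-9)) msg <- c(msg, "exposures must be >= 0")
  if (!object@degenerate &&
      abs(sum(object@proportions) - 1) > 1e-6)
    msg <- c(msg, "proportions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Two-sample / k-sample rank test result
#'
#' Uniform container for the rank-based tests used across the package:
#' the statistic, two-sided p-value, method label, and per-group
#' summaries (n, mean, mean rank in the pooled ranking).
#'
#' @slot statistic numeric.
#' @slot pValue numeric in \[0,1\].
#' @slot method character label.
#' @slot groupSummaries data.frame with columns `group`, `n`, `mean`,
#'   `meanRank`.
#' @seealso [kruskalWallis()], [wilcoxonRankSum()]
#' @export
setClass("TestResult", representation(
  statistic = "numeric",
  pValue = "numeric",
  method = "character",
  groupSummaries = "data.frame"
))

setValidity("TestResult", function(object) {
  if (is.na(object@pValue) || object@pValue < 0 || object@pValue > 1 + 1e-12)
    "pValue must lie in [0,1]" else TRUE
})
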