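#' The 96 trinucleotide-context substitution classes
#'
#' Labels in the conventional alphabetical layout: six pyrimidine-strand
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each crossed
#' with the 16 flanking-base combinations, written like `A[C>A]A`.
#'
#' @return character vector of length 96.
#' @export
contextLabels96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", s, "]", r))))))
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(.COMPLEMENT[b])), collapse = ""), character(1))
}

#' Synthetic mini-reference of substitution signatures
#'
#' A deterministic 96 x 5 reference matrix used by the simulator and the
#' default refitting: a clock-like CpG C>T profile (`SBS1like`), two
#' APOBEC-style profiles on the TpC motif (`SBS2like` C>T, `SBS13like`
#' C>G), a broad low-contrast profile (`SBS5like`), and a flat
#' background (`FLAT`). These are synthetic stand-ins constructed to
#' have the defining peaks of the correspondingly named catalog
#' signatures; they are not the catalog profiles. Users can supply a
#' real reference via [readSignatureMatrix()].
#'
#' @return numeric 96 x 5 matrix, columns summing to 1, context labels
#'   as rownames.
#' @export
syntheticSignatureMatrix <- function() {
  ctx <- contextLabels96()
  n <- length(ctx)
  peak <- function(labels, mass) {
    p <- rep((1 - mass) / (n - length(labels)), n)
    names(p) <- ctx
    p[labels] <- mass / length(labels)
    p
  }
  cpg <- paste0(c("A", "C", "G", "T"), "[C>T]G")
  tcw_ct <- c("T[C>T]A", "T[C>T]T")
  tcw_cg <- c("T[C>G]A", "T[C>G]T")
  sbs1 <- peak(cpg, 0.94)
  sbs2 <- peak(tcw_ct, 0.88)
  sbs13 <- peak(tcw_cg, 0.88)
  w5 <- rep(1, n)
  names(w5) <- ctx
  w5[grepl("T>C", ctx)] <- 3
  w5[grepl("C>T", ctx)] <- 2
  sbs5 <- w5 / sum(w5)
  flat <- rep(1 / n, n)
  mat <- cbind(SBS1like = sbs1, SBS2like = sbs2, SBS5like = sbs5,
               SBS13like = sbs13, FLAT = flat)
  rownames(mat) <- ctx
  mat
}

#' Build a 96-context spectrum from SNVs
#'
#' Maps each single-nucleotide variant to one of the 96 substitution
#' classes after pyrimidine-strand normalization: when the reference
#' base is a purine, the reference, alternate and flanking context are
#' reverse-complemented, so e.g. an `A[G>T]C` site counts toward
#' `G[C>A]T`. Context comes from the table's `context` column (the
#' trinucleotide on the reference strand with the reference base in the
#' middle), emitted by the simulator or an annotation step.
#'
#' @param snvs variant data.frame restricted to SNVs (single-base ref
#'   and alt); a `context` column is required.
#' @return named numeric vector of length 96 summing to `nrow(snvs)`.
#' @examples
#' snv <- data.frame(ref = "G", alt = "T", context = "AGC")
#' sp <- buildSpectrum(snv)
#' sp["G[C>A]T"]  # 1
#' @export
buildSpectrum <- function(snvs) {
  ctx <- contextLabels96()
  counts <- stats::setNames(numeric(length(ctx)), ctx)
  if (!nrow(snvs)) return(counts)
  if (!"context" %in% names(snvs))
    stop("buildSpectrum requires a 'context' column", call. = FALSE)
  if (any(nchar(snvs$ref) != 1L | nchar(snvs$alt) != 1L))
    stop("buildSpectrum accepts SNVs only (single-base ref and alt)",
         call. = FALSE)
  if (any(nchar(snvs$context) != 3L | is.na(snvs$context)))
    stop("context must be a 3-base string for every SNV", call. = FALSE)
  ref <- snvs$ref; alt <- snvs$alt; tri <- snvs$context
  if (any(substr(tri, 2, 2) != ref))
    stop("context middle base must equal the reference allele",
         call. = FALSE)
  bad <- !grepl("^[ACGT]{3}$", tri)
  if (any(bad))
    stop("unknown context base in: ", paste(utils::head(tri[bad], 3),
                                            collapse = ", "), call. = FALSE)
  purine <- ref %in% c("A", "G")
  ref[purine] <- unname(.COMPLEMENT[snvs$ref[purine]])
  alt[purine] <- unname(.COMPLEMENT[snvs$alt[purine]])
  tri[purine] <- .revcomp(snvs$context[purine])
  lab <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                substr(tri, 3, 3))
  tab <- table(factor(lab, levels = ctx))
  counts[] <- as.numeric(tab)
  counts
}

#' Refit a spectrum against reference signatures
#'
#' Solves the non-negative least squares problem
#' min || spectrum - reference e ||_2 subject to e >= 0 and reports
#' exposures, proportions and the L2 residual. An all-zero spectrum is
#' flagged degenerate (proportions undefined).
#'
#' @param spectrum numeric vector of 96 context counts (as from
#'   [buildSpectrum()]).
#' @param reference 96 x K matrix with columns summing to 1 (default the
#'   packaged synthetic mini-reference).
#' @return a [SignatureExposure-class].
#' @examples
#' ref <- syntheticSignatureMatrix()
#' sp <- 1000 * ref[, "SBS1like"]
#' signatureProportions(fitExposures(sp, ref))["SBS1like"]  # 1
#' @export
fitExposures <- function(spectrum, reference = syntheticSignatureMatrix()) {
  if (is.null(dim(reference)) || ncol(reference) == 0L)
    stop("reference must have at least one signature column", call. = FALSE)
  if (length(spectrum) != nrow(reference))
    stop("spectrum length must match reference rows", call. = FALSE)
  if (any(abs(colSums(reference) - 1) > 1e-6))
    stop("reference columns must each sum to 1", call. = FALSE)
  sig <- colnames(reference)
  if (is.null(sig)) sig <- paste0("S", seq_len(ncol(reference)))
  if (sum(spectrum) == 0) {
    return(new("SignatureExposure",
               exposures = stats::setNames(numeric(length(sig)), sig),
               proportions = stats::setNames(rep(NA_real_, length(sig)), sig),
               residual = 0, degenerate = TRUE))
  }
  fit <- pracma::lsqnonneg(unname(reference), as.numeric(spectrum))
  e <- pmax(fit$x, 0)
  names(e) <- sig
  new("SignatureExposure",
      exposures = e,
      proportions = e / sum(e),
      residual = sqrt(sum((as.numeric(spectrum) -
                             unname(reference) %*% fit$x)^2)),
      degenerate = FALSE)
}
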