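#' Accessors for lesionevo S4 objects
#'
#' Small accessor generics so downstream code never touches slots
#' directly: `caseId()`, `topologyTruth()`, `variants()`, `segments()`,
#' `truthLedger()` for [CaseBundle-class]; `cutoffValue()` for
#' [CnlohCutoff-class]; `exposures()`, `signatureProportions()` for
#' [SignatureExposure-class]; `parsimonyScore()`, `branchCounts()` for
#' [LesionTree-class]; `pValue()` for [TestResult-class].
#'
#' @param x an S4 object from this package.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("topologyTruth", function(x) standardGeneric("topologyTruth"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("truthLedger", function(x) standardGeneric("truthLedger"))
#' @rdname accessors
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))
#' @rdname accessors
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))
#' @rdname accessors
#' @export
setGeneric("signatureProportions",
           function(x) standardGeneric("signatureProportions"))
#' @rdname accessors
#' @export
setGeneric("parsimonyScore", function(x) standardGeneric("parsimonyScore"))
#' @rdname accessors
#' @export
setGeneric("branchCounts", function(x) standardGeneric("branchCounts"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
setMethod("caseId", "CaseBundle", function(x) x@caseId)
#' @rdname accessors
setMethod("topologyTruth", "CaseBundle", function(x) x@topology)
#' @rdname accessors
setMethod("variants", "CaseBundle", function(x) x@variants)
#' @rdname accessors
setMethod("segments", "CaseBundle", function(x) x@segments)
#' @rdname accessors
setMethod("truthLedger", "CaseBundle", function(x) x@truth)
#' @rdname accessors
setMethod("cutoffValue", "CnlohCutoff", function(x) x@value)
#' @rdname accessors
setMethod("exposures", "SignatureExposure", function(x) x@exposures)
#' @rdname accessors
setMethod("signatureProportions", "SignatureExposure",
          function(x) x@proportions)
#' @rdname accessors
setMethod("parsimonyScore", "LesionTree", function(x) x@score)
#' @rdname accessors
setMethod("branchCounts", "LesionTree", function(x) x@branchCounts)
#' @rdname accessors
setMethod("pValue", "TestResult", function(x) x@pValue)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nCases, "case(s), topology",
      paste(unique(object@topologyType), collapse = "/"), "\n")
  cat("  branch variants: trunk", object@nTrunk, "/ shared", object@nShared,
      "/ private", object@nPrivate, "; germline", object@nGermline, "\n")
  cat("  depth", object@meanDepth, "| purity",
      paste(sprintf("%s=%.2f", names(object@purity), object@purity),
            collapse = " "),
      "| vafShift", object@vafShift, "\n")
  cat("  CNA: private", object@nCnaPrivate, "shared", object@nCnaShared,
      "| CN-LOH MAF", object@cnlohMaf, "| seed", object@seed, "\n")
})

setMethod("show", "CaseBundle", function(object) {
  cat("CaseBundle", object@caseId, "(", object@topology, "):",
      nrow(object@variants), "variant rows,",
      nrow(object@segments), "segments,",
      length(unique(object@variants$sample_id)), "samples\n")
})

setMethod("show", "CnlohCutoff", function(object) {
  cat(sprintf("CnlohCutoff: %.4f (mean - 3 SD of %d per-normal p10 values)\n",
              object@value, object@nNormals))
})

setMethod("show", "BinaryCharacterMatrix", function(object) {
  cat("BinaryCharacterMatrix:", length(object@taxa), "taxa x",
      ncol(object@mat), "characters (",
      sum(object@informative), "informative )\n")
})

setMethod("show", "LesionTree", function(object) {
  if (object@nCharacters == 0L) {
    cat("LesionTree: empty (no characters)\n")
    return(invisible(NULL))
  }
  cat("LesionTree over {", paste(object@taxa, collapse = ","),
      "}: score", object@score, "on", object@nCharacters, "characters")
  if (object@nTied > 1L) cat(" [", object@nTied, "tied topologies ]")
  cat("\n  branch counts:",
      paste(sprintf("%s=%d", names(object@branchCounts),
                    as.integer(object@branchCounts)), collapse = " "), "\n")
})

setMethod("show", "SignatureExposure", function(object) {
  if (object@degenerate) {
    cat("SignatureExposure: degenerate (empty spectrum)\n")
    return(invisible(NULL))
  }
  cat("SignatureExposure (residual", format(object@residual, digits = 4), "):\n")
  print(round(object@proportions, 4))
})

setMethod("show", "TestResult", function(object) {
  cat(object@method, ": statistic =", format(object@statistic, digits = 5),
      ", p =", format(object@pValue, digits = 4), "\n")
  print(object@groupSummaries, row.names = FALSE)
})
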