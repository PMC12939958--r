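VARIANT_COLUMNS <- c("case_id", "sample_id", "role", "chrom", "pos", "ref",
                     "alt", "depth", "alt_reads", "vaf", "gene", "func_class",
                     "pop_af_eas", "phase")
SEGMENT_COLUMNS <- c("case_id", "sample_id", "chrom", "start", "end",
                     "copy_ratio", "minor_allele_fraction", "n_probes")
EVENT_COLUMNS <- c("case_id", "sample_id", "chrom", "start", "end",
                   "event_type", "affected_haplotype")

.checkColumns <- function(df, required, what, file = NULL) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s%s is missing required column(s): %s", what,
                 if (is.null(file)) "" else paste0(" '", file, "'"),
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.validateVariants <- function(df, strict = TRUE, file = NULL) {
  .checkColumns(df, VARIANT_COLUMNS, "variant table", file)
  if (!nrow(df)) return(df)
  bad <- which(df$alt_reads > df$depth | df$pos < 1 |
                 df$vaf < 0 | df$vaf > 1)
  if (length(bad) && strict)
    stop(sprintf("variant table: malformed row(s) %s (alt_reads > depth, pos < 1 or vaf outside [0,1])",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  unknown <- setdiff(unique(df$func_class), c(FUNC_CLASSES, NA))
  if (length(unknown))
    stop(sprintf("variant table: unknown func_class value(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  df
}

.validateSegments <- function(df, strict = TRUE, file = NULL) {
  .checkColumns(df, SEGMENT_COLUMNS, "segment table", file)
  if (!nrow(df)) return(df)
  bad <- which(df$start > df$end | df$copy_ratio < 0 |
                 df$minor_allele_fraction > 0.5 + 1e-9 |
                 df$minor_allele_fraction < 0)
  if (length(bad) && strict)
    stop(sprintf("segment table: malformed row(s) %s (start > end, negative ratio or MAF outside [0,0.5])",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  df
}

#' Read and write the package's tab-separated tables
#'
#' All interchange is plain TSV with a header row. Coordinates are
#' 1-based inclusive both in files and in memory (the IRanges
#' convention), so a round trip preserves every consumed field exactly.
#' Variant tables carry one row per variant per sample; segment tables
#' one row per genomic segment per sample; event tables one called
#' copy-number event per row.
#'
#' @param path file path.
#' @param df a data.frame in the corresponding dialect.
#' @param strict logical; when TRUE (default) malformed rows abort with
#'   their row numbers, when FALSE they are kept for inspection.
#' @return `read*` return a validated data.frame; `write*` return the
#'   path invisibly.
#' @examples
#' cfg <- simConfig(nCases = 1L, seed = 11L)
#' cb <- simulateCase(cfg, 1L)
#' f <- tempfile(fileext = ".tsv")
#' writeVariantTable(variants(cb), f)
#' identical(dim(readVariantTable(f)), dim(variants(cb)))
#' @name table-io
NULL

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

.writeTsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname table-io
#' @export
readVariantTable <- function(path, strict = TRUE) {
  df <- .readTsv(path)
  df$chrom <- as.character(df$chrom)
  .validateVariants(df, strict = strict, file = path)
}

#' @rdname table-io
#' @export
writeVariantTable <- function(df, path) {
  .validateVariants(df)
  .writeTsv(df, path)
}

#' @rdname table-io
#' @export
readSegmentTable <- function(path, strict = TRUE) {
  df <- .readTsv(path)
  df$chrom <- as.character(df$chrom)
  .validateSegments(df, strict = strict, file = path)
}

#' @rdname table-io
#' @export
writeSegmentTable <- function(df, path) {
  .validateSegments(df)
  .writeTsv(df, path)
}

#' @rdname table-io
#' @export
readEventTable <- function(path) {
  df <- .readTsv(path)
  .checkColumns(df, EVENT_COLUMNS, "event table", path)
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname table-io
#' @export
writeEventTable <- function(df, path) {
  .checkColumns(df, EVENT_COLUMNS, "event table")
  .writeTsv(df, path)
}

#' Convert segment or event tables to GRanges
#'
#' Interval work (event merging, reciprocal overlap, gene-event overlap)
#' runs on [GenomicRanges::GRanges]; tables are converted at the module
#' boundary. Coordinates are 1-based inclusive on both sides, so no
#' shifting occurs.
#'
#' @param df a segment- or event-dialect data.frame.
#' @return a `GRanges` with the non-coordinate columns as metadata.
#' @export
segmentsAsGRanges <- function(df) {
  if (!nrow(df)) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  meta <- df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  gr
}

#' Read a gene-role table (Cancer Gene Census style)
#'
#' Two-column TSV `gene`, `role` with roles ONCOGENE / TSG / BOTH /
#' UNKNOWN. A loader shim maps the CGC export's "Role in Cancer" column
#' ("oncogene", "TSG", "oncogene, TSG") onto these levels when present.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene`, `role`.
#' @export
readGeneRoles <- function(path) {
  df <- .readTsv(path)
  if (!"role" %in% names(df) && "Role.in.Cancer" %in% names(df)) {
    rc <- tolower(df$Role.in.Cancer)
    df$role <- ifelse(grepl("oncogene", rc) & grepl("tsg", rc), "BOTH",
               ifelse(grepl("oncogene", rc), "ONCOGENE",
               ifelse(grepl("tsg", rc), "TSG", "UNKNOWN")))
    if (!"gene" %in% names(df) && "Gene.Symbol" %in% names(df))
      df$gene <- df$Gene.Symbol
  }
  .checkColumns(df, c("gene", "role"), "gene-role table", path)
  bad <- setdiff(unique(df$role), GENE_ROLES)
  if (length(bad))
    stop("unknown gene role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$gene))
    stop("gene-role table has duplicated gene symbols", call. = FALSE)
  df[, c("gene", "role")]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 60), call. = FALSE)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Read or write a 96-context signature reference matrix
#'
#' TSV with a `context` column of labels like `A[C>A]A` (96 rows in the
#' conventional alphabetical layout) and one column per signature. On
#' read, columns are renormalized checkpointed: each signature must sum
#' to 1 within 1e-6.
#'
#' @param path TSV path.
#' @param mat numeric 96 x K matrix with context rownames.
#' @return `readSignatureMatrix` returns the 96 x K numeric matrix.
#' @export
readSignatureMatrix <- function(path) {
  df <- .readTsv(path)
  .checkColumns(df, "context", "signature matrix", path)
  ctx <- contextLabels96()
  if (!identical(sort(df$context), sort(ctx)))
    stop("signature matrix must contain exactly the 96 standard contexts",
         call. = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), "context"), drop = FALSE])
  rownames(mat) <- df$context
  mat <- mat[ctx, , drop = FALSE]
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-6))
    stop("signature columns must each sum to 1", call. = FALSE)
  mat
}

#' @rdname readSignatureMatrix
#' @export
writeSignatureMatrix <- function(mat, path) {
  df <- data.frame(context = rownames(mat), mat, check.names = FALSE)
  .writeTsv(df, path)
}

#' Write a lesion tree in Newick format
#'
#' Branch lengths are the per-branch character counts; the tree is
#' rooted at the myometrium reference for display.
#'
#' @param tree a [LesionTree-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  if (tree@nCharacters == 0L || !inherits(tree@tree, "phylo"))
    stop("empty tree cannot be written", call. = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(tree@tree, file = path)
  invisible(path)
}
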