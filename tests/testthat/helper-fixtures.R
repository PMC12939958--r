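# shared fixture builders; everything is generated in code

makeVariants <- function(n = 1, case_id = "case01", sample_id = "G1",
                         role = "G", chrom = "chr1", pos = seq_len(n),
                         ref = "C", alt = "T", depth = 100L,
                         alt_reads = 20L, gene = NA_character_,
                         func_class = "intronic", pop_af_eas = NA_real_,
                         phase = NA_integer_, context = "ACA",
                         mean_base_quality = 30) {
  if (n == 0)
    return(makeVariants(1)[0, , drop = FALSE])
  data.frame(case_id = case_id, sample_id = sample_id, role = role,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             depth = depth, alt_reads = alt_reads,
             vaf = alt_reads / depth, gene = gene,
             func_class = func_class, pop_af_eas = pop_af_eas,
             phase = phase, context = context,
             mean_base_quality = mean_base_quality,
             stringsAsFactors = FALSE)
}

makeSegments <- function(n = 1, case_id = "case01", sample_id = "G1",
                         chrom = "chr1", start = (seq_len(n) - 1) * 100 + 1,
                         end = seq_len(n) * 100, copy_ratio = 1,
                         minor_allele_fraction = 0.48, n_probes = 50L) {
  if (n == 0)
    return(makeSegments(1)[0, , drop = FALSE])
  data.frame(case_id = case_id, sample_id = sample_id, chrom = chrom,
             start = start, end = end, copy_ratio = copy_ratio,
             minor_allele_fraction = minor_allele_fraction,
             n_probes = n_probes, stringsAsFactors = FALSE)
}

makeEvent <- function(case_id = "case01", sample_id = "G1",
                      chrom = "chr1", start = 1, end = 1000,
                      event_type = "GAIN",
                      affected_haplotype = NA_integer_) {
  data.frame(case_id = case_id, sample_id = sample_id, chrom = chrom,
             start = start, end = end, event_type = event_type,
             affected_haplotype = affected_haplotype,
             stringsAsFactors = FALSE)
}

# small fast simulation configuration for unit tests
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nCases = 2L, nGermline = 40L, nTrunk = 10L,
                   nShared = 20L, nPrivate = 5L, nDriverGenes = 3L,
                   driverCasesEach = 2L, nPassengerGenes = 20L,
                   seed = 101L)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# character matrix straight from a taxa x characters 0/1 matrix
bcmFromMatrix <- function(mat) {
  cs <- colSums(mat)
  new("BinaryCharacterMatrix", taxa = rownames(mat), mat = mat,
      characterIds = as.character(seq_len(ncol(mat))),
      informative = cs > 0L & cs < nrow(mat))
}
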