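---
title: "lesionevo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lesionevo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionevo)
```

# The analysis problem

Gastric-type endocervical adenocarcinoma (GAS) is an HPV-independent
cervical cancer thought to arise from lobular endocervical glandular
hyperplasia (LEGH), a benign precursor. Multi-region studies
microdissect matched tissues from each patient — normal myometrium
(`Nm`, the germline reference), normal cervical glands (`N`), LEGH
(`L`) and GAS (`G`) — and ask, from the somatic alterations alone,
whether the carcinoma really descends from the precursor, what copy
number events accompany the transition, which mutational processes
operate, and which genes drive it.

`lesionevo` implements the downstream analysis of such a design as a
tested, reusable pipeline over plain TSV tables: somatic variant
filtering, copy-number and copy-neutral-LOH (CN-LOH) calling with a
normal-derived threshold, haplotype-aware event interpretation,
96-context mutational-signature refitting, exhaustive-search parsimony
phylogenies with lesion-topology classification, and a cancer-gene-census
style candidate-driver scoring system. Because real cohorts of this
kind are under controlled access, the package ships a clonal-evolution
simulator with a complete truth ledger; every stage is validated
against planted truth or an independent oracle.

# Somatic filtering

Variants observed in the myometrium reference of the same case are
removed as germline, keyed strictly on `(chrom, pos, ref, alt)` —
genotype, VAF and phase deliberately do not enter the key, so a
germline variant is subtracted even when its allele fraction differs
between tissues. Quality filtering keeps variants with mean base
quality ≥ 20, depth ≥ 10 and VAF ≥ 0.05, and drops mitochondrial and
unplaced contigs. The thresholds are conventional FFPE/WES floor
values and are all arguments of `qualityFilter()`; the tests exercise
the rule, not the constants. Burden summaries split variants into
exonic (nonsynonymous, synonymous, stopgain, frameshift,
non-frameshift) and non-exonic (splicing, intronic, intergenic, UTR)
classes and report mutations per megabase of callable territory.

# Copy-number events and the CN-LOH cutoff

Segments arrive as intervals with a tumor/normal copy ratio and a
minor allele fraction (MAF). The decision rule is fixed:

* copy ratio strictly above 1.1 → gain;
* strictly below 0.9 → loss;
* ratio inside the closed band [0.9, 1.1] with MAF below the CN-LOH
  cutoff → copy-neutral LOH;
* otherwise no event. Adjacent same-type calls merge.

The CN-LOH cutoff is derived from the normal reference samples: the
10th percentile of each normal's MAF values (quantile type 7, the
ubiquitous linear-interpolation convention; the percentile definition
is configurable) and then the mean of those per-sample percentiles
minus three sample standard deviations (n − 1 denominator). The
phrase "mean minus three SDs of the per-sample 10th percentiles" is
genuinely ambiguous in prose; this package fixes it as
`mean(p10) − 3 · sd(p10)` across normals, which makes the cutoff an
outlier bound for what a normal sample's lower MAF tail looks like.
Under the simulator's default noise the derived cutoff lands in the
low-to-mid 0.40s, the regime reported for this assay class. Per-site
versus per-segment percentiles are another unstated detail; the
package computes them over the per-segment MAF values supplied for
each normal sample.

Haplotype assignment uses phased heterozygous variants overlapping an
event: under loss or CN-LOH, phased alleles on the lost haplotype sit
below VAF 0.5, so each informative variant votes for the haplotype its
allele incriminates, and the majority wins; gains are symmetric with
elevated fractions. Ties and uninformative events stay `unknown` —
downstream scoring treats unknown-phase CN-LOH as unscorable rather
than guessing. A planted loss-of-function variant inside the event
votes too, which mirrors how a retained-haplotype mutation is actually
recognized in practice.

# Phylogeny and topology classes

Each case yields a binary character matrix: one character per somatic
variant key, presence meaning the variant passed filtering in that
sample, with `Nm` the all-absent outgroup. With at most four taxa per
case, heuristic tree search is unnecessary: `parsimonyTree()`
enumerates every unrooted binary topology (3 for four taxa, 15 for
five; six taxa at most by design) and scores each with the Fitch
small-parsimony algorithm, vectorized across characters with bitmask
state sets. The minimum-score topology is returned; exact ties are
reported and classify as `UNRESOLVED` rather than being broken
arbitrarily. Branch counts place each character's changes on the most
terminal admissible branch of one minimal reconstruction (a
DELTRAN-flavored tie-break); this affects per-branch counts only,
never the score. Trees are rooted at `Nm` for display and Newick
export, with branch lengths equal to character counts.

Topology classes follow the three observed patterns: `TYPE1` when L
and G form a cherry (carcinoma descends within the precursor lineage),
`TYPE2` for an N+L cherry, `TYPE3` for N+G. Cases without a
normal-gland sample cannot be oriented and return `UNRESOLVED`. A
maximum-likelihood cross-check (`mlTopologyCheck()`, a two-state
equal-rates model fitted with `phangorn` on each candidate topology)
is provided for robustness reporting; concordance is reported, never
enforced. The copy-number event tree uses the same machinery on
event-interval × event-type characters — a declared simplification of
minimum-event copy-number phylogenetics, which would require a
dedicated evolution model; with a handful of events per case, binary
presence characters carry the same topological signal.

The shared-variant VAF comparison collects variants present in both
lesions of a case and compares the two VAF collections with a
two-sided Wilcoxon rank-sum test, reporting per-lesion means — the
analysis that shows mutual mutations riding at higher allele fraction
in the carcinoma.

# Mutational signatures

SNVs are mapped to the 96 trinucleotide-context classes after
pyrimidine-strand normalization (purine-reference sites are
reverse-complemented). Refitting — not de novo extraction — is the
supported operation: with a couple dozen samples, supervised
refitting against a fixed reference is the reproducible core, and
exposures are obtained by non-negative least squares
(`pracma::lsqnonneg`), with proportions and an L2 residual. The
packaged reference (`sbs_reference_synthetic.tsv`) is synthetic: five
profiles carrying the defining peaks of the clock-like CpG C>T
process, the two APOBEC-style TpC processes, a broad low-contrast
profile, and a flat background. It is deliberately not the catalog
matrix (which is not redistributable here); `readSignatureMatrix()`
accepts any 96 × K reference with unit column sums.

# Driver scoring

Scoring is computed on carcinoma samples. A short variant qualifies
when exonic and non-synonymous with East-Asian population allele
frequency below 0.01 or absent. Each gene earns one point per case
with at least one qualifying variant (multiple hits in one case still
count once), plus one point per case with a biologically plausible
copy-number event: gain over an oncogene, loss over a tumor
suppressor, or CN-LOH only when a loss-of-function variant (stopgain,
frameshift or splicing; missense is "function unclear" and never
scores) lies on the retained haplotype. CN-LOH points are capped at
one per case per gene, parallel to the short-variant rule. Genes with
total ≥ 2 are candidates; the sensitivity analysis re-emits candidate
sets at thresholds 2–5, which are nested by construction. Pathway
over-representation is a generic one-sided hypergeometric test over
user-supplied GMT gene sets with Benjamini–Hochberg adjustment — a
deliberate replacement for external web services, keeping the
computation auditable and offline.

# Statistics

`kruskalWallis()` (omnibus, chi-square approximation with midrank
ties), `wilcoxonRankSum()` (exact enumeration for combined n ≤ 20
without ties, otherwise normal approximation with continuity and tie
correction; completely tied data return p = 1), `bhAdjust()` and
`correctedPairwise()` (pairwise rank tests gated on a significant
omnibus, BH by default with a Bonferroni switch — the upstream
software's exact pairwise correction is unstated, so the default is
declared in the output metadata). All tests are two-sided. These wrap
the reference implementations in base R; the test suite checks them
against exhaustive permutation enumeration and Monte-Carlo
calibration, not against themselves. One textbook note: step-up BH
adjustment is not idempotent as a map on p-value vectors, so the suite
asserts monotonicity and agreement with enumeration instead.

# The simulator and what it does (not) emulate

`simulateCase()` emits a four-sample case on an artificial diploid
genome (22 chromosomes × 10 Mb, segment grid of four 2.5 Mb segments
per chromosome, 10 genes of 100 kb per chromosome at fixed positions).
Defaults were chosen once to mirror the study conditions and are the
conditions under which the package's guarantees are tested:

* 7 cases, topology pattern `TYPE1, TYPE1, TYPE1, TYPE2, TYPE3`
  recycled (Type-1 predominant, as observed);
* 100 germline variants (80% heterozygous, phased), 30 trunk, 50
  shared-branch and 10 private variants per branch;
* mean depth 100×, binomial read sampling; lesion purity 0.4, so
  clonal heterozygous variants sit near VAF 0.2;
* a +0.06 expected VAF increment in the carcinoma for every variant
  mutual to L and G (trunk and, in `TYPE1` cases, the shared branch) —
  reproducing the 0.20 vs 0.26 mutual-VAF contrast;
* copy-number events: one L+G-shared event in `TYPE1` cases and two
  private events per lesion, with gains at ratio 1.2–1.5, losses at
  0.60–0.85, CN-LOH at ratio 1 with MAF 0.30; Gaussian ratio noise
  (SD 0.03 at a 100 kb reference scale, shrinking as the square root
  of segment length — segment estimates average over probes);
  neutral-segment MAF is 0.5 minus bounded uniform noise whose width
  varies by sample, which is what gives the normal-derived cutoff a
  clean separation from neutral segments;
* an SBS1-like/flat substitution-class mixture at weight 0.7, each
  variant carrying its trinucleotide context (on either strand with
  probability ½, so strand normalization is always exercised);
* 5 planted driver genes (mechanisms cycling over recurrent short
  variants, oncogene gain, suppressor loss, CN-LOH with a
  loss-of-function variant on the retained haplotype, and a mixed
  pattern), each in 3 cases, against 200 passenger genes of which half
  receive one qualifying variant in exactly one case.

Two constructions make scoring recovery well-posed by design, and they
are the main intentional departures from realism. Background somatic
variants never satisfy the scoring qualification rules (exonic
nonsynonymous background variants are emitted as population-frequent),
and background copy-number events are placed in intergenic windows
while planted driver events span exactly the gene body — so the
ledger's driver set is the unique right answer and precision/recall
can be asserted at 1.0. Real data have passenger hits that qualify
and events overlapping bystander genes; on real cohorts the scoring
output is a ranked shortlist, not a classifier with known truth.
Other simplifications: no subclonal structure (every somatic variant
is clonal within its branch), no read-level artifacts, no reference
genome (contexts are emitted, not looked up), and indels are not
emitted by default (the indel-specific scoring clauses are exercised
by fixtures). Passing tests therefore demonstrate the correctness of
the rules and estimators under the stated statistical model — not
robustness to every artifact of FFPE exome data.

# Numerical and convention choices

* Intervals are 1-based inclusive everywhere — files and memory — the
  native IRanges convention, so no boundary conversion exists to get
  wrong.
* Gain/loss boundaries are strict inequalities; the neutral band is
  closed, per the stated rule "between 0.9 and 1.1".
* The 96-context order is the conventional alphabetical layout;
  signature columns must sum to 1 within 1e-6.
* NNLS exposures are clipped at zero against solver round-off;
  proportions of an all-zero spectrum are NA with a degenerate flag.
* Exhaustive topology search refuses more than six taxa (105
  topologies) by design rather than silently switching to heuristics.
* Problem sizes in the shipped checks (e.g. 30–100 simulated cases per
  topology, 10,000 null replicates for calibration, 20 multinomial
  refits) were chosen as comfortable desk-scale sizes with tight
  Monte-Carlo error for the quantities asserted.

# Known limitations

Purity/ploidy estimation, segmentation, subclonal deconvolution and
phasing itself are out of scope: the pipeline consumes segment tables
and a phase column as inputs. The CN-LOH cutoff rule assumes at least
two normal samples (the between-sample SD is otherwise undefined) and
inherits the ambiguity of its prose definition, resolved as described
above. Topology classification is only defined against the
four-role design; cohorts with extra lesion multi-sampling per patient
would need the six-taxon ceiling raised and topology classes
generalized.
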