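---
title: "Splicing QTL mapping from junction reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing QTL mapping from junction reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionqtl)
```

# The problem

A coding variant can regulate its own gene's expression when it overlaps an
exonic splice enhancer (ESE): disrupting the enhancer slows splicing at one
or more junctions, intronic sequence lingers in the nascent transcripts, and
the yield of mature mRNA drops. The motivating system is the bovine *DGAT1*
locus, where a dinucleotide AA>GC substitution (the K232A amino-acid
replacement) sits inside two overlapping purine-rich hexamers at the 5' end
of exon 8, is associated with mammary *DGAT1* expression, with the usage of
an alternative 5' donor in exon 8, and with the splicing efficiency of
multiple introns — and where mini-gene constructs differing only by the two
alleles reproduce the splicing difference in cell culture.

`junctionqtl` implements that analysis end to end as reusable, tested
components:

1. **junction phenotypes** from aligned RNA-seq reads,
2. **association scans** of those phenotypes against genotype dosages,
3. **ESE hexamer scanning** of allele-specific exon sequence,
4. **mini-gene qPCR quantification** of spliced:unspliced ratios,
5. a **synthetic-data generator** reproducing the statistical structure of
   the cattle cohort, with truth tables for parameter recovery.

# Junction phenotypes

For a gene model with introns $j = 1 \dots K$ (transcription order), reads
are classified at each junction:

* **spliced** — a between-block gap of the alignment matches the intron
  interval exactly, with at least `min_anchor` aligned bases on the donor
  and acceptor exons ("bridging the junction");
* **unspliced** — a single aligned block crosses the donor-side exon–intron
  boundary with at least `min_anchor` bases on each side (from the 3' end
  of the preceding exon into the intron);
* **other** — anything else overlapping the junction neighbourhood (the
  intron extended by one base on each side).

These three classes partition the reads overlapping the neighbourhood, a
conservation property the test suite asserts on simulated data. Three
phenotypes are derived per sample:

* **splicing efficiency** at junction $j$:
  $(n^{spliced}_j + c) / (n^{unspliced}_j + c)$ with pseudocount
  $c = 0.5$ by default ($c = 0$ recovers the strict spliced:unspliced read
  ratio, undefined at zero unspliced reads). The ratio is a read-level
  proxy for the splicing rate constant of the junction.
* **intron-read percentage**: 100 × (reads overlapping the intron by at
  least one base) / (reads overlapping the gene span). This is the
  coarser, percentage-scale retention phenotype.
* **PSI** for an annotated alternative 5' donor event:
  $100 \, n^{ref}/(n^{ref}+n^{alt})$, where $n^{ref}$ and $n^{alt}$ count
  reads whose splice gap matches the reference-donor and
  alternative-donor gap exactly. PSI and alternative usage sum to 100.

Expression is summarised as `log2(reads + 1)` of the gene's read count; for
multi-gene count matrices, `normalize_expression()` provides median-of-ratios
size factors followed by `log2(x/s + 1)` with optional per-batch
mean-centering. This is a deliberate, documented approximation of a
variance-stabilising transform: the downstream linear models only need a
monotone transform with roughly mean-independent variance, and the
median-of-ratios size factors are tested against the reference
implementation in DESeq2.

## Parameter choices

* `min_anchor = 1` by default: the classification rule only requires that a
  read touch both sides of the junction; deeper anchors (tests also run 6)
  trade sensitivity for alignment robustness.
* Unspliced reads are counted at the **donor-side boundary only** by
  default, matching the phenotype definition the package follows; an
  acceptor-side option (`both_boundaries = TRUE`) exists for symmetric
  designs.
* Gaps shorter than 20 bp in alignments are treated as deletions, not
  splices (the conventional aligner minimum intron size); the threshold is
  an argument of `read_alignments()`.
* Reads are counted once per junction but may inform several junctions;
  paired mates are treated as independent reads (no fragment-level
  deduplication).

## Coordinates

All internal coordinates are 1-based inclusive — the native convention of
GTF, VCF, FASTA and the Bioconductor ranges stack that backs the readers.
BED is converted at the boundary (`to_zero_based()` / `to_one_based()`,
property-tested as exact inverses). Keeping a single convention internally
avoids the off-by-one traps that motivate hybrid schemes in other stacks.

# Association model

Each marker is fitted separately by least squares:

$$ y = \mu + X\beta_c + g\,\beta + \varepsilon $$

with $g$ the dosage of the alternative allele (0/1/2, treated as
quantitative/additive), and $X$ the covariates the cohort design calls for
(sequencing cohort, ancestry proportions, heterosis). A two-sided t-test on
$\beta$ gives the p-value; markers are ranked by ascending p with ties
broken by genomic position then marker id. Missing dosages are dropped
pairwise per marker; constant markers are skipped as `monomorphic`; a
marker whose dosage is perfectly explained by the covariates (e.g. perfect
LD with a conditioned marker) is reported with `p = 1` and reason
`aliased`, since it carries no independent information.

**Variance explained** is reported as
$100 (\mathrm{SSE}_{cov} - \mathrm{SSE}_{full}) / \mathrm{SSE}_{cov}$ —
the marker's share of the variance of the covariate-adjusted phenotype.
This convention is stated explicitly because percentage-of-variance claims
are model-dependent; it is not claimed to equal a pedigree-REML estimate.

**Conditional scans** append a focal marker's dosage to the covariates and
report the focal marker itself as `conditioned`. **LD** is summarised as
the squared Pearson correlation of dosages, invariant to allele coding.

**Relatedness**: the original cohort analysis used a pedigree-based mixed
model. The package approximates this with an optional single random
intercept (e.g. sire group) estimated by profiled REML over the one
variance ratio $\lambda = \sigma^2_u/\sigma^2_e$, optimised numerically
with fixed effects solved by GLS at the optimum; $\lambda = 0$ reproduces
the fixed-effects fit exactly (asserted to 1e-8 in tests), and the full fit
is cross-checked against lme4 as an independent oracle. Full pedigree REML
is out of scope.

**Multiple testing** is Bonferroni only: `alpha / n_tests`, with the three
relevant family sizes (markers × junctions for the junction-efficiency
scans; markers for a single conditional scan; 3 measurement types × 4
junctions for the mini-gene table). The genotype–PSI association uses a
Kruskal–Wallis rank test (chi-square reference with tie correction) because
within-class PSI distributions are heavily skewed. At very small samples
the chi-square reference is approximate: at $n = 9$ its tail error against
the exact permutation distribution can reach several percentage points
depending on the data, which the test suite documents with a fixed
moderate-separation fixture.

# ESE scanning

A panel of hexamers is scanned over a sequence window; every offset whose
6-mer is in the panel is a hit (windows containing N never match; scanning
is strand-naive — pass the reverse complement explicitly for the other
strand). For a substitution variant, `variant_motif_delta()` scans both
alleles and reports hits overlapping the variant span that are lost or
gained; swapping alleles swaps the two sets. Only same-length substitutions
(SNPs/MNPs) are supported, matching the AA>GC use case; indels are
rejected.

The package ships a *synthetic* 12-hexamer panel
(`inst/extdata/ese_panel_synthetic.txt`) containing the two reported
motifs (AGAAGG, AAGAAG) plus ten purine-rich decoys, and a reconstructed
23-nt exon-8 context (`exon8_context_synthetic.fa`): the true published
238-hexamer panel and the genomic flanking sequence are external resources
not redistributed here, and the exact 23-nt window is not printed in the
source material — the fixture reconstructs a consistent context in which
the reference (K) allele carries exactly the two overlapping hits and the
alternative (A) allele none. Real analyses should supply their own panel
file (one 6-mer per line, `#` comments).

# Mini-gene qPCR

Quantification uses the standard-curve method, not ΔΔCq, because each assay
has its own serial-dilution curve: Cq is regressed on log10(relative
concentration), amplification efficiency is $10^{-1/slope} - 1$ (flagged
when outside 0.7–1.2), and well quantities are interpolated as
$10^{(Cq - b)/m}$. Per sample × assay, quantities are averaged over
replicate wells and divided by the geometric mean of the sample's reference
assays (endogenous control and transfection control both enter the
geometric mean by default; `reference_assays` restricts the set). The
splicing ratio is the per-sample spliced:unspliced quantity ratio;
allele-level summaries are means ± SD across samples, contrasted with a
pooled-variance Student t-test (Welch optional) and a Bonferroni flag at
the 12-test family.

Note that per-sample ratio averaging does **not** equal the ratio of the
group-mean spliced and unspliced expressions; the package follows the
per-sample convention, which is the one consistent with the reported group
ratios and their across-sample spreads.

# The synthetic cohort

The generator emulates the structure the analysis assumes, with defaults
fixed to the anchored study conditions:

| quantity | default | origin |
|---|---|---|
| animals | 375 | cohort size |
| high-expression (K) allele frequency | 0.51 | cohort estimate |
| sequencing cohorts | 21 / 183 / 171 | cohort sizes |
| focal intron-read % by dosage 0/1/2 | 1.16 / 1.53 / 1.94 | class means |
| reference-donor PSI by dosage | 94.1 / 94.5 / 96.4 | class medians |
| expression by dosage | 9.628 / 9.436 / 9.244 | class means |
| expression residual SD | 0.25 | back-derived from class SEs |
| qPCR true ratios (introns 3/5/7/13) | per-allele Table values | mini-gene group means |

Dosage counts the expression-*decreasing* (GC / 232A) allele, so dosage 0
is the high-expression KK class. The three class anchors are used directly;
they are mutually consistent with additivity on a latent (logit for rates)
scale. Where the source material prints no value, defaults were chosen once
as realistic for the system and not revisited: 200 markers in the simulated
1-Mb interval (a desk-scale stand-in for the 3128 imputed variants), LD
partners generated by copying causal haplotypes with per-marker flip
probabilities uniform on (0.10, 0.45) (dosage r² roughly 0.01–0.65),
600 junction-bridging reads per junction and 1500 exon-body reads per
animal (the gene is highly expressed in the tissue), read length 100
single-end (the study's paired 100-bp protocol simplified; pairing adds
nothing at junction level), 40% of intronic reads crossing the donor
boundary (the remainder in the intron body), a mean-preserving lognormal
per-animal biological factor (log-SD 0.2) on retention and
alternative-usage rates, negative-binomial size 20 for read totals, qPCR
cycle noise SD 0.15, per-preparation lognormal ratio variation 8% (which
reproduces the printed across-sample SDs), transfection-efficiency
variation 15% shared between a sample's assays, and 3 preparations × 3
wells. All randomness flows from one master seed through named
sub-streams, so each component is reproducible in isolation.

Two generators share these expectations: `simulate_reads()` materialises
alignments read by read together with a truth table carrying every read's
true kind and the class the classifier must assign (the generator–classifier
round trip is asserted exactly, currently on >1e5 reads), and
`simulate_cohort_counts()` draws the same phenotypes at the count level for
association-scale simulation studies (a 375-animal, 200-marker scan takes a
fraction of a second, so hundred-seed studies stay cheap).

**What the generator does not emulate**: sequencing errors and base
qualities, mapping ambiguity, fragment-length structure of read pairs,
pedigree relatedness (covered only qualitatively by the REML random
intercept), genotype imputation error, and genome-scale context (one toy
gene on one contig). Passing recovery tests therefore demonstrate that the
estimators are consistent with their own definitions under clean
alignments, not that they are robust to alignment artefacts in real data.

# Numerical and degenerate-input conventions

* `efficiency_ratio` with pseudocount 0 and zero unspliced reads is NA, not
  infinite; PSI with zero informative reads is NA.
* Size-factor estimation excludes genes containing zero counts from the
  median (the reference convention); a single sample gets size factor 1.
* The REML ratio is optimised on $[0, 50]$ with the boundary checked
  explicitly, so a zero variance component is returned exactly.
* All-tied Kruskal–Wallis input returns $H = 0, p = 1$ rather than NaN.
* Zero within-group variance with distinct group means in the qPCR t-test
  (noise-free simulations) returns $p = 0$ with an infinite statistic
  rather than an error.
* Ranking ties (identical p) are broken by position then marker id so
  ranks are a deterministic permutation.

# Problem sizes used by the test suite

The suite simulates at the anchored cohort scale where the claim being
tested needs it (100 seeds × 375 animals × 200 markers for the
rank-recovery and conditional-scan study; 10 animals ≈ 1.1e5 reads for the
classifier round trip; 1000 markers for the type-I error check) and at
reduced scale elsewhere; the full run completes in a couple of minutes on
one CPU.

# Limitations

* The efficiency and retention phenotypes are read-level proxies; they do
  not model transcript-level intron linkage or nascent-RNA kinetics.
* The fixed-effects scan with covariates approximates, but does not
  replicate, a pedigree mixed model; rank comparisons with the original
  cohort analysis are qualitative.
* The ESE module is a presence/absence hexamer scanner by design — no
  position weight matrices, splice-site strength models or branch-point
  prediction.
* PSI is defined for one annotated alternative-donor event per gene model.
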