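---
title: "Dosage-compensation and proteostasis analysis for aneuploid yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-compensation and proteostasis analysis for aneuploid yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneudose)
```

## The scientific question

Haploid yeast strains that carry one or more whole extra chromosomes
(disomes) must transcribe and translate hundreds of additional gene copies.
Two very different outcomes are conceivable: the cell could attenuate
expression from the duplicated chromosomes back toward euploid levels
(dosage compensation), or it could transmit the dosage faithfully and absorb
the extra protein load with its proteostasis machinery. Distinguishing the
two requires (i) knowing the karyotype precisely, (ii) quantifying mRNA and
ribosome-footprint abundance on a scale where the euploid reference is
meaningful, and (iii) separating copy-number effects from genuine
stress-response programs and from background mutations.

`aneudose` implements that analysis chain as a set of small, testable
functions, together with a synthetic-data module that generates every input
with known ground truth. Because the generators expose the quantities the
analysis is supposed to recover (copy numbers, compensation strength,
planted stress programs, variant strata, decay half-lives), every stage can
be validated end to end without external data.

## Karyotyping

**qPCR arm probes.** Under amplification efficiency exactly 2, a locus
present in $c$ copies crosses the detection threshold $\log_2 c$ cycles
earlier than a single-copy locus. For each chromosome arm we average the Ct
of the technical replicates (3 by default), convert the strain-minus-
reference difference to a copy number
$c_{\mathrm{arm}} = p \cdot 2^{\,\overline{Ct}_{\mathrm{ref}} -
\overline{Ct}_{\mathrm{strain}}}$ (base ploidy $p = 1$ here), average the
two arms, and report the between-arm standard deviation as the error bar.
The integer call is the nearest integer, floored at 1. The efficiency-2
model is an explicit idealisation: real probe efficiencies vary by a few
percent, which perturbs copy estimates multiplicatively; with a one-cycle
separation between copy 1 and copy 2 the integer call tolerates
efficiency errors far larger than those seen in practice.

**Windowed sequencing depth.** Depth is summarised in non-overlapping 1-kb
windows (internally half-open, 1-based inclusive in exported tables). The
per-window log2 ratio of strain over euploid RPKM is summarised per
chromosome by its **median**, chosen over the mean for robustness to
mapping artefacts and depth spikes; the copy estimate is
$p \cdot 2^{\mathrm{median}}$. A *segmental screen* flags any chromosome
containing a contiguous run of at least 50 windows (50 kb) whose log2 ratio
deviates from the chromosome-level call by at least 0.58 (≈ 1.5-fold) —
those two thresholds are package conventions; the purpose of the screen is
to exclude large partial-chromosome gains or losses masquerading as clean
whole-chromosome calls, and 50 kb at 1.5-fold is far below any event that
could bias a chromosome median. Windows with zero euploid depth are
excluded and counted.

At the default simulation noise (Ct SD 0.1 cycles, depth CV 0.2) both
estimators call all chromosomes of the six study karyotypes (D2, D1/2,
D1/2/8, D1/2/8/11, D1/8, D13) correctly in over 99% of seeded replicates;
the acceptance script recomputes this rate.

## Expression quantification and normalization

Abundance is quantified as RPKM: reads per kilobase of coding sequence per
million mapped reads, computed separately for mRNA and footprint (FP)
libraries. Mitochondrial genes are removed **before** the per-sample totals
are taken, so the mapped-read denominator and the downstream gene universe
coincide (whether totals should be taken before or after that exclusion is
genuinely underdetermined; doing both on the same universe is the
self-consistent choice and changes totals by well under 1% in practice).

Aneuploid samples are then scaled by the **median ratio over nonduplicated
chromosomes**: the scale factor is the median of aneuploid/euploid RPKM
across genes on nonduplicated chromosomes with positive euploid RPKM, and
all aneuploid RPKM values are divided by it. After this step the median
nonduplicated ratio is exactly 1 (a definition-level identity, asserted in
the tests to 1e-12), the normalization is idempotent, and duplicated
chromosomes can be read directly as departures from the euploid baseline:
an uncompensated disome shows a median log2 fold change of 1.0 on its
duplicated chromosome and 0 elsewhere.

Fold changes are `log2(aneuploid_normalized / euploid)`; genes with a zero
on either side are flagged missing rather than imputed — no pseudocounts,
because a fabricated finite fold change is worse than an honest `NA` for
every downstream consumer (signature means, threshold selections,
completeness rules). Ribosome density is FP/mRNA per gene and its fold
change is the difference of the two assays' log2 fold changes. Each
aneuploid sample is compared against the euploid sample prepared in its
batch; that pairing is explicit configuration, never inferred.

Per-chromosome dosage summaries report the median log2 fold change against
the expectation $\log_2(c/p)$ and mark a duplicated chromosome as
*compensated* when its median falls short of the expectation by more than a
tolerance (default 0.3 log2, roughly halfway between full transmission and
full compensation for a disome).

## Synthetic data: what it emulates and what it does not

The count generator draws gene baselines from a log-normal distribution
(sdlog 1, spanning roughly two orders of magnitude of expression, as in
typical yeast RNA-seq), multiplies them by
$c_g^{\,1-\phi}$ where $c_g$ is the gene's chromosome copy number and
$\phi \in [0,1]$ the compensation fraction (0 = fully transmitted dosage,
the regime observed in the tolerant strains; the dial exists so both
regimes are testable), applies optional planted programs (gene sets shifted
by a log2 effect, per assay or in both), rescales expectations to the
target library size (default 5e6 reads), and draws negative-binomial counts
with dispersion 0.01 — the scale of replicate-level variability for
isogenic yeast cultures; RNA-seq counts are conventionally modelled as
negative binomial, and the Poisson limit (dispersion 0) is available for
exactness checks. Baselines depend only on the configuration seed, so a
strain and its euploid reference simulated from the same configuration
share them and differ only in copy number, planted programs, and sampling
noise.

Other generators follow the same pattern: qPCR plates under the
efficiency-2 model with Gaussian Ct noise; 1-kb windows with multiplicative
log-normal noise of a stated CV; variant tables with labelled strata
(haploid homozygous at frequency ≥ 0.9, heterozygous-on-duplicated near
0.5, noise below 0.3 or below quality 15) constructed so that the stated
filters separate them perfectly; exponential pulse-chase decay with
additive Gaussian noise floored at zero.

What the generators deliberately do **not** model: raw reads or alignment
(no FASTQ, no mapping bias, no multi-mappers), footprint-specific geometry
(P-sites, fragment lengths), correlated gene-gene noise, GC or length
biases in depth, batch effects beyond the explicit pairing, or real linkage
between variants and expression. A test that passes on this synthetic data
therefore validates the *arithmetic and the decision rules* of the
analysis, not its robustness to alignment artefacts — those live upstream
of this package's inputs.

## Signatures, enrichment, and the shared program

Stress-response gene sets (ESR induced and repressed scored separately,
HSR, OSR, UPR, and similar) are scored as the **mean** log2 fold change
over member genes that lie on chromosomes *not duplicated in the scored
strain* and have defined fold changes — excluding duplicated-chromosome
members is what prevents dosage itself from masquerading as a stress
response. An empty eligible set is an error, not an `NaN`. Heatmap matrices
restrict rows to genes nonduplicated in **every** strain displayed and
defined in **every** sample (the stricter of the two readings of
"nonduplicated", adopted because a single shared heatmap implies a single
shared gene universe).

Threshold selections use inclusive boundaries ("at least 1.5-fold" means
log2 fold change ≥ 0.585; the relaxed intersection cutoff is ≥ 0.38,
i.e. 30%). Enrichment is an upper-tail hypergeometric test
$P(X \ge k)$ for an overlap of $k$ query genes with a term of size $K$ in a
universe of size $N$ at query size $n$, Bonferroni-corrected by the number
of terms with at least one member in the universe (terms that cannot
overlap are untestable and do not belong in the multiplier). The universe
is all annotated non-mitochondrial genes with defined fold change in the
sample, declared in the output. The test suite checks the p-values against
exhaustive enumeration of all draws for every universe size up to 15.

The shared upregulation analysis intersects per-strain up-sets at the 0.38
cutoff across the four chromosome-II disome strains, excludes chromosome II
itself, and assigns each surviving gene to exactly one of twelve manually
curated functional categories. The curation is **data, not an algorithm**:
it ships as a package fixture (`upregulated_gene_categories()`, 251 genes, from
66-gene ribosome homeostasis down to 5 uncategorisable "others"), because a
manual curation can only be frozen, not recomputed.

## Variants

Filtering keeps a record iff base quality ≥ 15, mapping quality ≥ 15, and
variant allele frequency ≥ 70% on single-copy chromosomes or ≥ 40% on
duplicated chromosomes (a real heterozygous variant on one of two copies
sits near 50%). All comparisons are inclusive. Wild-type subtraction
removes records matching a wild-type record exactly on
(chromosome, position, ref, alt). Coding effects are classified for SNVs
only by translating the affected codon before and after the substitution,
strand-aware, under the standard genetic code: synonymous, nonsense (stop
gained), or missense; positions outside any CDS are intergenic and indels
are left unclassified — upstream alignment-level filters (mismatch quality
sums and the like) need alignment statistics this data model does not
carry and are out of scope.

## Assay calculators

The biochemical readouts are literal formula evaluations with validation:
Miller units `1000*(OD420 - 1.75*OD550)/(2*t*OD600)` (the factor 2 is the
assay's volume convention, overridable); ER-GFP folding capacity as
fluorescence over loading-normalized total GFP, expressed as percent of
wild type; HAC1 spliced fraction `S/(S+U)`, invariant to the ACT1 loading
control; pulse-chase percent remaining per replicate with a half-life from
log-linear least squares (the estimator implied by a single-exponential
model — a nonlinear fit would weight early timepoints differently but
estimates the same parameter); doubling time from a log-linear fit over a
user-chosen exponential window (no universal window exists — the user sees
the curve); Pearson correlation for the growth-versus-ORF-burden question.
Strain comparisons use the two-tailed unpaired Student test with pooled
variance at the final chase timepoint, and Welch's test with Satterthwaite
degrees of freedom where group sizes differ, both with the conventional
significance bands (0.05/0.01/0.001).

## Problem sizes and numerical conventions

The test suite and the acceptance script run on 16-chromosome genomes with
125 genes per chromosome (2000 nuclear genes), 20 seeded replicates for the
dosage-recovery checks, 100 seeded replicates per karyotype and estimator
for karyotype recovery, and 200 depth windows per chromosome — sizes at
which the medians under test have small enough sampling error to be
informative while a full run stays in the tens of seconds. Determinism is
taken seriously: every generator is bit-reproducible for a fixed seed, and
seeds for derived draws are composed arithmetically so that strains share
baselines but never sampling noise.

Degenerate inputs fail loudly by design: zero-total samples, missing qPCR
arms, non-positive Ct values, mismatched window grids, queries outside the
enrichment universe, gene sets with no eligible member, chromosomes absent
from a karyotype. Silent coercion in any of these places would corrupt a
downstream median without a trace.

## Known limitations

* The qPCR model fixes amplification efficiency at 2; probe-specific
  calibration is not modelled.
* Only SNV effects are classified; indels are reported but unclassified.
* The enrichment universe convention (defined-fold-change, non-mito genes)
  is one defensible choice among several; per-strain selected-gene counts
  are therefore not comparable across tools with different universes.
* The curated category table is frozen data; applying it to a different
  gene universe counts only the genes it knows.
* Signature scores on few-member sets carry sampling error of order
  `sd/sqrt(n)`; the reported `n_genes_used` makes that visible.

## A minimal end-to-end run

```{r, eval = FALSE}
library(aneudose)

conf <- pipeline_config(strain = "D2", duplicated = "chrII", seed = 1,
                        pairing = c(D2_1 = "WT_1"))
res <- run_pipeline(conf, out_dir = "d2_run")

res$karyotype_qpcr                      # per-chromosome copy calls
res$dosage$FP                           # dosage summary, footprint assay
head(res$enrichment)                    # chromosome-term enrichment
res$manifest$thresholds                 # what was applied, for the record
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow over TSV files and write their tables under `results/`.
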