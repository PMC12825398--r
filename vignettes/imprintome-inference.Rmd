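---
title: "Inferring an endosperm imprintome from reciprocal crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring an endosperm imprintome from reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

Genomic imprinting is the parent-of-origin-dependent expression of a gene.
In seeds, the endosperm is the tissue where imprinting is concentrated, and
the standard way to detect it is a reciprocal cross: the same two
polymorphic parents are crossed in both mother/father role assignments, so
that parent-of-origin effects can be separated from genotype effects. RNA
reads from the offspring tissue are assigned a parent of origin at SNPs
where the parental genotypes differ, each gene's **maternal proportion**
θ̂ is estimated in both cross directions, and genes whose θ̂ departs from
the ploidy expectation in the *same* parental direction in *both* crosses
are called imprinted: maternally expressed genes (MEGs) at high θ̂,
paternally expressed genes (PEGs) at low θ̂.

`imprintr` implements this chain for a diploid endosperm (1 maternal : 1
paternal genome, null θ = 0.5), as found in water lilies; a `2/3` null for
typical triploid endosperms is available through
`caller_config(null_maternal_proportion = 2/3)`.

```{r, eval = FALSE}
library(imprintr)
res <- run_pipeline("parents.vcf", "counts.tsv", "genes.gff3", "design.tsv",
                    filter_cfg = filter_config(min_minor_allele_count = 1))
```

# Informative sites and the transformation model

With two diploid parents and biallelic SNPs there are nine genotype pairs,
which `classify_site()` partitions into four categories:

* `reciprocal_hom` — parents homozygous for different alleles. Every read
  is assignable; the maternal-allele count is the maternal read equivalent.
* `mother_het` / `father_het` — exactly one parent heterozygous. The
  dissected tissue pools endosperms from many seeds, and a heterozygous
  parent transmits each of its alleles to half of them. Its
  parent-specific allele (the one the homozygous parent lacks) therefore
  appears at expected read frequency `(parental expression share) / 2`.
  `site_parental_counts()` doubles the parent-specific count and caps it at
  the site total (`truncated` flags capped sites), restoring an unbiased
  parental read equivalent under Mendelian transmission. The same site
  switches between `mother_het` and `father_het` when the cross direction
  is reversed, so it is informative in both directions.
* `uninformative` — both parents heterozygous or identically homozygous:
  no discriminant allele exists and the site is excluded (and counted).

The doubling model assumes equal transmission, no systematic mapping bias
between alleles and a pool large enough that the half/half transmission
split holds in expectation. Its correctness is checked in the test suite
against a transmission-state enumeration oracle and against the
reciprocal-homozygous-only estimator on simulations.

Per gene and direction, transformed counts are **summed** over sites
(`M = Σ m̂`, `P = Σ p̂`, `θ̂ = M/(M+P)`) rather than averaging per-site
proportions: summation depth-weights sites and keeps the gene-level
quantity a count pair, which is what the chi-squared departure test
consumes. Capping keeps θ̂ in [0, 1] at the cost of a small inward bias at
extreme θ for heterozygous sites; with the default category mix the bias
is well under 0.01 and is covered by the recovery tests' ±0.02 band.

# Variant filtering and the minor-allele-count floor

`filter_config()` retains biallelic SNPs with quality ≥ 20, site depth ≥ 5
and both genotypes called — deliberately conservative floors for
genotyping from moderate-coverage resequencing. The minor-allele-count
floor deserves explanation. Counted across the four parental allele
copies, a single-parent heterozygous site always carries exactly one copy
of its discriminant allele, so the genotype-level default
`min_minor_allele_count = 2` admits only reciprocal homozygous sites. That
strict default is what a count-based variant filter applied to a genotype
table means, and it is the package default for `site_passes_filters()`.
When the heterozygous-site pathway is wanted — the very point of the
transformation model above, and standard when variants were filtered at
the *read* level in the expression data, where an informative heterozygous
site easily shows its minor allele in ≥ 2 reads — set
`min_minor_allele_count = 1`. The simulator, the packaged example and the
acceptance script all run in this heterozygous-aware mode; the filter knob
makes either convention explicit rather than baking one in silently.

Sites are assigned to genes by interval overlap (1-based inclusive;
GFF3 or coordinate-flagged tabular annotations). A site inside two or more
overlapping genes is dropped and counted (`n_ambiguous`) rather than
contributing the same reads to two genes' θ̂.

# Testing and calling

One chi-squared goodness-of-fit test per gene compares the counts
**pooled across both directions** with the null split
`(n·θ₀, n·(1−θ₀))`; pooling keeps a single p per gene and maximises power,
while the threshold rule stays per-direction. q-values are
Benjamini–Hochberg over the genes estimable in both directions.
`call_status()` applies the reciprocal thresholds: MEG moderate θ̂ > 0.75,
strong > 0.9; PEG moderate θ̂ < 0.25, strong < 0.1, in **both**
directions, with strict inequalities (θ̂ exactly at a threshold does not
call), strong nested inside moderate (the strongest satisfied class is
reported, and class totals add strong + moderate members). By default a
call also requires q ≤ 0.05 (`require_significance = TRUE`); the
thresholds-only mode is retained as a flag because published pipelines
differ on whether significance acts as a filter or a description.

Tunables, defaults and units:

| parameter | default | meaning |
|---|---|---|
| `min_qual` | 20 | variant quality floor (phred-scaled) |
| `min_depth` | 5 | site read-depth floor (reads) |
| `min_minor_allele_count` | 2 | copies of the rarer parental allele (see above) |
| `min_reads` | 10 | transformed reads per gene and direction for an estimable θ̂ |
| `meg_moderate` / `meg_strong` | 0.75 / 0.9 | MEG θ̂ thresholds (both directions) |
| `peg_moderate` / `peg_strong` | 0.25 / 0.1 | PEG θ̂ thresholds (both directions) |
| `q_cut` | 0.05 | BH-FDR level of the departure test |
| `null_maternal_proportion` | 0.5 | ploidy null (2/3 for triploid endosperm) |

`min_reads = 10` has no published counterpart; it exists to stop θ̂ being
reported from a handful of reads, and genes must be estimable in **both**
directions to enter testing (otherwise they are reported `undetermined`).
Degenerate inputs are defined rather than accidental: `M + P = 0` is an
error for the test; a merged site total of 0 removes the site from that
direction; a dataset with no informative gene-assigned sites yields an
empty imprintome with a warning, not an error.

# Overlap statistics

`exact_overlap_test()` reports the sample cross-product odds ratio
`ad/(bc)` (∞ when `bc = 0` with `ad > 0`; the conditional-MLE estimate is
available via `or_method`) and an exact hypergeometric p-value: two-sided
by point-mass summation (the common exact-test convention) or the
one-sided upper tail. P-values are computed in log space internally, so
enrichments at the 1e-35 scale are represented exactly. Cross-species
comparisons (`pairwise_species_overlap()`) count in the focal species'
namespace — a focal gene with several orthologs counts once per species
pair — and species pairs without an ortholog map are reported
not-assessable (`NA`), never as zero overlap.

# What the simulator emulates — and what it does not

`sim_config()` defaults describe the reciprocal-cross study design the
package targets: two polymorphic diploid parents, 1000 genes, 5% planted
MEGs at true θ = 0.95 and 5% PEGs at θ = 0.05 against a 0.5 null, three
replicate libraries per cross direction, and per-site per-library depth
with mean 50. Informative-site counts per gene are negative binomial
(mean 5, size 8: a few genes have no usable site, as in real data);
categories are drawn with mix 0.40/0.225/0.225/0.15
(reciprocal-hom / mother-het / father-het / uninformative), reflecting
that between two outbred individuals single-parent heterozygous sites are
collectively about as common as reciprocal homozygous ones. Allelic counts
are beta-binomial with intraclass correlation `overdispersion`
(default 0.01; 0 degenerates to binomial), the standard noise model for
allele-specific counts. `contamination` mixes in reads drawn from the
*maternal sporophytic* genotype — seed-coat or perisperm carry-over, the
realistic failure mode of endosperm dissection. Its diagnostic signature
is an inflated null: the observed maternal fraction at a
reciprocal-homozygous site has expectation `(1−ρc)·θ + ρc`, so at
ρc = 0.3 an all-null dataset's mean θ̂ rises above 0.6 — checked in the
test suite, and worth checking in any real dataset whose dataset mean
drifts well above 0.5.

Depth is drawn per site (negative binomial, size 10), so genes vary in
information content. All randomness flows from `seed`; each generator
stage uses its own derived stream, fixtures embed the seed in the VCF
header, and byte-identical regeneration is tested.

The simulator does **not** emulate read-level artefacts (mapping bias
between alleles, PCR duplicates, genotyping error in the parents),
isoform-level variation, linked-site correlation beyond the shared gene
θ, or dosage effects of interspecific crosses. Passing recovery tests
therefore demonstrate the statistical machinery is correct under the
declared noise model — not that any particular real dataset is free of
those artefacts.

Validation experiments sized for an ordinary laptop run (and used by the
acceptance script): ten simulation replicates of the 1000-gene default for
recovery metrics, a 500-gene all-null replicate for calibration, exact
tests enumerated up to a universe of 200 for oracle comparisons.

# Known limitations

* The chi-squared test is binomial-based; allelic overdispersion beyond
  the simulated 0.01 would make it anti-conservative. A beta-binomial
  likelihood-ratio test is the natural extension and is deliberately out
  of scope here (the reciprocal threshold rule, not the test, does most of
  the calling work at realistic depths).
* Truncation of out-of-range heterozygous-site estimates (rather than
  discarding such sites) slightly shrinks extreme θ̂; at default settings
  the effect is within the tested bias band.
* One q-value per gene (pooled directions) cannot represent a gene that is
  significant in only one direction; such genes fail the reciprocal
  threshold rule anyway.
* Maternal sporophytic contamination biases θ̂ upward for *every* gene; the
  package flags the signature through the dataset means but does not
  attempt deconvolution.
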