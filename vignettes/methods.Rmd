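---
title: "Methods: three-platform SNP concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-platform SNP concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpconcord)
```

## The problem

When the same human genomes are assayed on a whole-genome sequencer (WGS), a
targeted exome sequencer, and a genotyping array, the three platforms rarely
agree perfectly on which sites carry a non-reference allele. `snpconcord`
quantifies that agreement: it harmonizes the three call sets onto one panel
of biallelic autosomal SNP sites inside the intersection of the exome
capture target and the array probe coverage, and then accounts for every
(site, sample) triple of calls.

The unit of comparison is **alt-positivity**: a call is positive when the
genotype carries at least one non-reference allele (het or hom-alt),
regardless of zygosity. This is deliberately coarser than genotype identity
— it matches how array-validated SNP panels are used (is the variant there
or not?) and makes the three-way Venn accounting well defined even when one
platform reports hom-alt and another het.

## The concordance model

For each sample, with $O$, $H$, $P$ the sets of alt-positive sites on the
array, WGS and exome platforms:

* single-platform counts $|O|, |H|, |P|$;
* pairwise concordant counts $|H \cap O|, |H \cap P|, |O \cap P|$ — these
  **include** the triple overlap $|O \cap H \cap P|$. The alternative
  (pairwise-exclusive) reading is inconsistent with the published
  per-sample table this layout mirrors: the union reproduced by
  inclusion–exclusion
  $|O \cup H \cup P| = |O|+|H|+|P|-|HO|-|OP|-|HP|+|OHP|$
  and the support ratio below only work out when pairwise counts contain
  the triple;
* the exome-support ratio $|O \cap H \cap P| / |H \cap O|$: of the
  WGS calls the array validates, the fraction the exome platform also
  confirms;
* the 8-class Venn partition (`OHP`, `OH`, `OP`, `HP`, `O`, `H`, `P`,
  `NONE`) of the panel, per sample.

**Overall concordance** between two platforms is the fraction of
(site, sample) pairs agreeing on alt-positivity. With
`include_negatives = TRUE` (the default, matching the published overall
figures) jointly-negative pairs count as agreements and the denominator is
all pairs; otherwise the universe is pairs where at least one platform is
positive. Pairs where either platform is MISSING are excluded from the
denominator by default and surfaced in a counter (`missing_policy =
"discordant"` counts them as disagreements instead); the published
convention is unstated, so both are computable and the real-data test
reports which one matches.

**Level matrices** count sites by their alternative-allele count on two
platforms (0–24 over 12 diploid samples; HET contributes 1, HOM_ALT 2).
Perfect agreement concentrates mass on the diagonal; the off-diagonal
corners isolate systematic single-platform failures (e.g. sites never
called on one platform but hom-alt everywhere on the other).

**Commonly discordant sites** — discordant with the array reference in
*every* sample — separate systematic error (manifest strand problems,
structural variation, reference bias) from sampling noise.

## Site harmonization

The panel is frozen before any concordance computation: intersect the two
target definitions (half-open BED semantics; a 1-based site $p$ is inside
$[s, e)$ iff $s < p \le e$), keep probes inside the intersection, drop
copy-number probes, and collapse duplicate probes at one position into one
site. Every filter increments a provenance counter and the counters are
exhaustive: `n_final` equals the probe input minus each filter's removals,
so the arithmetic of a real manifest can be audited.

Two harmonization decisions matter downstream:

* **Duplicate-probe disagreement → MISSING.** Probe replicates that
  disagree are not majority-voted; the conservative call keeps
  concordance counts from inheriting a coin-flip. The disagreement count
  is preserved so the alternative can be audited.
* **Strand-ambiguous probes (A/T, C/G).** For these, the observed allele
  pair cannot be oriented from the alleles alone: homozygous observations
  read differently on the two strands (A/A vs T/T). They are resolved only
  when the manifest supplies a design-strand annotation; otherwise every
  call at the probe is MISSING and counted as manifest ambiguity. Het
  observations at such probes are strand-invariant, but the probe is
  treated as a unit — silently keeping hets while dropping homs would bias
  the allele-count matrices.
* **Absent NGS records → hom-ref.** NGS VCFs list variant sites only, so a
  panel site absent from a sample's records is read as hom-ref (switchable
  per platform). Array sources report every probed site, so absence there
  stays MISSING.

## Locus features and the discordance model

Each panel site is annotated with:

* **GC fraction** in a 101-base window (50 bases each side), clipped — not
  NA — at chromosome edges so every site stays analyzable;
* **homopolymer length**: the longest run of identical reference bases
  among the run containing the site and the runs adjacent on each side.
  The field convention is unsettled; a switch (`include_site = FALSE`)
  instead excludes the site base and merges flanking runs across it. The
  default includes the site, so the minimum is 1, consistent with
  published homopolymer distributions starting at length 1;
* **transition/transversion class** (A↔G, C↔T are transitions), with
  Ti/Tv ratios computed per concordance class, pooling (site, sample)
  pairs — a site contributes once per class it occupies in each sample,
  the only convention under which class totals are well defined.

Call discordance of an NGS platform against the array is modeled by
maximum-likelihood logistic regression on read depth, GC and homopolymer
length, after restricting to observations within ±1 SD of the platform's
mean depth (computed per platform over the input observations). Covariates
enter untransformed by default — raw units keep coefficients interpretable
— with a standardization switch. Model quality is McFadden's pseudo-$R^2$,
$1 - \ell_1/\ell_0$, which is non-decreasing over nested factor
combinations; the published factor-combination table never names its
statistic, so only this monotone-pattern reading is asserted, and raw
coefficients are exported alongside so either reading can be checked.
Complete separation is flagged (near-zero residual deviance or runaway
coefficients), never fatal. Depth comparisons between concordant and
discordant calls use a two-sided Mann–Whitney U test: exhaustive
enumeration of all $\binom{n_1+n_2}{n_1}$ labelings when both groups have
≤ 8 observations (valid under ties), a tie-corrected normal approximation
otherwise.

`percent_cv` defaults to the population SD (n denominator): that convention
reproduces every published per-sample %CV at printed precision, which the
usual $n-1$ convention does not; the sample-SD variant is a switch.

## The synthetic world

The simulator exists so every pipeline stage, including file parsing, is
testable offline with known truth. Its defaults are fixed once:

| parameter | default | why |
|---|---|---|
| samples | 12 | the study design being emulated |
| sites | 5,000 | desk-scale stand-in for ~79k real sites |
| alt allele frequency | Uniform(0.05, 0.95) | segregating sites; 12-sample allele counts span 0–24 |
| genotypes | HWE, Binomial(2, p) i.i.d. | population-genetics null |
| WGS depth | NB(mean 32.4, size 10) | the platform's reported average depth |
| exome depth | NB(mean 109, size 5) | ditto; more dispersed (capture + duplicates) |
| miss process | logit-linear in depth deficit, GC, homopolymer | the three QC covariates under study |
| exome miss betas | b0 −4.5, depth 0.02, GC 2.0, homopolymer 0.12 | GC/homopolymer-sensitive platform; concordance lands in the mid-90s |
| WGS miss betas | b0 −5.5, depth 0.08, GC 0.5, homopolymer 0.01 | depth-dominated platform; concordance ~99% |
| array no-call / miscall | 0.002 / 0.001 | high-quality genotyping array |
| CNV probes | 6 | the published count |
| duplicate probe groups | 3.2% of sites | the published rate (2,626 / 83,237) |
| manifest-flip probes | 0.25% of sites | the published ~200 / 79,143 systematic discordances |

The depth covariate is the *deficit* (mean − depth), so a positive
coefficient means low coverage raises the miss probability. A missed
alt-positive truth is emitted as hom-ref, not MISSING: the NGS fixture VCFs
contain variant records only, so a missed call manifests as an absent
record, and the pipeline's absence rule converts it back to hom-ref — the
simulator exercises exactly the failure path that under-calling platforms
produce in real data. Manifest-flip probes are planted only at
strand-ambiguous sites, since flips at other sites are self-correcting
under complement matching.

What the generator does **not** emulate: linkage disequilibrium,
population structure, read-level errors (no FASTQ/BAM), capture-efficiency
gradients correlated with GC, or genotype-calling artifacts beyond the
flat miscall rate. A green synthetic test therefore establishes that the
accounting, file round-trips and statistical machinery are correct — not
that real platforms behave like the error model.

## Numerical choices and degenerate inputs

* All randomness flows from a mandatory integer seed; identical configs
  give byte-identical fixtures. Analysis stages are seed-free.
* Multi-allelic VCF records collapse to the cohort-wise most frequent alt
  (tie → alphabetically first); genotypes with two distinct non-reference
  alleles count as het, consistent with the alt-positivity unit.
* `intersect_targets` on empty input returns an empty set, not an error;
  an all-CNV probe set yields an empty panel with a warning.
* Mann–Whitney with identical groups returns p = 1; `titv_ratio` with no
  transversions returns `Inf` flagged `undefined`.
* Logistic fits with fewer than 10 observations error; separation is
  flagged via residual deviance < 1e-6.
* `%CV` requires n ≥ 2 and a nonzero mean.

## Known limitations

* Real-data reproduction requires the study's supplementary call files,
  which cannot ship with the package; the real-data path is exercised on
  emitted synthetic fixtures in the same formats, and the corresponding
  acceptance test states this explicitly rather than passing vacuously.
* The PED/MAP reader resolves strand via the manifest; without strand
  annotations all A/T and C/G probes are conservatively MISSING, which
  depresses array call counts by roughly the ambiguous-probe fraction.
* The exact statistic of the published logistic-regression table is
  undefined in its source; only monotonicity and relative-magnitude
  patterns are checked.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_sites = 1000, n_samples = 12, seed = 42)
dir <- tempfile()
run_simulation(cfg, dir)                       # FASTA/BED/VCF/PED fixtures
bundle <- run_full_analysis(file.path(dir, "analysis.config"))
bundle$concordance_table                       # per-sample summary + %CV
bundle$overall_concordance                     # platform-vs-array fractions
bundle$stat_models$exome$logistic              # pseudo-R2 per factor set
```

Every number in the rendered tables also appears in
`report_index.json` when `out_dir` is set, so headless pipelines can
assert the whole bundle.
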