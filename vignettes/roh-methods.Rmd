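---
title: "Runs of homozygosity and genomic inbreeding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity and genomic inbreeding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohkit)
```

rohkit implements the standard chip-data workflow for characterising
autozygosity in a livestock population: sliding-window ROH detection,
four genomic inbreeding coefficients, ROH-island detection, and QTL
annotation with enrichment — together with a pedigree gene-dropping
simulator that provides exact truth for validating every stage. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the package's validation does and does not demonstrate.

## The detection model

ROH calling follows the PLINK `--homozyg` scanning semantics. Within one
individual and chromosome, every window of `window_snps` (`W`)
consecutive markers is classified: it *qualifies* if it contains at most
`window_het_max` heterozygous and `window_missing_max` missing calls.
Each marker's *hit ratio* is the fraction of qualifying windows among
the windows that contain it and lie fully on the chromosome — markers
near chromosome ends sit in fewer windows, and chromosomes with fewer
than `W` markers yield no calls at all. Markers whose hit ratio reaches
`window_threshold` form candidate runs of consecutive markers; a run is
split wherever two adjacent markers are separated by more than
`max_gap_kb`; surviving runs are emitted if they span at least
`min_length_kb` and contain at least `min_snps` markers.

Defaults (`roh_params()`) are the common 60K-chip parameterization:
`W = 49`, one heterozygous and five missing calls per window, threshold
0.05, gap 1,500 kb, minimum length 1,000 kb. Two readings of "one
heterozygous SNP per segment" circulate; we take the window-level
allowance (PLINK's `--homozyg-window-het`), and additionally expose an
optional strict per-segment cap (`max_het_per_segment`, default off) for
users who want the literal reading. Likewise `min_snps` defaults to `W`
because chip-era studies typically pass the same value to the window
size and the segment SNP floor; both are configurable. PLINK's window-kb
cap and density filters are not applied.

The window size itself comes from the Lencz false-positive bound
(`min_window_snps()`): the smallest `L` with
$L = \ln(\alpha/(n_s n_i)) / \ln(1-het)$, where $n_s$ and $n_i$ are the
numbers of genotyped SNPs and individuals, $\alpha$ the tolerated
false-positive proportion (0.05) and $het$ the mean heterozygosity.
We round half-up and floor at 1. At $n_s = 53{,}872$, $n_i = 651$ and
$het = 0.34$ this gives 49, the default; note that with a typical chip
heterozygosity in the 0.3–0.4 range the bound is insensitive to
realistic $\alpha$.

Segment length is `end_bp - start_bp` over the first/last marker
positions (the PLINK KB convention), coordinates 1-based inclusive.
Length classes are left-closed: [1,2), [2,4), [4,8), [8,16), [16,∞) Mb;
a 2.0 Mb segment is "2–4". Sub-1 Mb lengths are unclassed — they cannot
occur after the default length filter.

## Inbreeding coefficients

`F_ROH` is the summed ROH length divided by the autosomal genome length
`l_auto` (default 0.94 Gb, the chicken autosomal assembly scale), overall
and per length class; the disjoint class values sum to the overall value
per individual, and individuals without segments are kept at zero. A
caveat documented rather than resolved: published per-class tables are
sometimes averaged only over individuals *carrying* segments of a class,
which yields nonzero class minima and per-class means that do not sum to
the overall mean. We default to the all-individuals decomposition because
it is the one with an exact identity; averaging over carriers can be
reproduced by filtering the per-individual table.

`F_GRM`, `F_HOM` and `F_UNI` are the three SNP-by-SNP estimators in
GCTA's `--ibc`. The formulas are in the README; design points:

- Allele frequencies are always estimated from the current sample. This
  is the well-known limitation of frequency-dependent estimators — they
  are only unbiased when sample frequencies match the (unavailable) base
  population — and is why values below 0 and above 1 occur.
- `F_GRM` defaults to the ratio-of-sums (VanRaden) form; GCTA's diagonal
  is per-SNP, so a `mean_of_ratios` variant is exposed as well. The two
  differ whenever MAF varies across markers.
- Monomorphic markers are excluded where they are undefined (`F_GRM`,
  `F_UNI`); for `F_HOM` they cancel exactly and are harmless.
- Missing calls are handled per individual: both numerator and
  denominator sums run over that individual's non-missing markers.
- A MAF ≥ 0.05 filter is applied before the SNP-by-SNP estimators but
  never before ROH calling: rare and fixed sites carry the homozygosity
  signal that ROH detection needs, while frequency-based estimators are
  dominated by noise at tiny `2pq` denominators.

Quality control mirrors chip practice: autosomes only, call rate ≥ 0.9,
exact Hardy–Weinberg p > 10⁻⁶ (the standard conditional exact test, not
mid-p, not chi-square — matching PLINK's `--hwe`), optional MAF. The
filter order (autosome → call rate → HWE → MAF) is fixed so removal
counts are reproducible. Call-rate and MAF thresholds are inclusive
(keep ≥), the HWE threshold exclusive (keep >), following the usual
"p-value > 10⁻⁶" phrasing.

## ROH islands

Per-SNP incidence counts the individuals whose ROH cover each marker
position (one count per individual). Counts are standardized genome-wide
and markers in the upper 0.1% tail — z above Φ⁻¹(0.999) ≈ 3.0902,
strictly — are merged into islands: maximal runs of consecutive
qualifying markers, split at gaps over 1,500 kb (the same gap rule as
ROH calling; no merge rule is standard, so we reuse the detector's).
Because incidence distributions on strongly swept genomes are far from
normal, an empirical-quantile alternative (`method = "empirical"`) is
provided; on skewed tracks the two thresholds differ and the z-score
rule is the package default only because it is the rule most chip
studies state. One structural fact worth knowing: on a two-valued track
(sweep present/absent) the z-score is bounded by $\sqrt{(1-f)/f}$ for
sweep fraction $f$, so sweeps covering more than ~9% of markers can
never clear the 0.999 cut — the rule is designed for *rare* shared
regions. A constant track has no threshold: the package warns and
returns zero islands rather than erroring.

Annotation treats all intervals as 1-based closed; features abutting an
island boundary by one base overlap. BED output is converted to 0-based
half-open on write only. QTL trait-class enrichment is a hypergeometric
upper-tail test over distinct QTL identifiers (database = population,
class members = successes, island-overlapping QTLs = draws) with
Benjamini–Hochberg adjustment across classes. Published chip studies
typically report only "adjusted p < 0.05" without naming the test; the
hypergeometric-within-database reading is our interpretation and is
calibrated under the null by simulation in the test suite.

## The simulator: what it emulates and what it does not

`gene_drop()` drops labelled founder haplotypes through a pedigree.
Founders are unrelated and in linkage equilibrium: each marker's allele
frequency is drawn once from `maf_law` (default uniform on [0.05, 0.5],
a typical post-QC chip spectrum), then haplotype alleles are independent
Bernoulli draws. Meioses follow the Haldane model — crossover count
Poisson with mean equal to the chromosome map length, positions uniform,
no interference — at a uniform 1 cM/Mb (configurable per chromosome).
Ancestry labels are tracked per chromosome *segment*, not per marker, so
true autozygous intervals have exact basepair breakpoints; realized
autozygosity is the labelled-IBD fraction of the genome, and
`expected_f_pedigree()` gives Wright's path-counting coefficient
(computed by the recursive kinship formulation). Genotyping error and
missingness injectors (default 0) exist so the caller's heterozygote and
missing allowances can be exercised. `plant` forces chosen intervals to
one shared founder haplotype in chosen individuals — the mechanism
behind both the toy fixture's known 5 Mb autozygous segment and the
planted-sweep island tests.

What the simulator does not emulate: linkage disequilibrium and
haplotype structure among founders (real chips have both), coalescent
"background" autozygosity from ancient shared ancestry, ascertainment
bias of chip SNPs, non-uniform recombination (chicken macro- and
micro-chromosomes differ several-fold), mutation and selection. Passing
validation on gene-drop data therefore demonstrates that the detector
and estimators recover *pedigree-scale* autozygosity with calibrated
ROH-length physics; it does not certify behaviour on ancient, short,
LD-driven homozygosity, which is exactly the regime where medium-density
chips are known to overestimate short ROH counts.

Default geometry: `study_map()` is a 28-autosome karyotype rescaled to
0.94 Gb at 57 SNPs/Mb, matching the genome the default `l_auto` assumes;
markers sit on a regular grid (deterministic fixtures). Validation runs
use 5 × 40 Mb chromosomes at the same density — large enough that a
49-SNP window (~0.86 Mb) and the 1 Mb length floor are exercised at
scale, small enough that a full four-design recovery study (500
independent families each at expected F = 0, 0.125, 0.25, 0.5; about
11,400 markers) runs in a couple of minutes. The toy fixture is 42 birds
over four generations on 5 × 7 Mb.

## Numerical choices and degenerate inputs

- HWE exact test: probabilities are computed in log-space and
  renormalised; configurations are included when their probability is at
  most the observed probability times (1 + 10⁻¹²), guarding against
  ties lost to floating point. Monomorphic markers give p = 1; all-zero
  counts are an error.
- Lencz rounding is half-up (`floor(L + 0.5)`), floored at 1.
- The hit-ratio comparison is `>=` on the threshold; island
  qualification is strict `>` on the z cut (ties at the island threshold
  are excluded by the "top 0.1%" phrasing; ties at the hit-ratio
  threshold are included).
- `F_HOM` with a degenerate denominator (all markers monomorphic for an
  individual's non-missing set) is flagged `NA` with a warning rather
  than silently dropped.
- Zero-variance estimator columns produce `NA` correlations with a
  warning; correlations use pairwise-complete observations.
- `apply_qc()` on a fully filtered panel warns ("empty result") instead
  of erroring, and `apply_qc()` is idempotent by construction since
  marker statistics do not change when markers are removed.
- All randomness flows through explicit integer seeds; every simulator
  output is a pure function of (pedigree, map, frequency law, seed).

## Known limitations

- The PED/MAP reader infers A1 as the minor allele (ties broken
  alphabetically); round trips through text lose the original A1/A2
  orientation when A1 was the major allele. The binary format preserves
  orientation exactly and is the recommended interchange.
- The ROH caller is the sliding-window heuristic, not a model-based
  (HMM) caller; sex chromosomes are out of scope.
- Enrichment treats QTL records as exchangeable units; overlapping or
  nested QTL intervals in real databases violate independence in ways
  the hypergeometric model ignores.
- `estimator_correlations()` is plain Pearson on whatever numeric
  columns are present; it does not partial out generation structure.
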