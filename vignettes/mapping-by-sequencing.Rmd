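---
title: "Mapping-by-sequencing with phenotype-selected pools: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing with phenotype-selected pools: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

# The genetic model

`bsamap` implements bulked segregant analysis (BSA) by pooled whole-genome
sequencing for a recessive point mutant recovered from a chemically
mutagenized plant population, of the kind produced by NMU treatment of the
C4 model grass *Setaria viridis*. The mutagenized line carries a set of
induced SNPs, strongly biased towards transitions, all homozygous; exactly
one of them — a C→T change at the first position of a CTC/CTT leucine codon,
producing a Leu→Phe substitution — is causal for a recessive phenotype
scored by chlorophyll fluorescence (dark-adapted
$F_v/F_m = (F_m - F_o)/F_m$, mutant iff $F_v/F_m < 0.6$).

The mutant is crossed to wild type and the F1 selfed, giving a BC~1~F~2~
population in which every induced SNP segregates 1:2:1 and the phenotype
segregates 3:1 (25% mutant). Three DNA pools are sequenced:

* **mutant pool** — 45 phenotype-mutant individuals, all homozygous at the
  causal locus (up to phenotyping error);
* **azygous pool** — 54 phenotypically wild-type segregants
  (1 homozygous-reference : 2 heterozygous at the causal locus);
* **wild-type pool** — 50 un-mutagenized plants, carrying none of the
  induced alleles.

For a marker at recombination fraction $r$ from the causal locus, with
perfect phenotype selection, the expected frequency of the mutant-line
allele among pooled chromosomes is

$$\mathrm{AF}_{\text{mutant}}(r) = 1 - r,\qquad
  \mathrm{AF}_{\text{azygous}}(r) = \frac{1 + r}{3},\qquad
  \mathrm{AF}_{\text{wildtype}} = 0 .$$

At $r = 0$ these give the association signature the candidate filter keys
on: fixed (AF = 1) in the mutant pool but ≈ 1/3 in the azygous pool.
`expected_pool_af()` returns these values; the test suite verifies them
against an exhaustive enumeration of the 16 ordered F1 gamete pairs in
exact integer arithmetic, on a grid of 11 recombination fractions.

Crossovers follow the Haldane model: a Poisson number of exchange points
per chromosome per meiosis (`recomb_rate`, in Morgans), positions uniform,
no interference. Map distance $d$ between two sites converts to a
recombination fraction by $\tilde r = (1 - e^{-2d})/2$ (`haldane_r()`).
Haldane was chosen over interference models because closed-form
expectations exist for every linked-site quantity the tests check.

# The synthetic experiment

`generate_reference()` builds i.i.d.-uniform ACGT chromosomes carrying
non-overlapping toy genes (1–3 exons, random strand) whose spliced CDS is
constructed codon-wise: ATG, a run of non-stop codons, one stop. Every
emitted model therefore translates to Met…Stop with no internal stop — an
invariant the suite asserts rather than assumes.

`induce_mutations()` places `n_mutations` SNPs uniformly without
replacement; alternative alleles are transitions with probability
`transition_fraction` (default 0.9, reflecting the strong transition bias
of alkylating mutagens), otherwise a random transversion. The causal SNP
is forcibly placed at codon position 1 of a CTC/CTT codon so its coding
consequence is the Leu→Phe missense the design assumes.

`breed_bc1f2()` forms each individual from two independent F1 gametes,
assigns the phenotype from causal dosage, flips it with probability
`misclassification` (default 0.01, modelling screening noise), and draws
$F_v/F_m$ from phenotype-conditional normal distributions truncated to
(0, 1): wild-type-like mean 0.69, sd 0.05; mutant mean 0.45, sd 0.07.
These defaults put the two classes on either side of the 0.6 cutoff with
a small, realistic overlap; they are configuration, not claims about any
particular instrument. Under them the cutoff classifier's analytic
accuracy against the truncated-normal mixture is ≈ 96.9%, and the test
suite checks the simulation against that analytic value (not against a
round number).

`simulate_pool_reads()` draws, per pool and site, a depth
Poisson(mean ~ Uniform(`coverage_range`)) — default 45–65× — and an
alt-read count Binomial(depth, $p$) with
$p = f(1-e) + (1-f)e$, where $f$ is the pool's true dosage fraction and
`seq_error` $e$ (default 0.001) is the per-read allele miscall rate.

**Pooled GT/GQ model.** Per-pool genotype calls use three hypotheses for
the pool alt fraction — ≈ 0, 0.5, ≈ 1 (each shifted by $e$) — with GT the
maximum-likelihood call and GQ the Phred-scaled ratio of the two best
likelihoods, capped at 99. This is a deliberate simplification of a
diploid caller's GQ applied to pooled data: it is monotone in the
evidence, and it reproduces the familiar ≈ 3 Phred per supporting read for
homozygous calls, which is exactly the regime in which a "≥ 10 reads and
GQ ≥ 30" filter pair is coherent (10 clean reads ↔ GQ ≈ 30). A
likelihood ratio over a fine grid of $2N + 1$ pool fractions was
considered and rejected: adjacent grid points differ by
$\sim e^{-\mathrm{dp}/2N}$ in likelihood, so the ratio is a few Phred at
any realistic depth and a GQ ≥ 30 threshold would discard every variant.

Every operation takes an explicit seed and documents its draw order;
`run_end_to_end()` derives fixed per-stage seeds from one master seed, so
a run is bit-reproducible and stages can be re-run alone.

# Filtering and candidate selection

`apply_quality_filters()` implements the published screen on the mutant
pool: discard a variant if its mutant-pool AF is ≤ 0.3 (alignment-artifact
rule, inclusive threshold), its used depth (`ad_ref + ad_alt`) is < 10, or
its GQ is < 30. Drop counts attribute each removal to the first matching
rule in the fixed order af, depth, gq, so reports are reproducible.
The artifact rule is applied to the mutant pool only: applying it to
"any pool" would be self-defeating, since the wild-type pool shows AF = 0
(≤ 0.3) at every genuine induced variant and the azygous pool hovers at
≈ 1/3. Whether the GQ rule also covers the other pools is left as
configuration (`gq_scope`), defaulting to mutant-only.

`select_candidates()` keeps variants with mutant-pool
AF ≥ `mutant_af_min` − `mutant_af_tolerance`, azygous-pool AF strictly
below 0.5, and (by default) no evidence in the wild-type pool.

**Strict defaults vs. pipeline defaults.** `filter_config()` defaults to
the strict published thresholds: exact AF = 1.0 and wild-type AF ≤ 0.
`run_config()` instead builds its filter with `mutant_af_tolerance = 0.1`
and `wildtype_af_max = 0.05`, because the generator's default error rates
make the strict rule fragile by arithmetic, not by bad luck: one
misclassified individual in the 45-plant mutant pool caps the true dosage
fraction at 88/90 ≈ 0.978 (and ≈ 1% phenotyping error contaminates the
pool in most runs), while at 50× a 0.1% per-read error leaves the
wild-type pool with at least one spurious alt read at ≈ 5% of sites. The
tolerances are set where those failure modes are absorbed but unlinked
sites (pool fraction ≈ 0.5, many standard deviations below 0.9) remain
excluded.

`linkage_consistency()` scores each candidate by the fraction of
neighbouring variants (± `window_bp`, minimum 3 neighbours) whose
mutant-pool AF is ≥ 0.8 — a truly linked causal site sits inside a
plateau of near-fixed variants, while an isolated artifact does not.

# Region scan

`window_af_profile()` averages per-variant mutant-pool AF in windows
tiling each chromosome at a fixed step (0-based half-open internally;
1-based inclusive on every report boundary, with the conversion
centralized and tested both ways). `detect_peak_region()` takes the
longest run of ≥ `min_windows` consecutive windows with mean AF ≥ 0.9;
empty windows break runs (conservative bounds rather than interpolation),
ties go to the leftmost run and peak window.

When no window size is given it auto-scales to **1/20 of the chromosome
length** with a step of 1/5 window. The scale is set by the empty-window
risk: with the default density of 300 SNPs over 10 Mb, a 1/50 window
(100 kb) holds ~3 variants on average, so ≈ 5% of windows are empty and
the plateau fragments into short runs; at 1/20 (250 kb, ~7.5 variants)
the empty-window probability is ~5 × 10⁻⁴ and runs stay contiguous. At
full genome scale users should pass the classic 1 Mb window / 100 kb step
explicitly.

# Effect annotation

`locate_variant()` classifies positions against gene models (CDS,
intronic, intergenic; overlapping genes yield all contexts), computing the
0-based offset into the spliced CDS in translation orientation —
minus-strand genes keep genomic coordinates and are
reverse-complement-resolved at this step. `annotate_effect()` does the
phase-aware codon arithmetic under the standard genetic code (hard-coded
and unit-tested against an independently published table) and classifies
changes as synonymous, missense, nonsense, stop_loss or start_loss;
a reference-base disagreement with the genome raises an error, because it
always signals a coordinate bug. Variants at exon–intron boundaries are
classified by their own base's location; splice-site prediction is out of
scope. When several transcripts exist, `read_gff3(keep = "longest")`
selects the longest CDS.

The whole annotator is property-tested against a brute-force oracle that
rebuilds the mutant chromosome, re-splices and translates both alleles
with an independent library route, and diffs the proteins — over a
thousand random variants across both strands and multi-exon genes.

`annotate_candidates()` ranks: nonsense/start_loss > missense >
synonymous > intronic > intergenic, ties by linkage score then position.
A tightly linked coding passenger can therefore legitimately outrank the
causal missense in a small fraction of runs — the same ambiguity that, in
real data of this design, is resolved with external expression evidence;
an exclusion list can be applied by filtering the candidate table before
annotation.

# Companion calculators

*Fluorescence.* `fluorescence_params()` computes
$F_v/F_m$, $F_v'/F_m'$, $\Phi_{PSII} = (F_m' - F')/F_m'$,
$qP = (F_m' - F')/(F_m' - F_o')$ and $NPQ = F_m/F_m' - 1$, each only when
its inputs are present, with validation errors naming the offending field.
The boundary $F_v/F_m = 0.6$ classifies as wild-type-like (strict `<` for
mutant), matching the screen's "reduced" phrasing; the convention is
asserted in the tests.

*Segregation.* `segregation_test()` is a Pearson chi-square (1 df)
against the 1/4 recessive expectation, without Yates correction by
default (the design operates at n ≈ 300; the correction is available as a
flag). The p-value comes from the chi-square survival function via
`stats::pchisq`.

*Isotope discrimination.* `delta_from_ratio()` implements
$\delta_p = R_p/R_s - 1$ against the PDB standard and `discrimination()`
implements $\Delta = (\delta_a - \delta_p)/(1 + \delta_p)$, identically
equal to $R_a/R_p - 1$; the identity is tested to ≈ 10⁻¹² over 10⁴ random
ratio triples. The air composition default is −8‰
($\delta_a = -0.008$), a configuration constant. The API works in
dimensionless fractions only; `as_permil()`/`from_permil()` are the sole
unit converters, which prevents thousand-fold unit mistakes.

# Problem sizes and what the tests do (and do not) show

The packaged checks run the full design at a reduced genome scale chosen
for statistical sufficiency: 2 chromosomes × 5 Mb with 300 induced SNPs
and 50× pools for the 100-seed end-to-end recovery study; 1000 populations
of 300 for segregation; 200 replicate populations for the linked-site AF
law at map distances 0, 0.1 and 0.25 Morgans; ≥ 1000 random variants for
the annotation oracle. Monte-Carlo tolerances are three standard errors
throughout.

The generator emulates the statistical structure the analysis relies on —
Mendelian segregation, Haldane linkage, transition-biased induced SNPs,
binomial pooled read sampling, phenotyping noise. It deliberately omits
natural standing variation, alignment and mapping artifacts, indels and
copy-number events, and read-level error correlation. Passing tests
therefore demonstrate that the filtering/scan/annotation logic recovers a
causal variant whenever the pooled-count model holds; they do not certify
performance on real alignments, where the AF ≤ 0.3 artifact rule and the
wild-type pool exclusion carry the burden the simulator does not model.
Real-data figures of this design (candidate counts, region sizes, peak
positions) depend on those unmodelled features and on genome-scale read
sets, and are reproduced here only qualitatively.
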