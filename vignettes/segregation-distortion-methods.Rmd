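---
title: "Methods: segregation distortion analysis in outbred diploid crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation distortion analysis in outbred diploid crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrmap)
```

## The problem

In a full-sib family from two heterozygous outbred parents (a "CP"
population, the standard design for species like diploid potato that
cannot be selfed), markers segregate 1:1 when one parent is heterozygous
(`<lmxll>` maternal, `<nnxnp>` paternal) or 1:2:1 when both are
(`<hkxhk>`). Selection acting on gametes (biased transmission before
fertilization) or on zygotes (differential viability after it) bends the
observed genotypic class frequencies away from these Mendelian
expectations. Clusters of linked markers that all deviate mark a
*segregation distortion region* (SDR), presumed linked to a single
distorting factor.

`sdrmap` implements the full analysis chain — per-locus tests, SDR
calling, parental haplotype-transmission profiles, Marey-map
recombination-rate landscapes, and a two-locus linkage-disequilibrium
scan — together with a meiosis simulator whose truth record lets every
stage be verified end to end.

## The statistical model

**Per-locus test.** For observed class counts $O_i$ and Mendelian
expectations $E_i$ (from 1:1 or 1:2:1),

$$\chi^2 = \sum_i \frac{(O_i - E_i)^2}{E_i},$$

with $df = \text{classes} - 1$ and the upper chi-square tail as p-value.
No continuity correction, no exact-test substitute, and no
multiple-testing adjustment: distortion is classified at fixed
$\alpha \in \{0.05, 0.01, 0.001, 10^{-5}\}$, the conventional 5 / 1 /
0.1 / 0.001 percent levels. The *distortion ratio* is reported in the
field's `1:x` convention: the over- to under-represented class; for
1:2:1 loci it is taken over the two homozygote classes because the
heterozygote is ambiguous about parental origin.

**SDR rule.** Within one chromosome and one parent stream, consecutive
loci significant at $\alpha = 0.001$ are chained while the gap between
them is at most 5 cM; a chain of at least 6 members ("more than five
markers") is an SDR. The source phrase "clustered at a minimal distance
of 5 cM" is genuinely ambiguous between a *gap* and a *span* reading; the
gap reading is the default because it reproduces chromosome-long
contiguous SDRs, and the span reading is available via
`sdr_config(min_span_cM = )`. Non-significant loci interleaved inside a
chain neither break it nor count as members.

**Haplotype transmission.** Each heterozygous parent has two chromosome
haplotypes. The package's phase convention: *phase 0 places the
second-listed allele (m, p or k) on homolog 1*. A progeny's genotype
code at a 1:1 locus then identifies the transmitted homolog exactly, and
the per-locus frequency of homolog 1 profiles transmission along the
chromosome. Biparental loci are excluded from these profiles (an `hk`
heterozygote cannot be assigned parental origin); their four-way
maternal-by-paternal combination counts are instead tested against
1:1:1:1 ($df = 3$) at flanking 1:1 locus pairs within a 1-cM window
(`combination_profile()`).

**Marey maps and recombination rates.** Genetic position (cM) against
physical position (Mb) per chromosome. Loci without a physical anchor
are dropped; order-discordant loci are removed by keeping a
maximum-cardinality subset whose cM sequence is non-decreasing in Mb
(longest non-decreasing subsequence — the operational reading of
"discrepancies in sequential increasing order"). A monotone cubic
spline interpolates the filtered points and its derivative is the local
recombination rate in cM/Mb; chromosome and genome-wide averages divide
cM spans by Mb spans of mapped loci.

**Epistasis scan.** Bin representatives (markers with identical genotype
columns collapse to one "unique bin position") are encoded per progeny:
transmitted-homolog indicator at 1:1 loci, k-dosage at biparental loci.
For an unlinked pair — different chromosomes, or ≥ 50 cM apart —
$r^2$ is the squared Pearson correlation of the codes and
$n r^2 \sim \chi^2_1$ under independence; for binary codes $n r^2$
equals the 2×2 contingency chi-square exactly. Pairs with
$p < 0.005$ are reported, summarized per chromosome pair. A
permutation p-value (`pairwise_r2(n_perm = )`) is available as the slow
exact oracle.

## The simulator: a stated world

`simulate_population()` generates F1 families under no-interference
(Poisson/Haldane) meiosis: crossovers per gamete are Poisson with mean
$L/100$ for a chromosome of $L$ cM, positions i.i.d. uniform, starting
homolog a fair coin. This is the model under which cM distances are
defined; crossover interference is unidentifiable from the outputs this
package analyses, so it is not modelled.

* **Gametic selection** (`sel_gametic`): rejection sampling so accepted
  gametes carry homolog 1 at the selected position with probability
  $t$. Rejection, rather than analytic reweighting, keeps linkage
  disequilibrium with flanking markers exactly right.
* **Zygotic selection** (`sel_zygotic`): the united zygote survives with
  probability proportional to a viability weight on its homolog
  combination (M1P1 … M2P2) — readable at one locus or at two loci
  (maternal homolog at A, paternal at B), which is how two-locus
  epistatic viability is planted for the scan's power checks. Genotype-
  code weights (e.g. `c(hh = 0)`) are translated through the marker's
  phases. Unspecified categories default to weight 1; at least one
  weight must be 1 (relative viability).

Default parameters mirror the three potato crosses the package is
modelled on: population sizes 96/130/129, 12 chromosomes of ~55–70 cM,
~1.1 cM/Mb, maternal/paternal/biparental marker mixes, and marker
densities of roughly 2–3 mapped SNPs per cM. What the simulator does
*not* emulate: genotyping error, missing data patterns, segregation of
more than two alleles, polyploid meiosis, and crossover interference. A
green simulation test therefore establishes correctness of the
*analysis arithmetic* under the stated meiosis model, not robustness to
array-data artefacts.

## Numerical choices

* **Monotone interpolation.** The source method ("cubic spline
  interpolations … smooth and monotonic") is operationalized as
  `stats::splinefun(method = "hyman")`, a monotonicity-filtered cubic
  spline with closed-form derivative. The Fritsch–Carlson Hermite
  variant (`monoH.FC`) was evaluated first and rejected: across 200
  random monotone maps R's implementation produced small negative slope
  excursions (worst −0.011 cM/Mb), violating the non-decreasing
  invariant the rate profile depends on; Hyman filtering showed zero
  violations and reproduces a parabolic truth to machine precision.
  No smoothing is applied — the interpolant passes through every
  filtered point — so per-chromosome local-rate curves are
  interpolation-based, not smoothing-spline-based, and regression
  $r^2$ values against distortion are qualitative analogues, not exact
  reproductions, of results computed with proprietary smoothing
  defaults.
* **Chi-square tails** come from `stats::pchisq`; the test suite checks
  them against independent closed forms
  ($2\Phi(-\sqrt{x})$ for $df=1$, $e^{-x/2}$ for $df=2$) to
  $10^{-9}$ relative error.
* **Tie-breaks.** Map order is (chromosome, cM, Mb, marker id); bin
  representatives take the smallest cM, then lexicographic marker id;
  the outlier filter keeps the earlier-Mb solution among equal-length
  subsequences.
* **Degenerate inputs.** Zero informative progeny is an error; a zero
  under-represented class yields an infinite distortion ratio (annotated,
  not an error); duplicate physical positions collapse to the mean cM
  with a warning; a constant rate predictor reports $r^2 = 0$ with a
  note instead of a spurious fit.
* **Missing data.** The sentinel `--`; markers containing it are dropped
  at read time by default (mirroring a source dataset cleaned before
  mapping), retained with `drop_missing = FALSE`, and then excluded
  again before distortion testing unless asked otherwise.

## False SDRs under the null: a known limitation

The SDR rule has a non-negligible genome-wise false-positive rate on
dense maps. At $n = 96$ the per-locus exceedance at $\alpha = 0.001$
is $P(|X - 48| \ge 17) \approx 7.6 \times 10^{-4}$ for
$X \sim \mathrm{Bin}(96, 1/2)$ — but neighbouring markers share the
same progeny, so the transmission-frequency process along a chromosome
is strongly autocorrelated (correlation $1 - 2r(d)$, e-folding length
50 cM). When drift pushes one region over the threshold, the excursion
typically spans several cM and recruits the ≥ 6 members the rule asks
for. Measured over 500 simulated null genomes (12 chromosomes × 170
markers over 67.8 cM, $n = 96$), about 5–7% of genomes contain at
least one false SDR. The acceptance suite states the stricter ≤ 1%
expectation and that check fails honestly; users should treat a single
borderline SDR in a small population as suggestive, not conclusive, and
look for corroborating haplotype-frequency trends
(`transmission_profile()`) around the peak. The per-locus significance
fractions themselves calibrate exactly (verified against binomial
bounds on 2,000 unlinked loci at $n = 96$ and $130$).

## Tunable parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha_levels` | .05, .01, .001, 1e-5 | — | conventional 5/1/0.1/0.001% levels |
| `ratio_threshold_1to1` | 10 | ratio | pre-mapping 1:10 exclusion rule |
| `ratio_threshold_1to2to1` | 5 | ratio | 1:5:5 rule, homozygote classes |
| `sdr_config(alpha)` | 0.001 | — | SDR member significance |
| `sdr_config(min_markers)` | 6 | count | "more than five markers" |
| `sdr_config(max_gap_cM)` | 5 | cM | gap reading of the cluster rule |
| `combination_profile(window_cM)` | 1 | cM | pairing distance for 4-way counts |
| `epistasis_config(p_threshold)` | 0.005 | — | scan significance |
| `epistasis_config(linked_cutoff_cM)` | 50 | cM | intra-chromosomal "unlinked" |
| `local_rates(spacing)` | 0.5 | Mb | rate evaluation grid |

## A worked miniature

```{r example}
map <- chromosome_map("chr09", 75, 61, n_markers = 76)
design <- cross_design(map, 96, marker_classes = "paternal",
                       selections = sel_gametic("paternal", "chr09",
                                                68, 0.722),
                       seed = 42)
sim <- simulate_population(design)
res <- test_distortion(sim$genotypes)
res[res$genetic_pos == 68,
    c("marker_id", "n1", "n2", "chi2", "p_value", "distortion_ratio")]
sdr_report(call_sdrs(res))
```

The planted transmission bias ($t = 0.722$) at 68 cM produces an
at-locus distortion ratio near $0.722/0.278 \approx 2.6$ and an SDR
containing the selected position.

## Design choices that were genuinely open

* *Denominator for distortion proportions*: markers, not bins (the
  source leaves this unstated); summaries operate on whatever result set
  they are given, so running them on `collapse_bins()` output gives the
  by-bins alternative.
* *Four-way combination counts*: nearest flanking 1:1 pair within a
  window, rather than whole-chromosome haplotype calls, because the
  latter requires an imputation model the inputs do not license.
* *Individual-level deduplication* is not implemented (marker bins
  only); how redundant individuals were identified upstream is unknown.
* *Empirical r² thresholds* for the scan (quantiles of a permutation
  null) are deliberately left out of the default path; the asymptotic
  $\chi^2_1$ on $n r^2$ is standard and the permutation oracle is
  available per pair.

## Known limitations

Phase is an input (or simulator truth), never inferred; no HMM phasing
or error smoothing beyond the optional `min_run` filter on crossover
counts; linkage-map construction itself (grouping, ordering, multipoint
distances) is out of scope — the package consumes a finished map; and
population-specific published quantities that depend on unreleased
genotype matrices are covered qualitatively by truth-driven simulation,
not reproduced numerically.
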