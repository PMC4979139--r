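---
title: "Estimating the recombination landscape of Eucalyptus globulus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the recombination landscape of Eucalyptus globulus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eucrr)
```

## The problem

Meiotic recombination rate (RR) — genetic distance per unit of physical
distance, in centimorgans per megabase — varies between individuals, between
chromosomes, and along chromosomes, and this variation shapes diversity,
selection efficacy and genome evolution. In forest trees, direct genome-wide
estimates are scarce. `eucrr` implements the full analysis for *Eucalyptus
globulus*: linkage maps built in 10 unrelated parents (three F1 and two
outbred F2 pedigrees, 172–503 progeny each) with dominant DArT and
microsatellite markers anchored to the 11 main scaffolds of the *E. grandis*
reference genome, giving one RR per parent × chromosome, and a statistical
battery relating the chromosome-level variation to genomic features.

The package has three layers:

1. **Fixtures** — the per-parent map summaries (110 records) and the
   chromosome attribute table (11 records), shipped as checksummed TSVs so
   every downstream statistic is reproducible without external data.
2. **Estimation pipeline** — CIP/CALP BLAST anchoring, two-point
   recombination-fraction estimators, Haldane map distances along the fixed
   physical order, and the interval/selection filters.
3. **Statistics** — balanced two-way fixed-effects ANOVA with Type-3 sums of
   squares, Tukey-Kramer HSD with a compact letter display, Pearson and
   first-order partial correlations, pooled t-tests.

A meiosis simulator with a known recombination landscape closes the loop:
the estimation pipeline is validated by parameter recovery, not only by
reproducing printed numbers.

## RR at three scales

For one parent and chromosome, RR is the ratio of the linkage-group length to
the anchored physical span, `total_cm / phys_mb` (`chromosome_rr()`). We
recompute this ratio at full precision rather than reusing the printed
2-decimal column: the printed numerator and denominator carry more information
than the rounded quotient, and all reproduced statistics agree with the
printed ones within rounding.

At the genome scale two different statistics coexist, and they do not agree:

* `genome_rr()` pools: the summed genetic length over the summed physical
  span, i.e. the physical-size-weighted mean of the 11 chromosome rates
  (2.61–3.34 cM/Mb across parents, mean 2.85).
* `parent_mean_rr()` averages the 11 chromosome rates with equal weight
  (2.71–3.51 cM/Mb, mean 2.98, CV 0.08).

The individual-level results of the study (its 2.98 mean and 2.71–3.51 range)
are the **unweighted** statistic: each chromosome contributes equally, so
small, recombination-rich chromosomes are not down-weighted by their size.
The package exposes both and uses `parent_mean_rr()` wherever the
individual-level summary is reproduced; the pooled ratio remains available
because it answers a different question (expected RR per physical megabase).

```{r scales}
maps <- load_table2()
parents <- parent_mean_rr(maps)
descriptive_stats(parents$mean_rr)[c("min", "max", "mean", "cv")]
genome_rr(subset(maps, parent_id == "F1.1-F"))$rr   # pooled, one parent
```

Cross-parent chromosome means (`chromosome_means()`, n = 11) are the inputs
to every correlation; they require the balanced 10 × 11 table and reproduce
the attribute-table RR column to ±0.01.

## The statistical battery

**ANOVA.** The 110 RR values are modelled as parent + chromosome fixed
effects with no interaction (each cell holds one observation, so an
interaction would saturate the model). Type-3 (marginal) sums of squares
equal sequential sums of squares in this balanced design; `anova_two_way()`
asserts this numerically via `drop1()` rather than assuming it, and refuses
unbalanced input, where the two decompositions genuinely differ and the
contract would be ambiguous.

```{r anova}
maps$rr <- chromosome_rr(maps$total_cm, maps$phys_mb)
anova_two_way(maps, "rr", "parent_id", "chromosome")
```

**Tukey-Kramer.** Pairwise chromosome comparisons use the studentized range
with the ANOVA residual mean square (10 replicates per chromosome, 90 df).
Letters come from the insert-and-absorb algorithm; levels sharing a letter
are not significantly different at α = 0.05. Chromosomes 10, 1 and 6 share
the top group and 3 and 5 the bottom one.

**Correlations.** Chromosome mean RR is correlated (Pearson, n = 11) with
scaffold length, GC content, gene density, transposable-element density, the
tandem-duplicate proportion, pooled six-species diversity (H~Hw~) and
between-species divergence (F~st~). First-order partial correlations
(`partial_corr()`, t on n − 3 df) remove the influence of chromosome size;
correlation against the length column itself uses the Mb scaffold lengths
(Pearson correlation is scale-invariant, so Mb vs bp is immaterial). The
size-adjusted ANOVA variant sometimes quoted alongside these results is not
implemented: a per-chromosome size covariate is collinear with the chromosome
factor, and no unambiguous model reproduces the stated degrees of freedom.

## The estimation pipeline

**Anchoring.** Marker sequences are located on the reference from BLAST
tabular output. For each marker, HSPs on one scaffold and strand within a
10 kb window (configurable; the clustering rule is our own, as only the
scoring criteria are standard) form a candidate locus scored by

* CIP, the alignment-length-weighted mean percent identity over the locus,
* CALP, 100 × (summed HSP length) / (query length).

Loci with CALP > 200 % are discarded (alignments covering the query more
than twice over indicate repetitive or chimeric matches); the highest CIP
wins, ties fall to the higher CALP, and any remaining tie is either broken by
the candidate minimising the implied local RR (when a map context is
supplied) or the marker is rejected as ambiguous — anchoring requires a
unique position. Redundant markers from an all-vs-all blast (≥ 50 bp,
e ≤ 1e−50) are collapsed to one representative per connected component,
lexicographically smallest for determinism.

**Two-point estimation.** Adjacent-pair recombination fractions come from
two estimators. For 1:1 (pseudo-testcross) pairs, the mismatch fraction over
pairwise-complete progeny, folded at 0.5 with the phase recorded. For 3:1
dominant pairs, the multinomial maximum-likelihood estimator: the
double-recessive phenotype has frequency p/4 with p = (1 − r)² in coupling
and r² in repulsion; the likelihood is maximised by 1-D search on [0, 0.5]
(tolerance 1e−7, endpoints checked) and verified in tests against a
brute-force grid. Mixed 1:1 × 3:1 pairs are not used for distances — the
mixed likelihood is weakly identified for dominant markers — matching the
study's preference for uniparental markers, with 3:1 markers admitted only
where they extend physical coverage (`select_markers()`, default 2 Mb gap).

**Map building.** Markers are ordered by their anchored physical position
(marker selection guaranteed map/physical colinearity in the source maps, so
no de novo ordering is attempted), cumulative cM positions are running sums
of Haldane distances d = −50 ln(1 − 2r), and pairs lacking a joint estimate
are bridged by skipping the unestimable marker. Intervals with
RR ≥ 25 cM/Mb — more plausibly genotyping error than real recombination —
are repaired by `filter_intervals()`: repeatedly remove the single marker
whose removal most reduces the violation count (ties: larger summed adjacent
RR, then later physical position). Haldane distances are additive, so a
merged interval inherits the sum of the removed distances unless a
re-estimation callback is supplied; the procedure terminates (one marker per
step) and is a fixed point on clean maps.

## The simulator and what it does (not) show

`simulate_pedigree()` draws, per progeny and chromosome, two independent
gametes. Crossover counts are Poisson with mean L/100 Morgans — the
interference-free model underlying Haldane's function, keeping simulation
and estimation internally consistent — with positions uniform in genetic
coordinates, mapped to physical space by the inverse Marey function of a
piecewise-constant RR profile. An obligate-crossover mode (zero-truncated
Poisson) honours the cytological one-crossover minimum but is biased upward
relative to Haldane expectations and is off by default. Dominant phases are
drawn per marker and parent, stored in the metadata, and withheld from
estimators.

Defaults are the study conditions: the 11 scaffold lengths (39.0–80.1 Mb)
with the cross-parent chromosome mean RRs (1.98–3.81 cM/Mb) as flat
profiles, 184 progeny (the F1 family size), 90 % 1:1 markers, 1 % call error
and 5 % missingness — error and missingness are not reported in the source
data, so typical DArT assay magnitudes were fixed once. Validation problem
sizes are kept modest by design (500 progeny, ~24 markers on one 50 Mb
chromosome for the headline recovery check; 184 progeny across all 11
chromosomes in the analysis script), which is ample for binomial-envelope
assertions.

What passing recovery tests show: the estimators are consistent — with
error-free dense 1:1 markers the estimated map length falls within 3
binomial standard errors of the true genetic span between the outermost
mapped markers (the span, not the full chromosome: two-point maps cannot see
beyond their terminal markers). What they do not show: robustness to real
DArT artefacts the simulator does not emulate — clustered markers, scoring
bias between coupling/repulsion dominant pairs, segregation distortion,
misanchored markers, or fine-scale rate heterogeneity (hotspots) within
bins. At realistic error rates the estimated lengths are biased upward,
because call errors masquerade as double recombinants; the source maps'
25 cM/Mb filter exists precisely to cap that inflation.

## Numerical choices and degenerate inputs

* Mb = bp / 1e6 exactly; map physical spans are max − min anchored bp, which
  is why map spans are smaller than scaffold lengths; genome coverage is the
  pooled span / scaffold percentage. The printed mean coverage (89.37 %)
  is not exactly recovered from the map table (89.7 % against the
  11-scaffold total, 84.9 % against the 640 Mb genome); the original
  denominator is ambiguous, so neither value is asserted.
* The coefficient of variation uses the sample (n − 1) standard deviation;
  both printed CV checks (0.20 chromosome-scale, 0.08 individual-scale) pass
  at 2-decimal rounding under this convention.
* `haldane_cm()` rejects r ≥ 0.5 (unlinked) and `estimate_rf_testcross()`
  folds rather than errors; zero-variance correlations, zero pooled
  variances, empty loci and zero-rate Marey inverses return `NA` sentinels
  with warnings rather than propagating NaN.
* Fixture loaders checksum their files and verify the printed-RR identity
  (|mean_rr − total_cm/phys_mb| ≤ 0.011) plus cross-table consistency. One
  printed interval count is 3 (F1.4-F, chromosome 10); the loader therefore
  requires ≥ 3, not the ≥ 4 that holds everywhere else.
* RNG: one root seed; per-chromosome streams are derived deterministically
  (seed × 1009 + chromosome, mod 2³¹ − 1) so chromosome subsets reproduce.

## Known limitations

Two-point distances along a fixed physical order replace multipoint
maximum-likelihood mapping; with markers pre-selected for colinearity the
two agree in expectation under Haldane's model, but the package neither
orders markers de novo nor detects misplacements. Windowed (sub-chromosome)
RR profiles, sex-averaged consensus maps, and re-derivation of the genomic
attribute columns from annotation are out of scope. The heterozygosity
t-test between cross types cannot be reproduced because per-parent counts
are not part of the shipped tables; `heterozygosity_count()` supports the
computation on genotype data.
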