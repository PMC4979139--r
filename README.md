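# eucrr — genome-wide recombination rate in *Eucalyptus globulus*

`eucrr` estimates and analyses meiotic recombination rate (RR, in
centimorgans per megabase) from genome-anchored linkage maps in *Eucalyptus
globulus*. It is written for geneticists studying recombination landscapes in
outbred trees: the RR of each of 10 mapping parents and 11 chromosomes is the
ratio of linkage-group length (Haldane map distance, cM) to the anchored
physical span (Mb), and the package ships the complete per-parent ×
per-chromosome map summary table and the chromosome attribute table as
checksummed fixtures, so every statistic is recomputable offline.

The core quantities and models:

* **RR per parent × chromosome**: `RR = total cM / physical Mb` (110 values).
* **Haldane mapping function**: `d = −50 · ln(1 − 2r)` cM, with two-point
  recombination fractions `r` from pseudo-testcross mismatch counts (1:1
  markers) or the F2 dominant-pair maximum likelihood (3:1 markers, class
  probabilities `((2+p)/4, (1−p)/4, (1−p)/4, p/4)` with `p = (1−r)²` in
  coupling, `r²` in repulsion).
* **CIP/CALP anchoring**: markers placed on the reference by cumulative
  identity (length-weighted mean %id) and cumulative alignment percentage
  (Σ HSP length / query length), rejecting CALP > 200 % and ambiguous hits.
* **Variance and correlation analysis**: balanced two-way fixed-effects
  ANOVA (parent + chromosome, Type-3 SS), Tukey-Kramer HSD with compact
  letters, and Pearson / first-order partial correlations of chromosome mean
  RR against gene density, GC content, transposable elements, tandem
  duplicates, diversity (H_Hw) and divergence (F_st).
* **Meiosis simulator**: Poisson (interference-free) crossovers over
  piecewise-constant RR landscapes, dominant 1:1 / 3:1 markers, configurable
  error and missingness — used to validate the estimators by parameter
  recovery.

## Worked example

```r
library(eucrr)

maps <- load_table2()                       # 110 parent x chromosome records
maps$rr <- chromosome_rr(maps$total_cm, maps$phys_mb)

parent_stats <- descriptive_stats(parent_mean_rr(maps)$mean_rr)
unlist(parent_stats)
#>        min        max       mean         cv
#> 2.71406617 3.51304547 2.97553655 0.08154991

anova_two_way(maps, "rr", "parent_id", "chromosome")
#>        term df    sum_sq   mean_sq         F        p
#>   parent_id  9  5.829251 0.6476945  6.123745 1.1e-06
#>  chromosome 10 35.812492 3.5812492 33.859567 < 2e-16
#> residual: df 90, MS 0.1058

att <- load_table4()
x <- chromosome_means(maps)$mean_rr          # n = 11 chromosome means
pearson_corr(x, att$gene_density)$r          #  0.938
partial_corr(x, att$gene_density, att$scaffold_mb)$r  # 0.874
```

Reading: individuals' genome-wide RR spans 2.71–3.51 cM/Mb (mean 2.98) and
differs significantly between parents (F(9,90) = 6.1) and, more strongly,
between chromosomes (F(10,90) = 33.9); chromosome-level RR rises with gene
density (r = 0.94), and the association survives controlling for chromosome
size (partial r = 0.87).

The numbered scripts under `analysis/` run the complete workflow and write
tables under `results/`:

```sh
Rscript analysis/01_reproduce_tables.R       # RR summaries at all scales
Rscript analysis/02_anova_correlations.R     # ANOVA, HSD letters, correlations
Rscript analysis/03_simulation_validation.R  # parameter recovery on simulated pedigrees
```

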