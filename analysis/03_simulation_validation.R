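#!/usr/bin/env Rscript
# Step 3: validation of the estimation pipeline by parameter recovery.
#
# Simulates pedigrees over the 11-chromosome default genome (scaffold lengths
# and chromosome-mean RRs of the attribute table) at the study's family sizes,
# rebuilds pseudo-testcross linkage maps with two-point Haldane distances
# along the physical order, applies the 25 cM/Mb interval filter, and compares
# estimated map lengths with the simulated truth. Writes
# results/simulation_recovery.tsv.

library(eucrr)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(n_progeny = 184, markers_per_chromosome = 16,
                  frac_testcross = 0.9, genotyping_error = 0.01,
                  missing_rate = 0.05, seed = 2016)
ped <- simulate_pedigree(cfg)
mfs <- lapply(cfg$chromosomes, marey_function)

rows <- list()
for (i in seq_along(cfg$chromosomes)) {
  chrom <- cfg$chromosomes[[i]]$chromosome
  for (parent in c("female", "male")) {
    map <- build_map(ped$geno, ped$markers, parent, chrom)
    if (is.null(map)) next
    map <- filter_intervals(map, max_rr = 25)
    if (is.null(map)) next
    pos_mb <- sort(map$positions$pos_bp / 1e6)
    true_cm <- mfs[[i]]$g(max(pos_mb)) - mfs[[i]]$g(min(pos_mb))
    rows[[length(rows) + 1]] <- data.frame(
      chromosome = chrom, parent = parent, n_markers = nrow(map$positions),
      est_cm = map$total_cm, true_cm = true_cm,
      est_rr = map$total_cm / map$phys_span_mb,
      true_rr = true_cm / map$phys_span_mb)
  }
}
rec <- do.call(rbind, rows)
utils::write.table(rec, "results/simulation_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("== Parameter recovery at n = 184 progeny, 1% error, 5% missing ==\n")
cat(sprintf("maps built: %d of %d parent x chromosome combinations\n",
            nrow(rec), 2 * length(cfg$chromosomes)))
cat(sprintf("mean |estimated - true| map length: %.1f cM (mean true %.1f cM)\n",
            mean(abs(rec$est_cm - rec$true_cm)), mean(rec$true_cm)))
cat(sprintf("correlation of estimated with true chromosome RR: %.2f\n",
            pearson_corr(rec$est_rr, rec$true_rr)$r))
cat("\nResidual upward bias at this family size reflects binomial sampling\n")
cat("error passed through the convex Haldane transform plus genotyping error;\n")
cat("it shrinks with error-free calls and larger families (see tests).\n")
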