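# Pipeline entry points and file formats. Native coordinates are 1-based
# inclusive (the linkage/BLAST convention); only the BED export converts.
# Logs go to the message stream, machine-readable output to files.

#' Simulate a pedigree and write its files
#'
#' Writes `genotypes.csv` (rows = markers with metadata columns, columns =
#' progeny, calls 0/1/NA), `markers.tsv`, and `truth.tsv` (true per-chromosome
#' genetic lengths). Identical configuration gives byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return The `pedigree_sim` object, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  ped <- simulate_pedigree(config)
  message("simulated ", nrow(ped$geno), " markers x ", ncol(ped$geno),
          " progeny (seed ", config$seed, ")")
  geno_df <- cbind(ped$markers[c("marker_id", "chromosome", "pos_bp",
                                 "seg_type", "phase_female", "phase_male")],
                   as.data.frame(ped$geno))
  utils::write.csv(geno_df, file.path(out_dir, "genotypes.csv"), row.names = FALSE)
  utils::write.table(ped$markers, file.path(out_dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ped$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ped)
}

#' Read a genotype CSV written by [run_simulate()]
#'
#' @param path the CSV file.
#' @return List with `markers` (metadata) and `geno` (marker x progeny matrix).
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("marker_id", "chromosome", "pos_bp", "seg_type",
                 "phase_female", "phase_male")
  if (!all(meta_cols %in% names(df))) {
    stop("genotype CSV missing metadata columns: ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "))
  }
  geno <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  if (!all(geno %in% c(0L, 1L, NA))) stop("genotype calls must be 0, 1 or NA")
  storage.mode(geno) <- "integer"
  rownames(geno) <- df$marker_id
  list(markers = df[meta_cols], geno = geno)
}

#' Anchor markers from an HSP file and write the anchor table
#'
#' @param hsp_path BLAST outfmt-6 TSV of marker-vs-genome HSPs.
#' @param lengths_path TSV with columns `marker_id`, `length_bp`.
#' @param out_path output anchor TSV.
#' @param window_bp,calp_max anchoring parameters (see [anchor_markers()]).
#' @param bed_path optional additional BED export of accepted anchors.
#' @return The anchor data.frame, invisibly.
#' @export
run_anchor <- function(hsp_path, lengths_path, out_path,
                       window_bp = 10000, calp_max = 200, bed_path = NULL) {
  hsps <- read_blast_tab(hsp_path)
  lengths <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "length_bp") %in% names(lengths))) {
    stop("marker-length file needs columns marker_id, length_bp")
  }
  if (nrow(hsps) == 0) warning("empty HSP file: all markers unanchored")
  anchors <- anchor_markers(hsps, lengths, window_bp = window_bp,
                            calp_max = calp_max)
  counts <- table(anchors$status)
  message("anchoring: ",
          paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  write_anchor_tsv(anchors, out_path)
  if (!is.null(bed_path)) write_anchor_bed(anchors, bed_path)
  invisible(anchors)
}

#' Run the full RR analysis on the shipped map fixtures
#'
#' Recomputes from the fixture tables every chromosome- and genome-scale
#' statistic of the study: per-parent mean and pooled genome RR, per-parent map
#' lengths and genome coverage, cross-parent chromosome means, the descriptive
#' statistics, the two-way ANOVA with Tukey-Kramer letters for chromosomes,
#' and the correlation / partial-correlation battery against the chromosome
#' attributes. Two runs produce identical reports.
#'
#' @param out_dir optional directory; when given, writes `report.json` plus
#'   `chromosome_means.tsv` and `parent_summary.tsv`.
#' @return The report list, invisibly when `out_dir` is given.
#' @export
run_analyze <- function(out_dir = NULL) {
  maps <- load_table2()
  att <- load_table4()
  maps$rr <- chromosome_rr(maps$total_cm, maps$phys_mb)

  parents <- parent_mean_rr(maps)
  pooled <- vapply(split(maps, maps$parent_id),
                   function(d) genome_rr(d)$rr, numeric(1))
  map_len <- tapply(maps$total_cm, maps$parent_id, sum)
  span <- tapply(maps$phys_mb, maps$parent_id, sum)
  coverage <- vapply(split(maps, maps$parent_id), function(d) {
    d <- d[order(d$chromosome), ]
    genome_coverage(d$phys_mb, att$scaffold_mb)
  }, numeric(1))
  parent_summary <- data.frame(
    parent_id = parents$parent_id,
    mean_rr = parents$mean_rr,
    pooled_rr = pooled[parents$parent_id],
    total_cm = as.numeric(map_len[parents$parent_id]),
    total_mb = as.numeric(span[parents$parent_id]),
    coverage_percent = coverage[parents$parent_id],
    row.names = NULL)

  chrom_means <- chromosome_means(maps)

  aov_res <- anova_two_way(maps, "rr", "parent_id", "chromosome")
  chrom_cell_means <- tapply(maps$rr, maps$chromosome, mean)
  hsd <- tukey_kramer(chrom_cell_means, n = 10, mse = aov_res$residual$mean_sq,
                      df_resid = aov_res$residual$df)

  x <- chrom_means$mean_rr[match(att$chromosome, chrom_means$chromosome)]
  feature_vars <- c("scaffold_mb", "gc_percent", "gene_density", "te_density",
                    "tandem_dup_prop", "diversity_hhw", "divergence_fst")
  feat_corr <- lapply(feature_vars, function(v) {
    res <- pearson_corr(x, att[[v]])
    partial <- if (v == "scaffold_mb") {
      list(r = NA_real_, p = NA_real_)  # cannot control a variable for itself
    } else {
      partial_corr(x, att[[v]], att$scaffold_mb, control_name = "scaffold_mb")
    }
    list(feature = v, r = res$r, p = res$p, stars = significance_stars(res$p),
         partial_r = partial$r, partial_p = partial$p)
  })
  names(feat_corr) <- feature_vars
  corr_mat <- correlation_matrix(
    cbind(data.frame(mean_rr = x), att[feature_vars]))

  report <- list(
    parent_summary = parent_summary,
    individual_stats = descriptive_stats(parents$mean_rr),
    map_length_stats = descriptive_stats(as.numeric(map_len)),
    chromosome_means = chrom_means,
    chromosome_stats = descriptive_stats(chrom_means$mean_rr),
    anova = list(terms = aov_res$terms,
                 residual = aov_res$residual, total_ss = aov_res$total_ss),
    tukey_letters = as.list(hsd$letters),
    feature_correlations = feat_corr,
    correlation_matrix = list(r = corr_mat$r, stars = corr_mat$stars)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(chrom_means, file.path(out_dir, "chromosome_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(parent_summary, file.path(out_dir, "parent_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}
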