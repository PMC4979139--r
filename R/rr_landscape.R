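# Recombination-rate summaries at interval, chromosome and genome scale, and
# the descriptive statistics reported alongside them. Unless stated otherwise,
# RR is recomputed as total_cm / phys_mb at full precision, not taken from the
# 2-decimal printed column.

#' Chromosome-scale recombination rate
#'
#' RR of one linkage group: total genetic length divided by the anchored
#' physical span, in cM/Mb.
#'
#' @param total_cm total map length(s) in cM.
#' @param phys_mb anchored physical span(s) in Mb.
#' @return Numeric vector of rates; `NA` where `phys_mb` is 0.
#' @export
#' @examples
#' chromosome_rr(122, 36.1)  # 3.38 cM/Mb
chromosome_rr <- function(total_cm, phys_mb) {
  stopifnot(length(total_cm) == length(phys_mb))
  out <- ifelse(phys_mb > 0, total_cm / phys_mb, NA_real_)
  if (any(total_cm < 0, na.rm = TRUE)) stop("negative map length")
  out
}

#' Genome-wide pooled recombination rate for one parent
#'
#' The ratio of the summed genetic length to the summed physical span over the
#' 11 chromosomes -- the physical-size-weighted mean of the chromosome rates,
#' not their unweighted mean (see [parent_mean_rr()] for that statistic).
#'
#' @param records map records of a single parent (data.frame with `chromosome`,
#'   `total_cm`, `phys_mb`).
#' @return List with `rr`, `numerator_cm`, `denominator_mb`.
#' @export
#' @examples
#' maps <- load_table2()
#' genome_rr(subset(maps, parent_id == "F1.1-F"))$rr  # 2.90
genome_rr <- function(records) {
  missing <- setdiff(1:11, records$chromosome)
  if (length(missing) > 0) {
    stop("missing chromosome(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(records$chromosome)) stop("duplicated chromosome records")
  list(rr = sum(records$total_cm) / sum(records$phys_mb),
       numerator_cm = sum(records$total_cm),
       denominator_mb = sum(records$phys_mb))
}

#' Per-parent mean recombination rate over chromosomes
#'
#' The unweighted mean of a parent's 11 chromosome RRs. This is the
#' individual-level "genome-wide RR" statistic of the study (range 2.71-3.51
#' cM/Mb across the 10 parents, mean 2.98): every chromosome contributes
#' equally regardless of its physical size, unlike the pooled [genome_rr()].
#'
#' @param records the full map table (or any subset of parents).
#' @param use_printed use the printed 2-decimal `mean_rr` column instead of
#'   recomputing `total_cm / phys_mb` (default `FALSE`).
#' @return data.frame `parent_id`, `mean_rr`, `n_chromosomes`.
#' @export
parent_mean_rr <- function(records, use_printed = FALSE) {
  rr <- if (use_printed) records$mean_rr else
    chromosome_rr(records$total_cm, records$phys_mb)
  agg <- tapply(rr, records$parent_id, mean)
  n <- tapply(rr, records$parent_id, length)
  data.frame(parent_id = names(agg), mean_rr = as.numeric(agg),
             n_chromosomes = as.integer(n), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cross-parent chromosome mean recombination rates
#'
#' Arithmetic mean over the parents of each chromosome's RR; requires a
#' balanced parent x chromosome table.
#'
#' @inheritParams parent_mean_rr
#' @return data.frame `chromosome`, `mean_rr`.
#' @export
chromosome_means <- function(records, use_printed = FALSE) {
  tab <- table(records$parent_id, records$chromosome)
  if (any(tab != 1)) stop("unbalanced parent x chromosome table")
  rr <- if (use_printed) records$mean_rr else
    chromosome_rr(records$total_cm, records$phys_mb)
  agg <- tapply(rr, records$chromosome, mean)
  data.frame(chromosome = as.integer(names(agg)), mean_rr = as.numeric(agg),
             row.names = NULL)
}

#' Genome coverage of an anchored map
#'
#' Percentage of the summed scaffold length covered by the anchored physical
#' spans.
#'
#' @param span_mb per-chromosome anchored spans (Mb).
#' @param scaffold_mb matching scaffold lengths (Mb).
#' @return Percent coverage.
#' @export
genome_coverage <- function(span_mb, scaffold_mb) {
  stopifnot(length(span_mb) == length(scaffold_mb))
  if (any(span_mb > scaffold_mb + 1e-9)) {
    stop("anchored span exceeds scaffold length (bad anchors)")
  }
  100 * sum(span_mb) / sum(scaffold_mb)
}

#' Count polymorphic (informative) markers per parent
#'
#' Relative heterozygosity of a parent, measured as the number of dominant
#' markers polymorphic (heterozygous) in that parent; also reported per
#' chromosome.
#'
#' @param markers marker metadata with `chromosome` and `informative_parent`
#'   (`"female"`, `"male"` or `"both"`).
#' @param parent `"female"` or `"male"`.
#' @return List with `total` and `per_chromosome` (named integer vector).
#' @export
heterozygosity_count <- function(markers, parent = c("female", "male")) {
  parent <- match.arg(parent)
  hit <- markers$informative_parent %in% c(parent, "both")
  per <- tapply(hit, markers$chromosome, sum)
  list(total = sum(hit),
       per_chromosome = setNames(as.integer(per), names(per)))
}

#' Descriptive statistics: min, max, mean, CV
#'
#' The coefficient of variation uses the sample (n-1) standard deviation.
#'
#' @param values numeric vector (>= 2 values).
#' @return List with `min`, `max`, `mean`, `cv` (`NA` when the mean is 0).
#' @export
descriptive_stats <- function(values) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  m <- mean(values)
  list(min = min(values), max = max(values), mean = m,
       cv = if (m == 0) NA_real_ else stats::sd(values) / m)
}

#' Export a linkage map as Marey-map points
#'
#' @param map a `linkage_map`.
#' @param path output TSV (`marker`, `chromosome`, `bp`, `cum_cm`); directly
#'   plottable as genetic vs physical position.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  out <- data.frame(marker = map$positions$marker_id,
                    chromosome = map$chromosome,
                    bp = map$positions$pos_bp,
                    cum_cm = map$positions$cum_cm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
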