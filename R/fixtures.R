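# Loaders for the printed map and chromosome-attribute tables shipped with the
# package. Values are stored exactly as printed; downstream statistics recompute
# RR as total_cm / phys_mb rather than reusing the 2-decimal printed mean_rr,
# unless the caller opts into printed-RR mode.

# Expected MD5 of the shipped fixtures; loaders refuse silently corrupted files.
.fixture_md5 <- c(
  table2_linkage_maps.tsv          = "ba1d3e40d3a8d92f325ee1765d6eaec0",
  table4_chromosome_attributes.tsv = "7ec8341d004594c19a60a15fcc7f4565"
)

# Scaffold sizes (Mb) of the 11 main reference scaffolds as printed at 1 decimal
# in the map-summary table header; cross-checked against the attribute table.
.scaffold_mb_1dp <- c(40.3, 64.2, 80.1, 42.0, 74.7, 53.9, 52.4, 74.3, 39.0, 39.3, 45.5)

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "eucrr")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("fixture not found: ", file)
  path
}

check_fixture <- function(path) {
  file <- basename(path)
  expected <- .fixture_md5[[file]]
  got <- unname(tools::md5sum(path))
  if (!identical(got, expected)) {
    stop("fixture checksum mismatch for ", file, ": expected ", expected,
         ", got ", got, " (corrupted installation?)")
  }
  invisible(TRUE)
}

#' Load the per-parent, per-chromosome linkage map summaries
#'
#' Returns the 110 map records (10 parents x 11 chromosomes) underlying all
#' chromosome- and genome-scale recombination-rate statistics: interval count,
#' total Haldane map length (cM), anchored physical span (Mb) and the printed
#' mean RR (cM/Mb). Parent ids follow the `<family>-<F|M>` convention
#' (e.g. `"F1.4-F"`); `cross_type` is derived from the family prefix and `sex`
#' from the parent suffix.
#'
#' @param check integrity-check the fixture (record count, checksum, printed-RR
#'   consistency). Default `TRUE`.
#' @return A `data.frame` with columns `parent_id`, `cross_type`, `sex`,
#'   `chromosome`, `interval_count`, `total_cm`, `phys_mb`, `mean_rr`.
#' @seealso [load_table4()], [chromosome_rr()], [genome_rr()]
#' @export
#' @examples
#' maps <- load_table2()
#' subset(maps, parent_id == "F1.1-F" & chromosome == 1)
load_table2 <- function(check = TRUE) {
  path <- fixture_path("table2_linkage_maps.tsv")
  if (check) check_fixture(path)
  rec <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  expected_cols <- c("parent_id", "cross_type", "sex", "chromosome",
                     "interval_count", "total_cm", "phys_mb", "mean_rr")
  if (!identical(names(rec), expected_cols)) {
    stop("unexpected columns in map fixture: ", paste(names(rec), collapse = ", "))
  }
  if (check) {
    stopifnot(
      nrow(rec) == 110,
      length(unique(rec$parent_id)) == 10,
      all(sort(unique(rec$chromosome)) == 1:11),
      all(rec$interval_count >= 3),
      all(rec$total_cm > 0), all(rec$phys_mb > 0),
      all(rec$cross_type %in% c("F1", "F2")),
      all(rec$sex %in% c("female", "male")),
      # printed mean_rr agrees with total_cm / phys_mb at printed rounding
      all(abs(rec$mean_rr - rec$total_cm / rec$phys_mb) <= 0.011),
      # cross_type / sex consistent with the parent id
      all(rec$cross_type == substr(rec$parent_id, 1, 2)),
      all(ifelse(rec$sex == "female", "F", "M") ==
            substr(rec$parent_id, nchar(rec$parent_id), nchar(rec$parent_id)))
    )
  }
  rec
}

#' Load the chromosome attribute table
#'
#' Returns the 11 chromosome-level records used in all correlation analyses:
#' scaffold length (Mb), GC content (%), gene and transposable-element density
#' (per Mbp), the proportion of genes that are tandem duplicates, pooled
#' six-species diversity (H_Hw), between-species divergence (F_st), and the
#' chromosome mean RR across the 10 mapping parents.
#'
#' @param check integrity-check the fixture, including the cross-check that the
#'   `mean_rr` column equals the cross-parent average of the map-summary RRs
#'   (to 0.01) and that scaffold sizes agree with the map-summary header row
#'   (to 0.1 Mb, both being printed roundings).
#' @return A `data.frame` with one row per chromosome (1-11).
#' @export
#' @examples
#' attrs <- load_table4()
#' attrs[attrs$chromosome == 10, c("mean_rr", "gc_percent", "gene_density")]
load_table4 <- function(check = TRUE) {
  path <- fixture_path("table4_chromosome_attributes.tsv")
  if (check) check_fixture(path)
  att <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  expected_cols <- c("chromosome", "mean_rr", "scaffold_mb", "gc_percent",
                     "gene_density", "te_density", "tandem_dup_prop",
                     "diversity_hhw", "divergence_fst")
  if (!identical(names(att), expected_cols)) {
    stop("unexpected columns in attribute fixture: ", paste(names(att), collapse = ", "))
  }
  if (check) {
    stopifnot(
      nrow(att) == 11,
      all(att$chromosome == 1:11),
      all(att$scaffold_mb >= 39.0 & att$scaffold_mb <= 80.1),
      all(att$gc_percent >= 35 & att$gc_percent <= 39),
      all(abs(att$scaffold_mb - .scaffold_mb_1dp) <= 0.1)
    )
    rec <- load_table2(check = FALSE)
    means <- chromosome_means(rec, use_printed = TRUE)
    stopifnot(all(abs(att$mean_rr - means$mean_rr) <= 0.011))
  }
  att
}
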