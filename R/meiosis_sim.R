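# Meiosis simulator: outbred pedigrees with dominant markers segregating 1:1
# (heterozygous in one parent) or 3:1 (heterozygous in both), crossovers drawn
# along chromosomes with a known piecewise-constant recombination landscape.
# Every estimation stage downstream is validated against this known truth.

#' Define a simulated chromosome with a piecewise-constant RR profile
#'
#' @param chromosome integer id.
#' @param length_mb physical length in megabases.
#' @param rr numeric vector of recombination rates (cM/Mb), one per bin.
#' @param breaks_mb bin boundaries in Mb; must start at 0, end at `length_mb`
#'   and be strictly increasing. Defaults to a single bin covering the whole
#'   chromosome (uniform landscape).
#' @return An object of class `sim_chromosome`.
#' @export
#' @examples
#' sim_chromosome(1, 50, rr = 2)                      # uniform 2 cM/Mb
#' sim_chromosome(2, 20, rr = c(1, 3), breaks_mb = c(0, 10, 20))
sim_chromosome <- function(chromosome, length_mb, rr,
                           breaks_mb = c(0, length_mb)) {
  stopifnot(length(length_mb) == 1, length_mb > 0,
            length(breaks_mb) == length(rr) + 1)
  if (any(rr < 0)) stop("negative recombination rate in rr profile")
  if (breaks_mb[1] != 0 || abs(breaks_mb[length(breaks_mb)] - length_mb) > 1e-12 ||
      any(diff(breaks_mb) <= 0)) {
    stop("breaks_mb must tile [0, length_mb] with strictly increasing bins")
  }
  structure(list(chromosome = as.integer(chromosome), length_mb = length_mb,
                 breaks_mb = breaks_mb, rr = rr),
            class = "sim_chromosome")
}

#' Default simulated genome: the 11-chromosome study conditions
#'
#' Eleven chromosomes with the scaffold lengths (39.0-80.1 Mb) and the
#' cross-parent chromosome-mean RRs (1.98-3.81 cM/Mb) of the fixture tables,
#' each as a uniform landscape.
#'
#' @return List of 11 `sim_chromosome` objects.
#' @export
default_sim_chromosomes <- function() {
  att <- load_table4(check = FALSE)
  lapply(seq_len(nrow(att)), function(i) {
    sim_chromosome(att$chromosome[i], att$scaffold_mb[i], rr = att$mean_rr[i])
  })
}

#' Simulation configuration
#'
#' Defaults emulate one F1 family of the study: 184 progeny, mostly 1:1
#' (pseudo-testcross) dominant markers with a small 3:1 fraction, 1 % call
#' error, 5 % missing data, Poisson (interference-free) crossovers.
#'
#' @param chromosomes list of [sim_chromosome()] objects.
#' @param n_progeny number of progeny (>= 2).
#' @param markers_per_chromosome markers per chromosome (>= 2).
#' @param frac_testcross fraction of markers segregating 1:1; the rest are 3:1.
#' @param genotyping_error per-call flip probability.
#' @param missing_rate per-call missing probability.
#' @param crossover_model `"poisson"` (no interference, Haldane-consistent) or
#'   `"obligate"` (zero-truncated Poisson count; at least one crossover).
#' @param seed integer root seed; all streams derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chromosomes = default_sim_chromosomes(),
                       n_progeny = 184,
                       markers_per_chromosome = 12,
                       frac_testcross = 0.9,
                       genotyping_error = 0.01,
                       missing_rate = 0.05,
                       crossover_model = c("poisson", "obligate"),
                       seed = 1L) {
  crossover_model <- match.arg(crossover_model)
  stopifnot(length(chromosomes) >= 1,
            all(vapply(chromosomes, inherits, logical(1), "sim_chromosome")))
  if (n_progeny < 2) stop("n_progeny must be >= 2")
  if (markers_per_chromosome < 2) stop("markers_per_chromosome must be >= 2")
  for (p in c(frac_testcross, genotyping_error, missing_rate)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  structure(list(chromosomes = chromosomes, n_progeny = as.integer(n_progeny),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 frac_testcross = frac_testcross,
                 genotyping_error = genotyping_error,
                 missing_rate = missing_rate,
                 crossover_model = crossover_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Marey function of a simulated chromosome
#'
#' The cumulative genetic position G(x) (cM) as a function of physical position
#' x (Mb): piecewise-linear, non-decreasing, with G(0) = 0 and G(length_mb) =
#' total genetic length. The inverse maps cM back to Mb, breaking ties across
#' zero-rate bins at the left bin edge.
#'
#' @param chrom a `sim_chromosome`.
#' @return List with elements `g` (Mb -> cM), `ginv` (cM -> Mb), `total_cm`,
#'   and `degenerate` (`TRUE` when the total genetic length is 0, in which case
#'   `ginv` is undefined beyond 0).
#' @export
#' @examples
#' mf <- marey_function(sim_chromosome(1, 50, rr = 2))
#' mf$g(25)    # 50 cM
#' mf$ginv(50) # 25 Mb
marey_function <- function(chrom) {
  stopifnot(inherits(chrom, "sim_chromosome"))
  cum_cm <- c(0, cumsum(chrom$rr * diff(chrom$breaks_mb)))
  total_cm <- cum_cm[length(cum_cm)]
  g <- stats::approxfun(chrom$breaks_mb, cum_cm, rule = 2)
  degenerate <- total_cm <= 0
  ginv <- if (degenerate) {
    function(cm) ifelse(cm == 0, 0, NA_real_)
  } else {
    # ties = min: a flat stretch of G maps back to its left edge
    stats::approxfun(cum_cm, chrom$breaks_mb, rule = 2, ties = min)
  }
  list(g = g, ginv = ginv, total_cm = total_cm, degenerate = degenerate)
}

#' Draw crossover positions for one gamete
#'
#' Under `"poisson"` the crossover count is Poisson with mean L/100 Morgans and
#' positions are i.i.d. uniform on the genetic length (no interference, the
#' Haldane model). Under `"obligate"` the count is zero-truncated Poisson with
#' the same rate, honouring the requirement of at least one crossover per
#' chromosome per meiosis (biased upward relative to Haldane expectations).
#'
#' @param genetic_length_cm total genetic length in cM (>= 0).
#' @param model `"poisson"` or `"obligate"`.
#' @return Sorted numeric vector of crossover positions in cM.
#' @export
simulate_crossovers <- function(genetic_length_cm,
                                model = c("poisson", "obligate")) {
  model <- match.arg(model)
  stopifnot(genetic_length_cm >= 0)
  if (genetic_length_cm == 0) return(numeric(0))
  lambda <- genetic_length_cm / 100
  n <- if (model == "poisson") {
    stats::rpois(1, lambda)
  } else {
    # zero-truncated Poisson via inverse-CDF on the conditional distribution
    stats::qpois(stats::runif(1, stats::dpois(0, lambda), 1), lambda)
  }
  sort(stats::runif(n, 0, genetic_length_cm))
}

# One gamete's haplotype indicator (0/1) at the given genetic positions.
gamete_haplotypes <- function(positions_cm, genetic_length_cm, model) {
  xo <- simulate_crossovers(genetic_length_cm, model)
  start <- stats::rbinom(1, 1, 0.5)
  n_below <- findInterval(positions_cm, xo)
  (start + n_below) %% 2
}

#' Simulate an outbred pedigree with dominant markers
#'
#' For each progeny and chromosome two independent gametes (one per parent) are
#' formed by starting on a random parental haplotype and switching at each
#' crossover; crossover positions are drawn in genetic coordinates and mapped
#' to physical space through the inverse Marey function. Markers segregating
#' 1:1 are heterozygous in exactly one parent (dominant allele on a random
#' haplotype); 3:1 markers are heterozygous in both parents. Dominant scoring
#' reports band presence (1) / absence (0); calls are flipped with probability
#' `genotyping_error` and set missing (`NA`) with probability `missing_rate`.
#' Identical configuration (including seed) gives identical output.
#'
#' @param config a [sim_config()].
#' @return An object of class `pedigree_sim`: list with `markers` (metadata:
#'   id, chromosome, physical bp, segregation type, informative parent, phases
#'   -- phase is recorded but withheld from estimators by default), `geno`
#'   (marker x progeny 0/1/NA matrix) and `truth` (per-chromosome true genetic
#'   lengths in cM).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  marker_tabs <- list()
  geno_rows <- list()
  truth <- data.frame(chromosome = integer(0), length_mb = numeric(0),
                      total_cm = numeric(0))
  n <- config$n_progeny
  for (chrom in config$chromosomes) {
    # deterministic per-chromosome stream so chromosome subsets reproduce
    set.seed(as.integer((as.numeric(config$seed) * 1009 + chrom$chromosome) %%
                          2147483647))
    mf <- marey_function(chrom)
    m <- config$markers_per_chromosome
    pos_mb <- sort(stats::runif(m, 0, chrom$length_mb))
    pos_cm <- mf$g(pos_mb)
    seg <- ifelse(stats::runif(m) < config$frac_testcross, "1:1", "3:1")
    inf_parent <- ifelse(seg == "3:1", "both",
                         ifelse(stats::runif(m) < 0.5, "female", "male"))
    phase_f <- stats::rbinom(m, 1, 0.5)  # haplotype carrying the dominant allele
    phase_m <- stats::rbinom(m, 1, 0.5)
    # allele matrices: does the maternal / paternal gamete carry the dominant allele
    dom_f <- matrix(0L, nrow = m, ncol = n)
    dom_m <- matrix(0L, nrow = m, ncol = n)
    for (j in seq_len(n)) {
      hap_f <- gamete_haplotypes(pos_cm, mf$total_cm, config$crossover_model)
      hap_m <- gamete_haplotypes(pos_cm, mf$total_cm, config$crossover_model)
      het_f <- inf_parent %in% c("female", "both")
      het_m <- inf_parent %in% c("male", "both")
      dom_f[, j] <- as.integer(het_f & hap_f == phase_f)
      dom_m[, j] <- as.integer(het_m & hap_m == phase_m)
    }
    band <- (dom_f | dom_m) * 1L
    flip <- matrix(stats::runif(m * n) < config$genotyping_error, m, n)
    band[flip] <- 1L - band[flip]
    band[matrix(stats::runif(m * n) < config$missing_rate, m, n)] <- NA_integer_
    id <- sprintf("chr%02d_m%03d", chrom$chromosome, seq_len(m))
    marker_tabs[[length(marker_tabs) + 1]] <- data.frame(
      marker_id = id, chromosome = chrom$chromosome,
      pos_bp = round(pos_mb * 1e6), seg_type = seg,
      informative_parent = inf_parent,
      phase_female = phase_f, phase_male = phase_m,
      stringsAsFactors = FALSE)
    rownames(band) <- id
    geno_rows[[length(geno_rows) + 1]] <- band
    truth <- rbind(truth, data.frame(chromosome = chrom$chromosome,
                                     length_mb = chrom$length_mb,
                                     total_cm = mf$total_cm))
  }
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- sprintf("p%03d", seq_len(n))
  structure(list(markers = do.call(rbind, marker_tabs), geno = geno,
                 truth = truth, config = config),
            class = "pedigree_sim")
}
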