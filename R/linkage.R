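# Two-point linkage estimation along the fixed physical-anchor order.
# Distances use Haldane's mapping function (no interference), matching the
# crossover model of the simulator; maps are built by summing adjacent-pair
# distances over markers sorted by physical position.

#' Haldane mapping function
#'
#' Converts a recombination fraction r to additive map distance
#' d = -50 * ln(1 - 2r) centimorgans, assuming no crossover interference.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return Map distance(s) in cM.
#' @export
#' @examples
#' haldane_cm(0.25)  # 34.657 cM
haldane_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' Inverse Haldane mapping function
#'
#' @param d map distance(s) in cM (>= 0).
#' @return Recombination fraction(s) r = (1 - exp(-2d/100)) / 2.
#' @export
haldane_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("map distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' Two-point recombination fraction for a pseudo-testcross pair
#'
#' Both markers must segregate 1:1 in the same parent. Over the pairwise
#' complete progeny, the mismatch fraction estimates r in coupling phase;
#' fractions above 0.5 are folded (`r_hat = 1 - m/n`) and the phase recorded
#' as repulsion.
#'
#' @param calls_a,calls_b integer 0/1/NA band calls for the two markers.
#' @param min_informative minimum pairwise-complete progeny before the
#'   estimate is flagged low-confidence (default 20).
#' @return List with `r_hat`, `n_informative`, `phase`
#'   (`"coupling"`/`"repulsion"`) and `low_confidence`; `r_hat` is `NA` when no
#'   informative progeny exist.
#' @export
estimate_rf_testcross <- function(calls_a, calls_b, min_informative = 20) {
  stopifnot(length(calls_a) == length(calls_b))
  ok <- !is.na(calls_a) & !is.na(calls_b)
  n <- sum(ok)
  if (n == 0) {
    return(list(r_hat = NA_real_, n_informative = 0L, phase = NA_character_,
                low_confidence = TRUE))
  }
  m <- sum(calls_a[ok] != calls_b[ok])
  frac <- m / n
  if (frac <= 0.5) {
    list(r_hat = frac, n_informative = n, phase = "coupling",
         low_confidence = n < min_informative)
  } else {
    list(r_hat = 1 - frac, n_informative = n, phase = "repulsion",
         low_confidence = n < min_informative)
  }
}

# Multinomial log-likelihood of dominant-dominant F2 phenotype counts.
# counts = (band/band, band/null, null/band, null/null); p = (1-r)^2 in
# coupling, r^2 in repulsion; class probabilities ((2+p)/4, (1-p)/4, (1-p)/4, p/4).
f2_dominant_loglik <- function(r, counts, phase) {
  p <- if (phase == "coupling") (1 - r)^2 else r^2
  probs <- c((2 + p) / 4, (1 - p) / 4, (1 - p) / 4, p / 4)
  probs <- pmax(probs, 1e-300)
  sum(counts * log(probs))
}

#' Maximum-likelihood recombination fraction for two dominant 3:1 markers
#'
#' F2-intercross phenotype counts for two dominant markers carry information
#' about r through the double-recessive class frequency p/4, with p = (1-r)^2
#' in coupling and p = r^2 in repulsion. The multinomial likelihood is
#' maximised by one-dimensional search of r on [0, 0.5]; when the phase is
#' unknown both are tried and the better-supported one returned.
#'
#' @param counts integer vector `(n_band_band, n_band_null, n_null_band,
#'   n_null_null)`.
#' @param phase `"coupling"`, `"repulsion"` or `"unknown"` (default).
#' @param tol search tolerance on r (default 1e-7).
#' @return List with `r_hat`, `phase`, `loglik`, `n_informative`; `r_hat` is
#'   `NA` when all counts are zero.
#' @export
estimate_rf_f2_dominant <- function(counts, phase = c("unknown", "coupling", "repulsion"),
                                    tol = 1e-7) {
  phase <- match.arg(phase)
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) {
    return(list(r_hat = NA_real_, phase = NA_character_, loglik = NA_real_,
                n_informative = 0L))
  }
  fit_one <- function(ph) {
    opt <- stats::optimize(f2_dominant_loglik, c(0, 0.5), counts = counts,
                           phase = ph, maximum = TRUE, tol = tol)
    # optimize never visits the interval ends; check them explicitly
    cand_r <- c(opt$maximum, 0, 0.5 - 1e-12)
    ll <- vapply(cand_r, f2_dominant_loglik, numeric(1), counts = counts, phase = ph)
    best <- which.max(ll)
    list(r_hat = cand_r[best], phase = ph, loglik = ll[best], n_informative = n)
  }
  if (phase != "unknown") return(fit_one(phase))
  fits <- list(fit_one("coupling"), fit_one("repulsion"))
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

#' Build a linkage map for one parent and chromosome
#'
#' Markers informative in the given parent (segregating 1:1) are sorted by
#' anchored physical position; cumulative cM positions are the running sum of
#' Haldane distances over adjacent-pair recombination fractions. Adjacent pairs
#' with no joint estimate (no pairwise-complete progeny) are bridged by the
#' nearest estimable pair, dropping the unestimable marker from the map.
#'
#' @param geno marker x progeny 0/1/NA matrix with marker ids as rownames.
#' @param markers metadata data.frame with columns `marker_id`, `chromosome`,
#'   `pos_bp`, `seg_type`, `informative_parent`.
#' @param parent `"female"` or `"male"`.
#' @param chromosome chromosome id to map.
#' @param parent_id label stored on the map (defaults to the parent role).
#' @param min_informative passed to [estimate_rf_testcross()].
#' @return An object of class `linkage_map` (or `NULL` when fewer than two
#'   estimable markers remain): list with `parent_id`, `chromosome`, `positions`
#'   (marker_id, pos_bp, cum_cm), `intervals` (delta_cm, delta_mb, r_hat, rr),
#'   `total_cm`, `phys_span_mb`.
#' @export
build_map <- function(geno, markers, parent = c("female", "male"), chromosome,
                      parent_id = NULL, min_informative = 20) {
  parent <- match.arg(parent)
  if (is.null(parent_id)) parent_id <- parent
  sel <- markers$chromosome == chromosome &
    markers$seg_type == "1:1" &
    markers$informative_parent == parent
  mk <- markers[sel, , drop = FALSE]
  if (nrow(mk) < 2) return(NULL)
  mk <- mk[order(mk$pos_bp), , drop = FALSE]
  calls <- geno[mk$marker_id, , drop = FALSE]
  # chain markers left to right, skipping those that cannot be joined
  kept <- 1L
  r_hats <- numeric(0)
  i <- 1L
  for (j in 2:nrow(mk)) {
    est <- estimate_rf_testcross(calls[i, ], calls[j, ], min_informative)
    if (is.na(est$r_hat) || est$r_hat >= 0.5) next
    kept <- c(kept, j)
    r_hats <- c(r_hats, est$r_hat)
    i <- j
  }
  if (length(kept) < 2) return(NULL)
  mk <- mk[kept, , drop = FALSE]
  new_linkage_map(parent_id, chromosome, mk$marker_id, mk$pos_bp, r_hats)
}

# Assemble a linkage_map from ordered markers and adjacent r_hat estimates.
new_linkage_map <- function(parent_id, chromosome, marker_id, pos_bp, r_hats) {
  delta_cm <- haldane_cm(r_hats)
  cum_cm <- c(0, cumsum(delta_cm))
  delta_mb <- diff(pos_bp) / 1e6
  structure(list(
    parent_id = parent_id, chromosome = chromosome,
    positions = data.frame(marker_id = marker_id, pos_bp = pos_bp,
                           cum_cm = cum_cm, stringsAsFactors = FALSE),
    intervals = data.frame(delta_cm = delta_cm, delta_mb = delta_mb,
                           r_hat = r_hats, rr = delta_cm / delta_mb),
    total_cm = sum(delta_cm),
    phys_span_mb = (max(pos_bp) - min(pos_bp)) / 1e6
  ), class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("linkage map %s chr %s: %d markers, %.1f cM over %.1f Mb (%.2f cM/Mb)\n",
              x$parent_id, x$chromosome, nrow(x$positions), x$total_cm,
              x$phys_span_mb, x$total_cm / x$phys_span_mb))
  invisible(x)
}

#' Remove markers creating implausibly high interval RR
#'
#' While any interval has RR (delta_cm / delta_mb) at or above `max_rr` --
#' adjacent-marker rates that high most likely reflect genotyping error --
#' the single marker whose removal most reduces the number of violating
#' intervals is removed (ties: larger summed adjacent RR, then the later
#' marker in physical order) and the map rebuilt. Haldane distances are
#' additive, so a merged interval inherits the sum of the removed adjacent
#' distances unless `rf_fun` re-estimates the joined pair directly.
#'
#' @param map a `linkage_map`.
#' @param max_rr threshold in cM/Mb (default 25).
#' @param rf_fun optional `function(marker_id_a, marker_id_b)` returning a
#'   fresh `r_hat` for a merged pair; by default merged distances are the sum
#'   of the removed adjacent distances.
#' @return The filtered `linkage_map`, or `NULL` if fewer than 2 markers
#'   survive. Idempotent: filtering a filtered map changes nothing.
#' @export
filter_intervals <- function(map, max_rr = 25, rf_fun = NULL) {
  stopifnot(inherits(map, "linkage_map"), max_rr > 0)
  ids <- map$positions$marker_id
  bp <- map$positions$pos_bp
  r <- map$intervals$r_hat
  repeat {
    if (length(ids) < 2) return(NULL)
    d_cm <- haldane_cm(r)
    d_mb <- diff(bp) / 1e6
    rr <- d_cm / d_mb
    bad <- which(rr >= max_rr)
    if (length(bad) == 0) break
    k <- length(ids)
    # candidate removals: every marker; score by violations remaining
    score <- vapply(seq_len(k), function(m) {
      if (m == 1) {
        sum(rr[-1] >= max_rr)
      } else if (m == k) {
        sum(rr[-(k - 1)] >= max_rr)
      } else {
        merged_cm <- if (is.null(rf_fun)) d_cm[m - 1] + d_cm[m] else
          haldane_cm(rf_fun(ids[m - 1], ids[m + 1]))
        merged_mb <- (bp[m + 1] - bp[m - 1]) / 1e6
        sum(rr[-c(m - 1, m)] >= max_rr) + (merged_cm / merged_mb >= max_rr)
      }
    }, numeric(1))
    adj_rr <- vapply(seq_len(k), function(m) {
      sum(rr[c(if (m > 1) m - 1, if (m < k) m)])
    }, numeric(1))
    best <- which(score == min(score))
    if (length(best) > 1) best <- best[adj_rr[best] == max(adj_rr[best])]
    m <- max(best)  # later in physical order on remaining ties
    if (m == 1) {
      r <- r[-1]
    } else if (m == k) {
      r <- r[-(k - 1)]
    } else {
      merged_r <- if (is.null(rf_fun)) {
        haldane_r(d_cm[m - 1] + d_cm[m])
      } else {
        rf_fun(ids[m - 1], ids[m + 1])
      }
      r <- c(r[seq_len(m - 2)], merged_r, r[seq.int(m + 1, length.out = k - 1 - m)])
    }
    ids <- ids[-m]
    bp <- bp[-m]
  }
  new_linkage_map(map$parent_id, map$chromosome, ids, bp, r)
}

#' Apply the marker-selection priorities
#'
#' Retains anchored, non-redundant markers, preferring 1:1 (pseudo-testcross)
#' segregation: a 3:1 marker is kept only where it extends coverage, i.e. it
#' falls in a physical gap larger than `gap_mb` between retained 1:1 markers
#' (or beyond the outermost one). Markers failing linkage support are dropped
#' unless they fill such a coverage gap and their order matches the physical
#' order (`order_ok`).
#'
#' @param markers data.frame with columns `marker_id`, `pos_bp`, `anchored`,
#'   `redundant`, `seg_type` (`"1:1"`/`"3:1"`), `linkage_ok`, and optionally
#'   `order_ok` (default `TRUE`).
#' @param gap_mb coverage-gap threshold in Mb (default 2).
#' @return The retained subset, sorted by physical position.
#' @export
select_markers <- function(markers, gap_mb = 2) {
  need <- c("marker_id", "pos_bp", "anchored", "redundant", "seg_type", "linkage_ok")
  stopifnot(all(need %in% names(markers)))
  if (is.null(markers$order_ok)) markers$order_ok <- TRUE
  mk <- markers[markers$anchored & !markers$redundant, , drop = FALSE]
  mk <- mk[order(mk$pos_bp), , drop = FALSE]
  core <- mk[mk$seg_type == "1:1" & mk$linkage_ok, , drop = FALSE]
  fills_gap <- function(bp) {
    if (nrow(core) == 0) return(TRUE)
    d <- abs(core$pos_bp - bp) / 1e6
    min(d) > gap_mb
  }
  extra <- mk[!(mk$marker_id %in% core$marker_id), , drop = FALSE]
  keep_extra <- vapply(seq_len(nrow(extra)), function(i) {
    row <- extra[i, ]
    if (!row$order_ok) return(FALSE)
    fills_gap(row$pos_bp)
  }, logical(1))
  out <- rbind(core, extra[keep_extra, , drop = FALSE])
  out[order(out$pos_bp), , drop = FALSE]
}
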