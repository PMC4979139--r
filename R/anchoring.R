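# Anchoring marker sequences to unique genome positions from precomputed BLAST
# tabular output, using the cumulative identity (CIP) and cumulative alignment
# (CALP) criteria, and removal of redundant markers via an all-vs-all blast.

blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) HSP file
#'
#' @param path TSV with the 12 standard outfmt-6 columns, no header.
#' @return data.frame of HSP records with a `strand` column (`"+"`/`"-"` from
#'   subject coordinate orientation). Malformed lines are fatal, citing the
#'   line number.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), blast_cols))
    out$strand <- character(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12)) {
    stop("malformed BLAST tabular line ", which(nfield != 12)[1], " in ", path,
         ": expected 12 tab-separated fields, got ", nfield[nfield != 12][1])
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- blast_cols
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")
  out[num_cols] <- lapply(out[num_cols], as.numeric)
  if (any(out$length <= 0) || any(out$qstart <= 0) || any(out$sstart <= 0)) {
    stop("invalid HSP coordinates or lengths in ", path)
  }
  out$strand <- ifelse(out$send >= out$sstart, "+", "-")
  out
}

#' Group one marker's HSPs into candidate loci
#'
#' HSPs on the same scaffold and strand whose subject intervals lie within
#' `window_bp` of each other form one candidate locus; loci are disjoint and
#' every HSP belongs to exactly one.
#'
#' @param hsps HSP data.frame for a single query (as from [read_blast_tab()]).
#' @param window_bp clustering window (default 10000).
#' @return List of data.frames, one per locus.
#' @export
group_hsps <- function(hsps, window_bp = 10000) {
  if (nrow(hsps) == 0) return(list())
  stopifnot(length(unique(hsps$qseqid)) == 1)
  lo <- pmin(hsps$sstart, hsps$send)
  hi <- pmax(hsps$sstart, hsps$send)
  hsps$.lo <- lo
  hsps$.hi <- hi
  out <- list()
  for (key in split(seq_len(nrow(hsps)), paste(hsps$sseqid, hsps$strand))) {
    sub <- hsps[key, , drop = FALSE]
    sub <- sub[order(sub$.lo), , drop = FALSE]
    gap_open <- c(TRUE, sub$.lo[-1] > cummax(sub$.hi)[-nrow(sub)] + window_bp)
    for (idx in split(seq_len(nrow(sub)), cumsum(gap_open))) {
      locus <- sub[idx, , drop = FALSE]
      locus$.lo <- NULL
      locus$.hi <- NULL
      out[[length(out) + 1]] <- locus
    }
  }
  out
}

#' CIP / CALP score of one candidate locus
#'
#' With AL the summed HSP alignment lengths over the locus, the cumulative
#' identity percentage is the alignment-length-weighted mean identity,
#' CIP = 100 * sum(pident/100 * length) / AL, and the cumulative alignment
#' percentage is CALP = 100 * AL / query length. CALP exceeds 100 only when
#' HSPs cumulatively exceed the query length (overlapping or duplicated
#' alignments).
#'
#' @param locus HSP data.frame (one locus from [group_hsps()]).
#' @param query_length_bp marker sequence length (> 0).
#' @return List with `cip` and `calp` (percent).
#' @export
score_locus <- function(locus, query_length_bp) {
  stopifnot(query_length_bp > 0)
  al <- sum(locus$length)
  if (al == 0) stop("locus with zero aligned length")
  list(cip = 100 * sum(locus$pident / 100 * locus$length) / al,
       calp = 100 * al / query_length_bp)
}

#' Select the unique anchor position for one marker
#'
#' Loci with CALP strictly above `calp_max` are removed; among survivors the
#' locus with the highest CIP wins, ties broken by the higher CALP, and
#' remaining ties by the candidate whose implied adjacent-interval RR is
#' smallest when an `rr_context` is supplied. Markers without a unique best
#' locus are rejected as ambiguous: anchoring requires a known and unique
#' physical location.
#'
#' @param loci list of loci (from [group_hsps()]).
#' @param query_length_bp marker sequence length.
#' @param calp_max CALP rejection cutoff in percent (default 200, strictly
#'   greater-than).
#' @param rr_context optional `function(scaffold, anchor_bp)` returning the
#'   implied RR of anchoring the marker there; used only to break exact
#'   CIP/CALP ties.
#' @return One-row data.frame: `scaffold`, `anchor_bp` (minimum subject
#'   coordinate, 1-based), `strand`, `cip`, `calp`, `status` (one of
#'   `accepted`, `rejected_calp`, `rejected_ambiguous`).
#' @export
select_anchor <- function(loci, query_length_bp, calp_max = 200,
                          rr_context = NULL) {
  reject <- function(status) data.frame(
    scaffold = NA_character_, anchor_bp = NA_real_, strand = NA_character_,
    cip = NA_real_, calp = NA_real_, status = status, stringsAsFactors = FALSE)
  if (length(loci) == 0) return(reject("rejected_ambiguous"))
  cand <- do.call(rbind, lapply(loci, function(locus) {
    sc <- score_locus(locus, query_length_bp)
    data.frame(scaffold = locus$sseqid[1],
               anchor_bp = min(pmin(locus$sstart, locus$send)),
               strand = locus$strand[1], cip = sc$cip, calp = sc$calp,
               stringsAsFactors = FALSE)
  }))
  cand <- cand[cand$calp <= calp_max, , drop = FALSE]
  if (nrow(cand) == 0) return(reject("rejected_calp"))
  cand <- cand[cand$cip == max(cand$cip), , drop = FALSE]
  cand <- cand[cand$calp == max(cand$calp), , drop = FALSE]
  if (nrow(cand) > 1 && !is.null(rr_context)) {
    rr <- mapply(rr_context, cand$scaffold, cand$anchor_bp)
    cand <- cand[which(rr == min(rr)), , drop = FALSE]
  }
  if (nrow(cand) > 1) return(reject("rejected_ambiguous"))
  cand$status <- "accepted"
  cand
}

#' Anchor a set of markers from a BLAST HSP table
#'
#' Runs [group_hsps()], [score_locus()] and [select_anchor()] for every marker
#' in the table. Markers present in `query_lengths` but absent from the HSP
#' table are reported as ambiguous (no alignment at all).
#'
#' @param hsps full HSP table (all markers vs genome).
#' @param query_lengths named numeric vector (or two-column data.frame
#'   `marker_id`, `length_bp`) of marker sequence lengths.
#' @param window_bp,calp_max,rr_context passed through.
#' @return data.frame with one row per marker: `marker_id`, `scaffold`,
#'   `anchor_bp`, `strand`, `cip`, `calp`, `status`.
#' @export
anchor_markers <- function(hsps, query_lengths, window_bp = 10000,
                           calp_max = 200, rr_context = NULL) {
  if (is.data.frame(query_lengths)) {
    query_lengths <- setNames(query_lengths$length_bp, query_lengths$marker_id)
  }
  res <- lapply(names(query_lengths), function(id) {
    sub <- hsps[hsps$qseqid == id, , drop = FALSE]
    loci <- group_hsps(sub, window_bp)
    out <- select_anchor(loci, query_lengths[[id]], calp_max, rr_context)
    cbind(data.frame(marker_id = id, stringsAsFactors = FALSE), out)
  })
  do.call(rbind, res)
}

#' Identify redundant markers from an all-vs-all marker blast
#'
#' Marker pairs whose alignment meets the thresholds (aligned length >= 50 bp,
#' e-value <= 1e-50 by default) are considered redundant; redundancy is closed
#' transitively (connected components) and one representative is kept per
#' component, the lexicographically smallest id.
#'
#' @param pairs data.frame of marker-vs-marker alignments with columns
#'   `qseqid`, `sseqid`, `length`, `evalue` (self-hits ignored).
#' @param marker_ids universe of marker ids (markers with no qualifying
#'   alignment are their own representative).
#' @param min_len,max_evalue edge thresholds.
#' @return data.frame `marker_id`, `representative`, `redundant` (logical).
#' @export
remove_redundant <- function(pairs, marker_ids, min_len = 50,
                             max_evalue = 1e-50) {
  marker_ids <- sort(unique(marker_ids))
  keep <- pairs$qseqid != pairs$sseqid &
    pairs$length >= min_len & pairs$evalue <= max_evalue &
    pairs$qseqid %in% marker_ids & pairs$sseqid %in% marker_ids
  edges <- pairs[keep, c("qseqid", "sseqid"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = marker_ids))
  comp <- igraph::components(g)$membership
  rep_of <- tapply(names(comp), comp, function(ids) min(ids))
  representative <- unname(rep_of[as.character(comp[marker_ids])])
  data.frame(marker_id = marker_ids, representative = representative,
             redundant = marker_ids != representative,
             stringsAsFactors = FALSE)
}

#' Write anchors as TSV (1-based) or BED (0-based half-open)
#'
#' Native outputs keep BLAST's 1-based inclusive coordinates; the BED export is
#' the single place where conversion to 0-based half-open happens.
#'
#' @param anchors data.frame from [anchor_markers()].
#' @param path output file.
#' @export
write_anchor_tsv <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchor_tsv
#' @export
write_anchor_bed <- function(anchors, path) {
  acc <- anchors[anchors$status == "accepted", , drop = FALSE]
  bed <- data.frame(chrom = acc$scaffold,
                    start = as.integer(acc$anchor_bp) - 1L,  # 0-based half-open
                    end = as.integer(acc$anchor_bp),
                    name = acc$marker_id,
                    score = round(acc$cip, 1),
                    strand = acc$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
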