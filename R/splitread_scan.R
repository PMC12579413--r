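# ---------------------------------------------------------------------------
# Split-read breakpoint detection: segment extraction, breakpoint inference
# for query-adjacent segment pairs, and single-linkage clustering of
# breakpoint pairs supported by two or more reads.
# ---------------------------------------------------------------------------

#' Extract split alignment segments grouped by read
#'
#' Filters segments by mapping quality and minimum anchor length, and orders
#' them by query coordinate within each read. Reads with a single remaining
#' segment are retained (they still inform read depth) but contribute no
#' breakpoint pairs.
#'
#' @param aln an \code{alignments} data.frame (see
#'   \code{\link{project_alignments}} / \code{\link{read_alignments}}).
#' @param min_mapq drop segments below this mapping quality (default 10;
#'   multi-mapping alignments at MAPQ 1 are excluded by default, as in the
#'   study's filtering).
#' @param min_anchor minimum aligned query bases per segment (bp); shorter
#'   segments are treated as spurious micro-splits.
#' @return The filtered \code{alignments} data.frame ordered by read and
#'   query position, with attribute \code{multi} listing read ids with two
#'   or more segments.
#' @export
extract_splits <- function(aln, min_mapq = 10L, min_anchor = 100L) {
  stopifnot(is.data.frame(aln))
  need <- c("read_id", "ref_start", "ref_end", "read_start", "read_end",
            "strand", "mapq")
  if (!all(need %in% names(aln)))
    stop("extract_splits: malformed alignment table; missing column(s): ",
         paste(setdiff(need, names(aln)), collapse = ", "))
  keep <- aln$mapq >= min_mapq &
    (aln$read_end - aln$read_start + 1L) >= min_anchor
  out <- aln[keep, , drop = FALSE]
  out <- out[order(out$read_id, out$read_start), , drop = FALSE]
  tab <- table(out$read_id)
  attr(out, "multi") <- names(tab)[tab >= 2L]
  out
}

#' Infer a breakpoint pair from two query-adjacent segments of one read
#'
#' With both segments on the same strand, the reference gap between the end
#' of the first and the start of the second (in query order) classifies the
#' junction: a skip larger than \code{join_tol} is a deletion signature
#' (DEL), a rewind beyond \code{join_tol} is a tandem-duplication signature
#' (TANDEM_DUP); discordant strands give INV, anything else OTHER. The
#' breakpoint pair is (first segment's ref_end, second segment's ref_start).
#'
#' @param segA,segB single-row data.frames (query-adjacent segments of the
#'   same read, A before B in reference-forward query order).
#' @param join_tol dead zone (bp) within which a gap or rewind is treated as
#'   part of one alignment rather than a structural junction.
#' @return data.frame with \code{left_bp}, \code{right_bp},
#'   \code{signature}, \code{read_id}.
#' @export
infer_breakpoint <- function(segA, segB, join_tol = 50L) {
  if (!identical(segA$read_id, segB$read_id))
    stop("infer_breakpoint: segments from different reads")
  sig <- if (!identical(segA$strand, segB$strand)) "INV"
  else {
    delta <- segB$ref_start - segA$ref_end
    if (delta > join_tol) "DEL"
    else if (segB$ref_start < segA$ref_end - join_tol) "TANDEM_DUP"
    else "OTHER"
  }
  data.frame(left_bp = segA$ref_end, right_bp = segB$ref_start,
             signature = sig, read_id = segA$read_id,
             stringsAsFactors = FALSE)
}

#' Breakpoint pairs from all query-adjacent split segments
#'
#' @param segments output of \code{\link{extract_splits}}.
#' @param join_tol see \code{\link{infer_breakpoint}}.
#' @return data.frame of breakpoint pairs (possibly zero rows).
#' @export
split_pairs <- function(segments, join_tol = 50L) {
  multi <- attr(segments, "multi")
  out <- list()
  for (rid in multi) {
    s <- segments[segments$read_id == rid, , drop = FALSE]
    for (j in seq_len(nrow(s) - 1L))
      out[[length(out) + 1L]] <- infer_breakpoint(s[j, ], s[j + 1L, ],
                                                  join_tol)
  }
  if (!length(out))
    return(data.frame(left_bp = integer(0), right_bp = integer(0),
                      signature = character(0), read_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Cluster breakpoint pairs shared by multiple reads
#'
#' Single-linkage clustering of breakpoint pairs of the same signature
#' class, with per-coordinate (Chebyshev) distance at most \code{tol_bp}
#' between linked members. Each read contributes at most one pair per
#' cluster; clusters supported by fewer than \code{min_support} distinct
#' reads are dropped from the main output but retained in the
#' \code{subthreshold} attribute (single-read junctions are surfaced as
#' warnings downstream, not as calls). Output is sorted by consensus left
#' then right breakpoint.
#'
#' @param pairs data.frame from \code{\link{split_pairs}}.
#' @param tol_bp junction jitter tolerance (bp).
#' @param min_support minimum distinct supporting reads (default 2, the
#'   study's "two or more split reads sharing common breakpoints" rule).
#' @return data.frame of class \code{breakpoint_clusters} with
#'   \code{consensus_left}, \code{consensus_right}, \code{signature},
#'   \code{support}, \code{reads}; attribute \code{subthreshold} holds the
#'   clusters below \code{min_support}.
#' @export
cluster_breakpoints <- function(pairs, tol_bp = 20L, min_support = 2L) {
  stopifnot(tol_bp >= 0)
  empty <- data.frame(consensus_left = integer(0),
                      consensus_right = integer(0),
                      signature = character(0), support = integer(0),
                      reads = character(0), stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    attr(empty, "subthreshold") <- empty
    class(empty) <- c("breakpoint_clusters", "data.frame")
    return(empty)
  }
  res <- list()
  for (sig in unique(pairs$signature)) {
    p <- pairs[pairs$signature == sig, , drop = FALSE]
    cl <- if (nrow(p) == 1L) 1L else {
      d <- stats::dist(cbind(p$left_bp, p$right_bp), method = "maximum")
      stats::cutree(stats::hclust(d, method = "single"), h = tol_bp)
    }
    for (k in unique(cl)) {
      m <- p[cl == k, , drop = FALSE]
      m <- m[!duplicated(m$read_id), , drop = FALSE]  # one pair per read
      res[[length(res) + 1L]] <- data.frame(
        consensus_left = as.integer(round(median(m$left_bp))),
        consensus_right = as.integer(round(median(m$right_bp))),
        signature = sig, support = nrow(m),
        reads = paste(m$read_id, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$consensus_left, out$consensus_right), , drop = FALSE]
  rownames(out) <- NULL
  keep <- out$support >= min_support
  main <- out[keep, , drop = FALSE]
  attr(main, "subthreshold") <- out[!keep, , drop = FALSE]
  class(main) <- c("breakpoint_clusters", "data.frame")
  main
}

#' Scan alignments for split-read breakpoint clusters
#'
#' Convenience wrapper: \code{\link{extract_splits}} then
#' \code{\link{split_pairs}} then \code{\link{cluster_breakpoints}}.
#'
#' @param aln an \code{alignments} data.frame.
#' @param min_mapq,min_anchor see \code{\link{extract_splits}}.
#' @param join_tol see \code{\link{infer_breakpoint}}.
#' @param tol_bp,min_support see \code{\link{cluster_breakpoints}}.
#' @return A \code{breakpoint_clusters} data.frame.
#' @export
scan_splitreads <- function(aln, min_mapq = 10L, min_anchor = 100L,
                            join_tol = 50L, tol_bp = 20L, min_support = 2L) {
  segs <- extract_splits(aln, min_mapq, min_anchor)
  cluster_breakpoints(split_pairs(segs, join_tol), tol_bp, min_support)
}
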