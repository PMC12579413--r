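# ---------------------------------------------------------------------------
# Trio Mendelian checks, parental-origin assignment, and localization of
# recombination breakpoints as haplotype switches against phased parents.
# Genotypes are unordered biallelic pairs coded "AA"/"AB"/"BB"; missing is
# NA or "".
# ---------------------------------------------------------------------------

split_gt <- function(g) {
  if (is.na(g) || !nzchar(g)) return(NULL)
  strsplit(g, "")[[1]]
}

gt_compatible_pairs <- function(sire, dam, off) {
  s <- split_gt(sire); d <- split_gt(dam); o <- split_gt(off)
  if (is.null(o)) return(NULL)
  s <- if (is.null(s)) c("A", "B") else unique(s)
  d <- if (is.null(d)) c("A", "B") else unique(d)
  pairs <- list()
  for (a in s) for (b in d)
    if (identical(sort(c(a, b)), sort(o)))
      pairs[[length(pairs) + 1L]] <- c(paternal = a, maternal = b)
  pairs
}

#' Mendelian consistency of a trio genotype table
#'
#' Counts markers at which the offspring genotype cannot be formed by one
#' allele from each parent, and the opposing-homozygote rate (offspring and
#' a parent homozygous for different alleles).
#'
#' @param geno data.frame with columns \code{pos}, \code{sire}, \code{dam},
#'   \code{offspring} (genotypes \code{"AA"}, \code{"AB"}, \code{"BB"},
#'   missing allowed).
#' @param threshold maximum tolerated conflict rate for a \code{"pass"}
#'   verdict (default 0.1%).
#' @return list of class \code{mendelian_report}: marker counts, conflict
#'   count and rate, opposing-homozygote rate, and verdict
#'   (\code{"pass"}, \code{"fail"} or \code{"untestable"}).
#' @export
mendelian_consistency <- function(geno, threshold = 0.001) {
  if (!nrow(geno)) stop("mendelian_consistency: empty marker list")
  testable <- 0L; conflicts <- 0L; opp_hom <- 0L
  for (i in seq_len(nrow(geno))) {
    o <- geno$offspring[i]
    if (is.na(o) || !nzchar(o)) next
    s <- geno$sire[i]; d <- geno$dam[i]
    if ((is.na(s) || !nzchar(s)) && (is.na(d) || !nzchar(d))) next
    testable <- testable + 1L
    if (!length(gt_compatible_pairs(s, d, o)))
      conflicts <- conflicts + 1L
    hom <- function(g) !is.na(g) && nzchar(g) &&
      substr(g, 1, 1) == substr(g, 2, 2)
    if (hom(o) && ((hom(s) && s != o) || (hom(d) && d != o)))
      opp_hom <- opp_hom + 1L
  }
  verdict <- if (testable == 0L) "untestable"
  else if (conflicts / testable <= threshold) "pass" else "fail"
  structure(list(n_markers = nrow(geno), n_testable = testable,
                 conflicts = conflicts,
                 conflict_rate = if (testable) conflicts / testable else NA,
                 opposing_homozygote_rate =
                   if (testable) opp_hom / testable else NA,
                 verdict = verdict), class = "mendelian_report")
}

#' @export
print.mendelian_report <- function(x, ...) {
  cat(sprintf(
    "<mendelian_report> %d/%d testable, %d conflict(s) (rate %.4f) -> %s\n",
    x$n_testable, x$n_markers, x$conflicts,
    ifelse(is.na(x$conflict_rate), 0, x$conflict_rate), x$verdict))
  invisible(x)
}

#' Assign parental origin to offspring alleles
#'
#' At markers where transmission is unambiguous (all Mendelian-compatible
#' allele assignments agree), the offspring alleles are split into a
#' paternal and a maternal allele; ambiguous markers (e.g. all three
#' individuals heterozygous) are uninformative and conflicting markers are
#' flagged and excluded.
#'
#' @param geno trio genotype data.frame (see
#'   \code{\link{mendelian_consistency}}).
#' @return data.frame with \code{pos}, \code{paternal}, \code{maternal}
#'   (allele characters or NA) and \code{status}
#'   (assigned/uninformative/conflict/missing).
#' @export
assign_parental_origin <- function(geno) {
  n <- nrow(geno)
  pat <- mat <- rep(NA_character_, n)
  status <- rep("missing", n)
  for (i in seq_len(n)) {
    o <- geno$offspring[i]
    if (is.na(o) || !nzchar(o)) next
    pairs <- gt_compatible_pairs(geno$sire[i], geno$dam[i], o)
    if (is.null(pairs)) next
    if (!length(pairs)) { status[i] <- "conflict"; next }
    ps <- unique(vapply(pairs, `[[`, character(1), "paternal"))
    ms <- unique(vapply(pairs, `[[`, character(1), "maternal"))
    if (length(ps) == 1L && length(ms) == 1L) {
      pat[i] <- ps; mat[i] <- ms; status[i] <- "assigned"
    } else status[i] <- "uninformative"
  }
  data.frame(pos = geno$pos, paternal = pat, maternal = mat,
             status = status, stringsAsFactors = FALSE)
}

#' Detect haplotype switches of a transmitted gamete against a phased parent
#'
#' The offspring's transmitted allele sequence (from
#' \code{\link{assign_parental_origin}}) is matched against the parent's
#' two phased haplotypes at markers heterozygous in the parent (the only
#' markers informative for a switch). Maximal runs of the best-matching
#' haplotype are computed; runs shorter than \code{min_run} informative
#' markers are absorbed into their flanks (isolated mismatches are treated
#' as genotyping error), and each remaining change of haplotype emits a
#' switch call whose interval is bounded by the last informative marker
#' before and the first after the change.
#'
#' @param origin output of \code{\link{assign_parental_origin}}.
#' @param parent_haps data.frame with \code{pos}, \code{hap1}, \code{hap2}:
#'   the parent's phased haplotype alleles at the same markers.
#' @param parent \code{"sire"} or \code{"dam"} (selects the transmitted
#'   allele column).
#' @param min_run minimum informative-marker run length retained as a real
#'   haplotype block (default 2).
#' @return data.frame of class \code{switch_calls} with \code{parent},
#'   \code{from_hap}, \code{to_hap}, \code{interval_start},
#'   \code{interval_end}, \code{point_estimate}; attribute \code{verdict}
#'   is \code{"ok"} or \code{"untestable"} (fewer than 2 informative
#'   markers).
#' @export
detect_switches <- function(origin, parent_haps, parent = c("sire", "dam"),
                            min_run = 2L) {
  parent <- match.arg(parent)
  allele_col <- if (parent == "sire") "paternal" else "maternal"
  m <- merge(origin, parent_haps, by = "pos")
  m <- m[order(m$pos), , drop = FALSE]
  informative <- m$status == "assigned" & m$hap1 != m$hap2 &
    !is.na(m[[allele_col]])
  m <- m[informative, , drop = FALSE]
  empty <- data.frame(parent = character(0), from_hap = integer(0),
                      to_hap = integer(0), interval_start = integer(0),
                      interval_end = integer(0), point_estimate = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(m) < 2L) {
    attr(empty, "verdict") <- "untestable"
    class(empty) <- c("switch_calls", "data.frame")
    return(empty)
  }
  match_hap <- ifelse(m[[allele_col]] == m$hap1, 1L, 2L)
  r <- rle(match_hap)
  # absorb runs shorter than min_run (their binary neighbors always agree)
  while (length(r$lengths) > 1L && any(r$lengths < min_run)) {
    k <- which(r$lengths < min_run)[1L]
    if (k == 1L) {
      r$values <- r$values[-1L]
      r$lengths[2L] <- r$lengths[2L] + r$lengths[1L]
      r$lengths <- r$lengths[-1L]
    } else if (k == length(r$lengths)) {
      n <- length(r$lengths)
      r$lengths[n - 1L] <- r$lengths[n - 1L] + r$lengths[n]
      r$values <- r$values[-n]; r$lengths <- r$lengths[-n]
    } else {
      r$lengths[k - 1L] <- r$lengths[k - 1L] + r$lengths[k] +
        r$lengths[k + 1L]
      r$values <- r$values[-c(k, k + 1L)]
      r$lengths <- r$lengths[-c(k, k + 1L)]
    }
  }
  if (length(r$lengths) == 1L) {
    attr(empty, "verdict") <- "ok"
    class(empty) <- c("switch_calls", "data.frame")
    return(empty)
  }
  ends <- cumsum(r$lengths)
  out <- data.frame(
    parent = parent,
    from_hap = r$values[-length(r$values)],
    to_hap = r$values[-1L],
    interval_start = m$pos[ends[-length(ends)]],
    interval_end = m$pos[ends[-length(ends)] + 1L],
    point_estimate = (m$pos[ends[-length(ends)]] +
                        m$pos[ends[-length(ends)] + 1L]) / 2,
    stringsAsFactors = FALSE)
  attr(out, "verdict") <- "ok"
  class(out) <- c("switch_calls", "data.frame")
  out
}
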