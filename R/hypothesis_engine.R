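# ---------------------------------------------------------------------------
# Decision procedures: classify offspring evidence from the
# Holstein-Friesian trio into H1 / H2 / H3-or-H4 / expected transmission,
# and from the Fleckvieh trio into parental / crossover-wild-type /
# cis-fusion. H3 and H4 are reported as one outcome: with no variant
# differentiating the original and duplicated copies beyond the two sites
# at the copy's start, an exact-unit deletion spanning both copies is
# indistinguishable from a deletion of the duplicated copy alone.
# ---------------------------------------------------------------------------

HYPOTHESIS_LABELS <- c("EXPECTED_TRANSMISSION", "H1", "H2", "H3_OR_H4",
                       "FV_PARENTAL", "FV_AHR_WILDTYPE", "FV_CIS_FUSION",
                       "INCONSISTENT")

#' Bundle detection evidence for one offspring
#'
#' @param split_clusters a \code{breakpoint_clusters} data.frame.
#' @param cnv_calls a \code{cnv_calls} data.frame.
#' @param pc_counts,pf2d_counts \code{diag_counts} at the Celtic and P_F2D
#'   diagnostic sites.
#' @param switches named list of \code{switch_calls} per parent (elements
#'   \code{sire} and/or \code{dam}); may be empty for read-only analyses.
#' @param min_depth zygosity-call depth gate passed to the genotypers.
#' @param track optional \code{depth_track}; when present, the classifier
#'   corroborates split-read breakpoints with a depth test on the fixed
#'   span they delimit.
#' @return list of class \code{evidence_bundle} with the raw evidence plus
#'   the derived \code{pc_call} and \code{pf_call}.
#' @export
evidence_bundle <- function(split_clusters, cnv_calls, pc_counts,
                            pf2d_counts, switches = list(),
                            min_depth = 10L, track = NULL) {
  stopifnot(inherits(pc_counts, "diag_counts"),
            inherits(pf2d_counts, "diag_counts"))
  structure(list(
    split_clusters = split_clusters, cnv_calls = cnv_calls,
    pc_counts = pc_counts, pf2d_counts = pf2d_counts,
    pc_call = genotype_pc(pc_counts, min_depth),
    pf_call = genotype_pf(pf2d_counts, min_depth),
    switches = switches, track = track, locus = polled_locus()),
    class = "evidence_bundle")
}

# Depth corroboration of a split-read cluster: tests the fixed span the
# cluster's breakpoints delimit (a priori coordinates, so the Poisson test
# needs no scan correction). Returns a cnv_call-shaped row or NULL.
cluster_depth_support <- function(e, cluster, min_length = 1000L,
                                  alpha = 0.01) {
  span <- sort(c(cluster$consensus_left, cluster$consensus_right))
  direction <- if (cluster$signature == "TANDEM_DUP") "gain" else "loss"
  if (cluster$signature == "DEL") {
    # the depth change lies strictly between the junction coordinates
    span <- c(span[1] + 1L, span[2] - 1L)
  }
  if (span[2] - span[1] + 1L < min_length) return(NULL)
  if (is.null(e$track)) {
    # no track available: fall back to overlap with emitted CNV calls
    hit <- e$cnv_calls$direction == direction &
      e$cnv_calls$start <= span[2] & e$cnv_calls$end >= span[1]
    if (!any(hit)) return(NULL)
    return(e$cnv_calls[which(hit)[1], , drop = FALSE])
  }
  ts <- span_depth_test(e$track, span[1], span[2], direction)
  if (ts$p_value > alpha) return(NULL)
  data.frame(start = span[1], end = span[2], direction = direction,
             mean_ratio = ts$mean_ratio,
             n_windows = NA_integer_, p_value = ts$p_value,
             stringsAsFactors = FALSE)
}

# Variant presence with zygosity-call priority and count fallback (low
# depth at a deleted site must not void the classification).
variant_present <- function(call, counts) {
  if (!call$no_call) return(grepl("P_", call$genotype))
  site_variant_present(counts)
}

new_hypothesis_call <- function(label, rationale, phenotype) {
  structure(list(label = label, rationale = rationale,
                 phenotype_prediction = phenotype),
            class = "hypothesis_call")
}

#' @export
print.hypothesis_call <- function(x, ...) {
  cat(sprintf("<hypothesis_call> %s (predicted phenotype: %s)\n", x$label,
              x$phenotype_prediction))
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Classify Holstein-Friesian trio offspring evidence
#'
#' Implements the study's decision procedure for a trio with a P_F/P_F
#' sire and p/p dam whose offspring lacks the expected polled genotype:
#' \itemize{
#'   \item P_F2D present: expected transmission (rule precedence —
#'     the allele arrived intact).
#'   \item P_F2D absent + tandem-duplication split cluster + a coverage
#'     gain over a span shorter than the 80,128-bp unit: H1 (deletion
#'     shorter than the unit, duplicated residue left behind).
#'   \item P_F2D absent + deletion split cluster + a coverage loss: H2
#'     (deletion longer than the unit, wild-type sequence removed).
#'   \item P_F2D absent + no cluster with two or more supporting reads +
#'     no CNV call of at least 1 kbp: H3 or H4 (exact-unit deletion; not
#'     separable without copy-discriminating variants).
#'   \item anything else: INCONSISTENT.
#' }
#' Depth and split evidence are coupled (the study's reporting rule ties
#' coverage changes to split reads with consistent breakpoints): the gain
#' or loss backing H1/H2 is established by a Poisson depth test on the
#' fixed span the cluster's breakpoints delimit — a span known a priori,
#' so the test needs no genome-scan correction and retains full power —
#' or, failing that, by overlap with a scan-significant CNV call.
#' Sub-threshold (single-read) clusters never trigger a hypothesis but are
#' surfaced in the rationale as warnings.
#'
#' @param e an \code{evidence_bundle} for the offspring.
#' @return A \code{hypothesis_call}.
#' @export
classify_hf <- function(e) {
  stopifnot(inherits(e, "evidence_bundle"))
  pf_present <- variant_present(e$pf_call, e$pf2d_counts)
  if (is.na(pf_present))
    stop("classify_hf: no usable diagnostic evidence at the P_F2D site")
  cl <- e$split_clusters
  cnv <- e$cnv_calls
  unit_len <- e$locus$pf_unit_length
  warns <- character(0)
  sub <- attr(cl, "subthreshold")
  if (!is.null(sub) && nrow(sub))
    warns <- sprintf(
      "warning: %d sub-threshold junction(s) supported by a single read (e.g. %s at %d|%d)",
      nrow(sub), sub$signature[1], sub$consensus_left[1],
      sub$consensus_right[1])

  if (isTRUE(pf_present))
    return(new_hypothesis_call(
      "EXPECTED_TRANSMISSION",
      c("P_F2D detected in the offspring: the Friesian allele was transmitted intact",
        warns), "polled"))

  dup <- cl[cl$signature == "TANDEM_DUP", , drop = FALSE]
  del <- cl[cl$signature == "DEL", , drop = FALSE]

  for (i in seq_len(nrow(dup))) {
    sup <- cluster_depth_support(e, dup[i, ])
    if (is.null(sup)) next
    span <- sup$end - sup$start + 1L
    if (span >= unit_len) next
    return(new_hypothesis_call("H1", c(
      "P_F2D absent",
      sprintf("tandem-duplication split cluster at %d|%d (support %d)",
              dup$consensus_left[i], dup$consensus_right[i],
              dup$support[i]),
      sprintf("coverage gain over the %d bp between the breakpoints (< %d bp unit, ratio %.2f, p = %.2g): duplicated residue retained",
              span, unit_len, sup$mean_ratio, sup$p_value), warns),
      "horned"))
  }
  for (i in seq_len(nrow(del))) {
    sup <- cluster_depth_support(e, del[i, ])
    if (is.null(sup)) next
    return(new_hypothesis_call("H2", c(
      "P_F2D absent",
      sprintf("deletion split cluster at %d|%d (support %d)",
              del$consensus_left[i], del$consensus_right[i],
              del$support[i]),
      sprintf("coverage loss over %d-%d (ratio %.2f, p = %.2g): wild-type sequence removed",
              sup$start, sup$end, sup$mean_ratio, sup$p_value), warns),
      "horned"))
  }
  if (!nrow(cl) && !nrow(cnv))
    return(new_hypothesis_call("H3_OR_H4", c(
      "P_F2D absent",
      "no split-read cluster supported by two or more reads",
      "no region of at least 1 kbp with significant coverage gain or loss",
      sprintf("consistent with a deletion of exactly %d bp; H3 and H4 are not separable without copy-discriminating variants",
              unit_len), warns), "horned"))
  new_hypothesis_call("INCONSISTENT", c(
    "P_F2D absent but the split/depth evidence matches no single hypothesis",
    warns), NA_character_)
}

#' Classify Fleckvieh trio offspring evidence
#'
#' For a trio with a p/p sire and a dam carrying the Celtic and Friesian
#' variants in trans: exactly one variant transmitted with no maternal
#' haplotype switch is parental transmission; both absent with exactly one
#' maternal switch between the Celtic span and the duplication junction is
#' the allelic-crossover wild-type gamete; both present on the maternal
#' side is the cis fusion (phenotypically polled — such offspring would be
#' mistaken for homozygous polled).
#'
#' @param e an \code{evidence_bundle} (with \code{switches$dam}).
#' @param dam_trans must be TRUE: the dam is an established trans-phase
#'   P_C/P_F heterozygote.
#' @return A \code{hypothesis_call}.
#' @export
classify_fv <- function(e, dam_trans = TRUE) {
  stopifnot(inherits(e, "evidence_bundle"))
  if (!isTRUE(dam_trans))
    stop("classify_fv: dam must be an established trans P_C/P_F heterozygote")
  pc <- variant_present(e$pc_call, e$pc_counts)
  pf <- variant_present(e$pf_call, e$pf2d_counts)
  if (is.na(pc) || is.na(pf))
    stop("classify_fv: no usable diagnostic evidence at both sites")
  sw <- e$switches$dam
  n_sw <- if (is.null(sw)) 0L else nrow(sw)
  L <- e$locus
  # localization is interval-valued: the switch is compatible with the
  # scenario if its informative-marker interval overlaps the span between
  # the Celtic InDel and the duplication junction
  in_window <- if (n_sw) sw$interval_end > L$pc_del_end &
    sw$interval_start <= L$pf_unit_end else logical(0)

  if (pc && pf)
    return(new_hypothesis_call("FV_CIS_FUSION", c(
      "both the Celtic insertion and P_F2D present with a p/p sire: maternal cis fusion",
      if (n_sw) sprintf("maternal haplotype switch near %.0f supports a crossover origin",
                        sw$point_estimate[1])), "polled"))
  if (xor(isTRUE(pc), isTRUE(pf)) && n_sw == 0L)
    return(new_hypothesis_call("FV_PARENTAL", c(
      sprintf("%s transmitted unchanged; no maternal haplotype switch",
              if (isTRUE(pc)) "P_C" else "P_F")),
      "polled"))
  if (!pc && !pf && n_sw == 1L && all(in_window))
    return(new_hypothesis_call("FV_AHR_WILDTYPE", c(
      "neither polled variant transmitted",
      sprintf("exactly one maternal haplotype switch in %d-%d (point estimate %.0f): allelic crossover skipping both variants",
              sw$interval_start[1], sw$interval_end[1],
              sw$point_estimate[1])), "horned"))
  new_hypothesis_call("INCONSISTENT", c(sprintf(
    "diagnostics (P_C %s, P_F %s) and %d maternal switch(es) match no scenario",
    pc, pf, n_sw)), NA_character_)
}

#' Gamete classes and probabilities for a parent genotype
#'
#' Trans-phase P_C/P_F parents produce the two parental gametes at
#' \code{(1-r)/2} each and the recombinant wild-type and cis-fusion
#' gametes at \code{r/2} each (the two recombinants are equally likely);
#' all other genotypes segregate their alleles 1:1 (non-allelic
#' recombination within a homozygote is a qualitative possibility and is
#' not assigned a rate).
#'
#' @param genotype a POLLED genotype label.
#' @param r recombination fraction in [0, 0.5].
#' @return Named numeric vector of gamete probabilities (sums to 1).
#' @export
enumerate_gametes <- function(genotype, r = 0) {
  gamete_distribution(genotype, r)
}
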