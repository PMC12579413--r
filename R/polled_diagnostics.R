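# ---------------------------------------------------------------------------
# In-silico analog of the diagnostic polled test: read-count genotyping of
# the Celtic 212-bp insertion and of the Friesian 2-bp deletion (P_F2D)
# with its ratio-based zygosity rule, plus Mendelian-expectation and
# genetic-map calculators.
# ---------------------------------------------------------------------------

#' Read counts at a diagnostic site
#'
#' @param site \code{"P_C_site"} or \code{"P_F2D_site"}.
#' @param ref_supporting,variant_supporting non-negative read counts.
#' @return list of class \code{diag_counts}.
#' @export
diag_counts <- function(site = c("P_C_site", "P_F2D_site"),
                        ref_supporting, variant_supporting) {
  site <- match.arg(site)
  if (ref_supporting < 0 || variant_supporting < 0)
    stop("diag_counts: counts must be >= 0")
  structure(list(site = site,
                 ref_supporting = as.integer(ref_supporting),
                 variant_supporting = as.integer(variant_supporting)),
            class = "diag_counts")
}

binom_genotype <- function(counts, fractions, labels, min_depth) {
  n <- counts$ref_supporting + counts$variant_supporting
  k <- counts$variant_supporting
  if (n < min_depth) {
    return(structure(list(site = counts$site, genotype = NA_character_,
                          confidence = NA_real_, no_call = TRUE,
                          reason = sprintf("depth %d < %d", n, min_depth),
                          counts = counts,
                          phenotype_prediction = NA_character_),
                     class = "polled_genotype_call"))
  }
  ll <- dbinom(k, n, fractions, log = TRUE)
  best <- which.max(ll)
  conf <- exp(ll[best]) / sum(exp(ll))
  gt <- labels[best]
  structure(list(site = counts$site, genotype = gt, confidence = conf,
                 no_call = FALSE, reason = NULL, counts = counts,
                 phenotype_prediction =
                   if (grepl("P_", gt)) "polled" else "horned"),
            class = "polled_genotype_call")
}

#' @export
print.polled_genotype_call <- function(x, ...) {
  if (x$no_call)
    cat(sprintf("<polled_genotype_call> %s: no call (%s)\n", x$site,
                x$reason))
  else
    cat(sprintf("<polled_genotype_call> %s: %s (confidence %.3f, %d ref / %d var)\n",
                x$site, x$genotype, x$confidence,
                x$counts$ref_supporting, x$counts$variant_supporting))
  invisible(x)
}

#' Genotype the Celtic insertion from diagnostic read counts
#'
#' The 212-bp insertion is either absent, on one, or on both haplotypes, so
#' the expected variant-read fraction is ~0, 1/2 or ~1; the call maximizes
#' the binomial likelihood over the fractions {0.02, 0.5, 0.98} (the 2%
#' floor/ceiling tolerate sequencing error).
#'
#' @param counts a \code{diag_counts} at the P_C site.
#' @param min_depth minimum total reads for a call (default 10).
#' @return A \code{polled_genotype_call} (\code{p/p}, \code{P_C/p} or
#'   \code{P_C/P_C}).
#' @export
genotype_pc <- function(counts, min_depth = 10L) {
  stopifnot(inherits(counts, "diag_counts"))
  binom_genotype(counts, c(0.02, 0.5, 0.98),
                 c("p/p", "P_C/p", "P_C/P_C"), min_depth)
}

#' Genotype the Friesian duplication from P_F2D read counts
#'
#' The duplicated copy carries the 2-bp deletion while the original copy
#' does not, so the expected reference:variant read ratios at the P_F2D
#' site are 1:0 for \code{p/p}, 2:1 for \code{P_F/p} (two reference copies,
#' one deleted copy — the "approximately double height" heterozygote rule)
#' and 1:1 for \code{P_F/P_F} ("similar peak heights"); the call maximizes
#' the binomial likelihood over variant fractions {0.02, 1/3, 1/2}.
#'
#' @param counts a \code{diag_counts} at the P_F2D site.
#' @param min_depth minimum total reads for a call (default 10).
#' @return A \code{polled_genotype_call} (\code{p/p}, \code{P_F/p} or
#'   \code{P_F/P_F}).
#' @export
genotype_pf <- function(counts, min_depth = 10L) {
  stopifnot(inherits(counts, "diag_counts"))
  binom_genotype(counts, c(0.02, 1 / 3, 1 / 2),
                 c("p/p", "P_F/p", "P_F/P_F"), min_depth)
}

# Presence/absence of the diagnostic variant from raw counts (no zygosity,
# no depth gate beyond a 3-read floor): used by the hypothesis engine when
# site depth is too low for a confident zygosity call.
site_variant_present <- function(counts) {
  n <- counts$ref_supporting + counts$variant_supporting
  if (n < 3L) return(NA)
  ll <- dbinom(counts$variant_supporting, n, c(0.02, 1 / 3, 1 / 2, 0.98),
               log = TRUE)
  which.max(ll) > 1L
}

# ---------------------------------------------------------------------------
# Diagnostic counts from alignments
# ---------------------------------------------------------------------------

# Reference-space ranges of D (or query widths of I) ops for one cigar.
cigar_site_ops <- function(cigar, ref_start) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref_adv <- ifelse(ops %in% c("M", "D", "N", "=", "X"), lens, 0L)
  ref_pos <- ref_start + c(0L, cumsum(ref_adv))[seq_along(ops)]
  data.frame(op = ops, len = lens, ref_pos = ref_pos,
             stringsAsFactors = FALSE)
}

#' Count reads supporting the reference or variant at a diagnostic site
#'
#' For the P_F2D site, a variant-supporting read aligns across the 2-bp
#' site with a deletion enclosing it; a reference-supporting read aligns
#' through the site and \code{flank} bases on each side without such a
#' deletion. For the P_C site, a variant-supporting read carries an
#' insertion of at least \code{min_ins} bases anchored within
#' \code{flank} bp of the Celtic InDel; reference support is an alignment
#' through the InDel span without one.
#'
#' @param aln an \code{alignments} data.frame.
#' @param site \code{"P_C_site"} or \code{"P_F2D_site"}.
#' @param flank required aligned flank (bp, default 10) and anchor
#'   tolerance for the insertion.
#' @param min_ins minimum insertion length attributed to the Celtic variant
#'   (default 100 bp).
#' @param min_mapq drop alignments below this mapping quality.
#' @return A \code{diag_counts}.
#' @export
count_diagnostic_reads <- function(aln, site = c("P_C_site", "P_F2D_site"),
                                   flank = 10L, min_ins = 100L,
                                   min_mapq = 10L) {
  site <- match.arg(site)
  L <- polled_locus()
  if (site == "P_F2D_site") {
    s <- L$pf_unit_start + L$pf_del_offset - 1L
    e <- s + L$pf_del_length - 1L
  } else {
    s <- L$pc_del_start
    e <- L$pc_del_end
  }
  aln <- aln[aln$mapq >= min_mapq &
               aln$ref_start <= s - flank & aln$ref_end >= e + flank, ,
             drop = FALSE]
  n_ref <- 0L; n_var <- 0L
  for (i in seq_len(nrow(aln))) {
    co <- cigar_site_ops(aln$cigar[i], aln$ref_start[i])
    if (site == "P_F2D_site") {
      dels <- co[co$op == "D", , drop = FALSE]
      hit <- any(dels$ref_pos <= s & dels$ref_pos + dels$len - 1L >= e)
    } else {
      ins <- co[co$op == "I" & co$len >= min_ins, , drop = FALSE]
      hit <- any(abs(ins$ref_pos - s) <= e - s + 2L * flank + 50L)
    }
    if (hit) n_var <- n_var + 1L else n_ref <- n_ref + 1L
  }
  diag_counts(site, n_ref, n_var)
}

# ---------------------------------------------------------------------------
# Mendelian expectation and genetic-map calculators
# ---------------------------------------------------------------------------

POLLED_GENOTYPES <- c("p/p", "P_C/p", "P_C/P_C", "P_F/p", "P_F/P_F",
                      "P_C/P_F")

gamete_distribution <- function(genotype, r = 0) {
  if (!genotype %in% POLLED_GENOTYPES)
    stop("unknown POLLED genotype label: ", genotype)
  if (r < 0 || r > 0.5) stop("recombination fraction must lie in [0, 0.5]")
  if (genotype == "P_C/P_F") {
    # trans phase: parental gametes carry one variant each; a crossover
    # between the variant spans yields wild-type or the cis fusion, each r/2
    return(c("P_C" = (1 - r) / 2, "P_F" = (1 - r) / 2, "p" = r / 2,
             "P_C+P_F" = r / 2))
  }
  alleles <- strsplit(genotype, "/")[[1]]
  tab <- table(alleles) / 2
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Expected offspring genotype and phenotype distribution
#'
#' Combines the two parents' gamete distributions multiplicatively. For a
#' trans-phase \code{P_C/P_F} parent the gametes are P_C and P_F at
#' \code{(1-r)/2} each and the recombinant wild-type and cis-fusion gametes
#' at \code{r/2} each; recombination is irrelevant for the other genotypes.
#' Phenotype follows dominance: polled iff at least one polled allele.
#'
#' @param g_sire,g_dam parental genotypes from \code{"p/p"},
#'   \code{"P_C/p"}, \code{"P_C/P_C"}, \code{"P_F/p"}, \code{"P_F/P_F"},
#'   \code{"P_C/P_F"}.
#' @param r recombination fraction between the Celtic and Friesian variant
#'   positions (0 to 0.5).
#' @return data.frame with \code{genotype}, \code{phenotype}, \code{prob}
#'   (summing to 1), plus attribute \code{p_horned}.
#' @export
expected_offspring <- function(g_sire, g_dam, r = 0) {
  gs <- gamete_distribution(g_sire, r)
  gd <- gamete_distribution(g_dam, r)
  rows <- list()
  allele_rank <- c("P_C+P_F" = 1L, "P_C" = 2L, "P_F" = 3L, "p" = 4L)
  for (a in names(gs)) for (b in names(gd)) {
    al <- c(a, b)[order(allele_rank[c(a, b)])]
    gt <- paste(al, collapse = "/")  # polled allele first
    phen <- if (any(c(a, b) != "p")) "polled" else "horned"
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = gt, phenotype = phen, prob = gs[[a]] * gd[[b]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- stats::aggregate(prob ~ genotype + phenotype, out, sum)
  out <- out[order(-out$prob), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_horned") <- sum(out$prob[out$phenotype == "horned"])
  out
}

#' Genetic-map parameters for the female cattle map
#'
#' @param mb_per_cm megabases per centimorgan (default 1.085, the average
#'   for female cattle used in the study's worked example).
#' @return list of class \code{genetic_map_params}.
#' @export
genetic_map_params <- function(mb_per_cm = 1.085) {
  if (mb_per_cm <= 0) stop("mb_per_cm must be > 0")
  structure(list(mb_per_cm = mb_per_cm), class = "genetic_map_params")
}

#' Recombinant gamete rate for a physical distance
#'
#' Converts a physical distance to map distance at the given Mb/cM scale
#' and to a recombinant gamete fraction with the small-distance linear
#' approximation (1 cM = 1% recombinants, no mapping function), plus the
#' expected recombinant gametes per 1,000.
#'
#' @param distance_bp physical distance (bp, >= 0).
#' @param m a \code{genetic_map_params}.
#' @return list with \code{cM}, \code{fraction}, \code{per_1000}
#'   (= \code{round(1000 * fraction)}).
#' @export
recombinant_gamete_rate <- function(distance_bp, m = genetic_map_params()) {
  if (distance_bp < 0) stop("recombinant_gamete_rate: negative distance")
  cM <- distance_bp / (m$mb_per_cm * 1e6)
  fraction <- cM / 100
  list(cM = cM, fraction = fraction, per_1000 = round(1000 * fraction))
}

#' Per-class percentage summary of genotype counts
#'
#' @param counts named non-negative counts per genotype class.
#' @return data.frame with \code{class}, \code{count}, \code{percent}
#'   (100 * count / total).
#' @export
genotype_summary <- function(counts) {
  if (any(counts < 0)) stop("genotype_summary: negative count")
  total <- sum(counts)
  if (total == 0) stop("genotype_summary: total count is zero")
  data.frame(class = names(counts), count = as.integer(counts),
             percent = 100 * as.numeric(counts) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}
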