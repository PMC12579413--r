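# ---------------------------------------------------------------------------
# Synthetic study data: reference segment, trio designs, ONT-like reads with
# exact truth provenance, analytically projected split alignments, and
# 50K-style SNP panels.
# ---------------------------------------------------------------------------

#' Create a diplotype
#'
#' @param individual_id individual label.
#' @param role one of \code{"sire"}, \code{"dam"}, \code{"offspring"}.
#' @param hap1,hap2 \code{haplotype}s built on the same segment.
#' @return An object of class \code{diplotype}.
#' @export
diplotype <- function(individual_id, role = c("sire", "dam", "offspring"),
                      hap1, hap2) {
  role <- match.arg(role)
  stopifnot(inherits(hap1, "haplotype"), inherits(hap2, "haplotype"))
  structure(list(individual_id = individual_id, role = role,
                 haplotypes = list(hap1, hap2)), class = "diplotype")
}

#' @export
print.diplotype <- function(x, ...) {
  cat(sprintf("<diplotype> %s (%s): %s / %s\n", x$individual_id, x$role,
              x$haplotypes[[1]]$allele_id, x$haplotypes[[2]]$allele_id))
  invisible(x)
}

#' Generate a repeat-free pseudo-random reference segment
#'
#' Draws a random sequence at the requested GC fraction and rejects any
#' draw containing an exact internal repeat of \code{max_exact_repeat} bp or
#' longer (screened as duplicated k-mers, k = \code{max_exact_repeat}), so
#' that the only long duplication in a simulated genome is the engineered
#' one. Deterministic under \code{seed}.
#'
#' @param length segment length in bp.
#' @param seed integer RNG seed.
#' @param gc_fraction target GC fraction.
#' @param max_exact_repeat reject sequences with exact repeats at least this
#'   long (bp, >= 20).
#' @param start genomic coordinate of the first base.
#' @param name segment name.
#' @param max_tries bounded number of rejection retries.
#' @return A \code{genome_segment}.
#' @export
make_reference <- function(length, seed, gc_fraction = 0.42,
                           max_exact_repeat = 50L, start = 1L,
                           name = "segment", max_tries = 10L) {
  stopifnot(length >= 1, max_exact_repeat >= 20)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  for (i in seq_len(max_tries)) {
    seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = "")
    if (!has_repeat(seq, max_exact_repeat)) return(
      genome_segment(name, start, seq))
  }
  stop("make_reference: repeat constraint unsatisfiable after ", max_tries,
       " tries")
}

#' Test whether a sequence contains an exact repeat of a given length
#'
#' A sequence contains an exact internal repeat of length >= k if and only
#' if some k-mer occurs twice; screened by k-mer duplication.
#'
#' @param seq DNA string.
#' @param k minimum repeat length (bp).
#' @return Logical.
#' @export
has_repeat <- function(seq, k) {
  n <- nchar(seq)
  if (n < 2 * k) k <- max(20L, min(k, n %/% 2L))
  if (n <= k) return(FALSE)
  kmers <- substring(seq, seq_len(n - k + 1L), k:n)
  anyDuplicated(kmers) > 0L
}

#' Simulated reference for the POLLED locus window
#'
#' A repeat-free random segment standing in for BTA1 2.42-2.73 Mb, with the
#' bases named by the variant nomenclature anchored: a T at the first bp of
#' the Friesian duplication unit (the P_T>A site) and TG at unit offsets
#' 38-39 (the P_F2D site). The segment extends 20 kb beyond the scanned
#' locus window on each side so that simulated fragment ends (where
#' coverage necessarily ramps down) fall outside the analysis region, as
#' they would on a whole chromosome.
#'
#' @param seed integer RNG seed.
#' @param length segment length (default 390,000 bp: the 350-kb locus
#'   window plus the margins).
#' @param gc_fraction,max_exact_repeat passed to \code{make_reference}.
#' @return A \code{genome_segment} named \code{"BTA1_sim"} starting at
#'   2,400,000.
#' @export
polled_reference <- function(seed, length = 390000L, gc_fraction = 0.42,
                             max_exact_repeat = 50L) {
  L <- polled_locus()
  seg <- make_reference(length, seed, gc_fraction, max_exact_repeat,
                        start = L$locus_start - 20000L, name = "BTA1_sim")
  anchor <- function(seg, pos, bases) {
    i <- pos - seg$start + 1L
    substr(seg$sequence, i, i + nchar(bases) - 1L) <- bases
    seg
  }
  seg <- anchor(seg, L$pf_unit_start, "T")
  seg <- anchor(seg, L$pf_unit_start + L$pf_del_offset - 1L, "TG")
  seg
}

# ---------------------------------------------------------------------------
# Trio designs
# ---------------------------------------------------------------------------

TRIO_SCENARIOS <- c("HF_expected", "HF_H1", "HF_H2", "HF_H3H4",
                    "FV_parental", "FV_ahr_wildtype", "FV_cis_fusion",
                    "custom")

#' Design a trio under a named inheritance scenario
#'
#' Builds sire, dam and offspring diplotypes for the scenarios of the two
#' study trios. HF scenarios: sire P_F/P_F, dam p/p; the offspring's
#' paternal haplotype is the transmitted P_F allele (\code{HF_expected}), a
#' shorter-than-unit deletion product leaving a residual tandem duplication
#' (\code{HF_H1}), a longer-than-unit deletion removing wild-type flanks
#' (\code{HF_H2}), or the non-allelic homologous recombination product at a
#' crossover offset past the diagnostic variants (\code{HF_H3H4}). FV
#' scenarios: sire p/p, dam P_F/P_C in trans; the offspring's maternal
#' haplotype is a parental haplotype (\code{FV_parental}), the allelic
#' crossover product skipping both polled variants
#' (\code{FV_ahr_wildtype}), or the cis fusion carrying both
#' (\code{FV_cis_fusion}).
#'
#' @param scenario scenario label.
#' @param segment a \code{genome_segment} (typically
#'   \code{\link{polled_reference}}).
#' @param params scenario parameters: \code{nahr_offset} (HF_H3H4 crossover
#'   offset, default 40,000; must be > 39), \code{h1_residual} (H1 residual
#'   duplication length, default 40,000 bp), \code{h2_flank} (H2 extra
#'   wild-type bases deleted each side, default 5,000), \code{breakpoint}
#'   (FV crossover position, default 2,694,883), \code{transmit}
#'   (FV_parental transmitted allele, \code{"P_C"} or \code{"P_F"}), or for
#'   \code{custom} the offspring gamete haplotypes \code{paternal} /
#'   \code{maternal}.
#' @return An object of class \code{trio_design}.
#' @export
design_trio <- function(scenario = TRIO_SCENARIOS, segment, params = list()) {
  scenario <- match.arg(scenario)
  L <- polled_locus()
  p_hap <- build_haplotype(segment, polled_allele("p"))
  events <- data.frame(parent = character(0), kind = character(0),
                       position = integer(0), from_hap = integer(0),
                       to_hap = integer(0))
  if (startsWith(scenario, "HF") || scenario == "custom") {
    pf_hap <- build_haplotype(segment, polled_allele("P_F"))
    sire <- diplotype("HF_sire", "sire", pf_hap, pf_hap)
    dam <- diplotype("HF_dam", "dam", p_hap, p_hap)
    paternal <- switch(scenario,
      HF_expected = pf_hap,
      HF_H1 = {
        residual <- as.integer(params$h1_residual %||% 40000L)
        off0 <- as.integer(params$h1_offset %||% 20000L)
        if (off0 <= L$pf_del_offset + 1L)
          stop("design_trio: H1 residue must exclude the diagnostic sites")
        s <- L$pf_unit_start + off0
        e <- s + residual - 1L
        if (e >= L$pf_unit_end)
          stop("design_trio: H1 residual duplication exceeds the unit")
        build_haplotype(segment, allele_spec("H1_residual_dup", list(
          edit_op("tandem_duplication", s, e)), "wildtype"))
      },
      HF_H2 = {
        flank <- as.integer(params$h2_flank %||% 5000L)
        build_haplotype(segment, allele_spec("H2_deletion", list(
          edit_op("deletion", L$pf_unit_start - flank,
                  L$pf_unit_end + flank)), "wildtype"))
      },
      HF_H3H4 = {
        off <- as.integer(params$nahr_offset %||% 40000L)
        if (off <= L$pf_del_offset + L$pf_del_length - 1L)
          stop("design_trio: HF_H3H4 crossover offset must lie past the ",
               "diagnostic variants (> 39)")
        nahr_product(pf_hap, off)
      },
      custom = params$paternal %||% pf_hap)
    maternal <- if (scenario == "custom") params$maternal %||% p_hap else p_hap
    if (scenario %in% c("HF_H1", "HF_H2", "HF_H3H4"))
      events <- rbind(events, data.frame(
        parent = "sire", kind = "nahr_crossover",
        position = if (scenario == "HF_H3H4")
          L$pf_unit_start + as.integer(params$nahr_offset %||% 40000L) - 1L
        else NA_integer_,
        from_hap = 1L, to_hap = 1L))
    offspring <- diplotype("HF_offspring", "offspring", paternal, maternal)
  } else {
    pf_hap <- build_haplotype(segment, polled_allele("P_F"))
    pc_hap <- build_haplotype(segment, polled_allele("P_C"))
    sire <- diplotype("FV_sire", "sire", p_hap, p_hap)
    dam <- diplotype("FV_dam", "dam", pf_hap, pc_hap)   # trans phase
    bp <- as.integer(params$breakpoint %||% L$fv_breakpoint)
    if (scenario != "FV_parental" &&
        (bp <= L$pc_del_end || bp > L$pf_unit_end))
      stop("design_trio: FV breakpoint must lie between the Celtic span ",
           "and the duplication junction")
    maternal <- switch(scenario,
      FV_parental = if (identical(params$transmit %||% "P_C", "P_F"))
        pf_hap else pc_hap,
      FV_ahr_wildtype = ahr_product(pf_hap, pc_hap, bp),
      FV_cis_fusion = ahr_product(pc_hap, pf_hap, bp))
    if (scenario %in% c("FV_ahr_wildtype", "FV_cis_fusion"))
      events <- rbind(events, data.frame(
        parent = "dam", kind = "ahr_crossover", position = bp,
        from_hap = if (scenario == "FV_ahr_wildtype") 1L else 2L,
        to_hap = if (scenario == "FV_ahr_wildtype") 2L else 1L))
    offspring <- diplotype("FV_offspring", "offspring", p_hap, maternal)
  }

  expected <- c(HF_expected = "EXPECTED_TRANSMISSION", HF_H1 = "H1",
                HF_H2 = "H2", HF_H3H4 = "H3_OR_H4",
                FV_parental = "FV_PARENTAL",
                FV_ahr_wildtype = "FV_AHR_WILDTYPE",
                FV_cis_fusion = "FV_CIS_FUSION", custom = NA)[scenario]
  structure(list(scenario = scenario, segment = segment, sire = sire,
                 dam = dam, offspring = offspring, gamete_events = events,
                 expected_label = unname(expected)),
            class = "trio_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trio_design <- function(x, ...) {
  cat(sprintf("<trio_design> %s\n", x$scenario))
  print(x$sire); print(x$dam); print(x$offspring)
  if (nrow(x$gamete_events)) {
    cat("gamete events:\n"); print(x$gamete_events)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Read simulation
# ---------------------------------------------------------------------------

#' Read-simulation parameters
#'
#' Lognormal read lengths (defaults give an N50 of roughly 9 kb, inside the
#' range observed on PromethION runs of the study trios) and ONT-like error
#' rates (2% mismatch, 1% insertion, 1% deletion).
#'
#' @param coverage target mean diploid alignment coverage (fold).
#' @param length_log_mu,length_log_sigma lognormal parameters of the read
#'   length distribution (bp).
#' @param mismatch_rate,ins_rate,del_rate per-base error probabilities, each
#'   in [0, 0.2].
#' @param min_length shortest simulated read (bp).
#' @return An object of class \code{read_sim_params}.
#' @export
read_sim_params <- function(coverage = 20, length_log_mu = log(6500),
                            length_log_sigma = 0.55, mismatch_rate = 0.02,
                            ins_rate = 0.01, del_rate = 0.01,
                            min_length = 300L) {
  rates <- c(mismatch_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.2))
    stop("read_sim_params: error rates must lie in [0, 0.2]")
  if (coverage <= 0) stop("read_sim_params: coverage must be > 0")
  structure(list(coverage = coverage, length_log_mu = length_log_mu,
                 length_log_sigma = length_log_sigma,
                 mismatch_rate = mismatch_rate, ins_rate = ins_rate,
                 del_rate = del_rate, min_length = as.integer(min_length)),
            class = "read_sim_params")
}

#' Per-member simulation presets mirroring the study trios
#'
#' Coverage and read-length N50 presets for the Holstein-Friesian and
#' Fleckvieh trios (sire/dam/offspring coverages 22.98/9.68/22.50 and
#' 7.24/12.01/8.80 fold; N50s 7.8/14.0/4.0 kb and 8.4/10.0/14.1 kb). The
#' lognormal \code{mu} is set so the length-weighted median matches the N50
#' at the default sigma.
#'
#' @param trio \code{"HF"} or \code{"FV"}.
#' @return Named list of \code{read_sim_params} for sire, dam and offspring.
#' @export
trio_sim_presets <- function(trio = c("HF", "FV")) {
  trio <- match.arg(trio)
  tab <- switch(trio,
    HF = list(coverage = c(22.98, 9.68, 22.50), n50 = c(7786, 13986, 3957)),
    FV = list(coverage = c(7.24, 12.01, 8.80), n50 = c(8379, 10001, 14093)))
  sigma <- 0.55
  out <- lapply(1:3, function(i)
    read_sim_params(coverage = tab$coverage[i],
                    length_log_mu = log(tab$n50[i]) - sigma^2,
                    length_log_sigma = sigma))
  names(out) <- c("sire", "dam", "offspring")
  out
}

DNA_BASES_RAW <- charToRaw("ACGT")

# Apply per-base noise to a raw sequence; returns the noised raw vector and
# an integer matrix of indel ops (columns: pos [1-based offset in the clean
# sequence], kind [2 = insertion after pos, 3 = deletion of pos]).
apply_read_noise <- function(r, mismatch_rate, ins_rate, del_rate) {
  n <- length(r)
  nmm <- rbinom(1L, n, mismatch_rate)
  nin <- rbinom(1L, n, ins_rate)
  nde <- rbinom(1L, n, del_rate)
  if (nmm + nin + nde == 0L)
    return(list(seq = r, ops = NULL))
  if (nmm > 0L) {
    mmpos <- sample.int(n, nmm)
    cur <- match(r[mmpos], DNA_BASES_RAW)
    r[mmpos] <- DNA_BASES_RAW[((cur - 1L + sample.int(3L, nmm,
                                                     replace = TRUE)) %% 4L) + 1L]
  }
  delpos <- if (nde > 0L) sort(sample.int(n, nde)) else integer(0)
  inspos <- if (nin > 0L) sort(sample.int(n, nin)) else integer(0)
  keep <- rep(TRUE, n)
  keep[delpos] <- FALSE
  keys <- c(seq_len(n)[keep], inspos + 0.5)
  vals <- c(r[keep], DNA_BASES_RAW[sample.int(4L, nin, replace = TRUE)])
  seq <- vals[order(keys)]
  ops <- NULL
  if (nde + nin > 0L)
    ops <- cbind(pos = c(inspos, delpos),
                 kind = c(rep(2L, nin), rep(3L, nde)))
  list(seq = seq, ops = ops)
}

#' Simulate ONT-like reads from a diplotype
#'
#' Reads are drawn uniformly from both haplotypes (equal probability) until
#' the total simulated bases reach \code{coverage} times the reference
#' segment length; lengths are lognormal truncated to
#' \code{[min_length, haplotype length]}; substitution and indel noise is
#' applied per base; full truth provenance (haplotype index, interval,
#' strand, indel positions) is recorded. Deterministic under \code{seed}.
#'
#' @param d a \code{diplotype}.
#' @param p a \code{read_sim_params}.
#' @param seed integer RNG seed.
#' @return An object of class \code{simulated_reads}: a data.frame with one
#'   row per read (\code{read_id}, \code{hap_index}, \code{hap_start},
#'   \code{hap_end}, \code{strand}, \code{seq}) plus indel-op provenance in
#'   \code{attr(, "ops")}.
#' @export
simulate_reads <- function(d, p, seed) {
  stopifnot(inherits(d, "diplotype"), inherits(p, "read_sim_params"))
  set.seed(seed)
  hl <- vapply(d$haplotypes, function(h) nchar(h$sequence), integer(1))
  ref_len <- d$haplotypes[[1]]$segment_end -
    d$haplotypes[[1]]$segment_start + 1L
  target <- p$coverage * ref_len
  mean_len <- exp(p$length_log_mu + p$length_log_sigma^2 / 2)
  n_guess <- max(10L, ceiling(1.3 * target / mean_len))

  lens <- integer(0); haps <- integer(0)
  repeat {
    l <- pmin(pmax(round(rlnorm(n_guess, p$length_log_mu,
                                p$length_log_sigma)), p$min_length),
              max(hl))
    # fragments are sampled from the diplotype's DNA, so a haplotype
    # contributes reads in proportion to its length
    hp <- sample.int(2L, n_guess, replace = TRUE, prob = hl / sum(hl))
    l <- pmin(l, hl[hp])
    lens <- c(lens, l); haps <- c(haps, hp)
    if (sum(lens) >= target) break
  }
  ncut <- which(cumsum(as.numeric(lens)) >= target)[1L]
  lens <- lens[seq_len(ncut)]; haps <- haps[seq_len(ncut)]
  starts <- 1L + floor(runif(ncut) * (hl[haps] - lens + 1L))
  strands <- c("+", "-")[1L + (runif(ncut) < 0.5)]

  rawhaps <- lapply(d$haplotypes, function(h) charToRaw(h$sequence))
  seqs <- character(ncut)
  ops <- vector("list", ncut)
  for (i in seq_len(ncut)) {
    r <- rawhaps[[haps[i]]][starts[i]:(starts[i] + lens[i] - 1L)]
    nz <- apply_read_noise(r, p$mismatch_rate, p$ins_rate, p$del_rate)
    sq <- nz$seq
    if (strands[i] == "-") sq <- rev_comp_raw(sq)
    seqs[i] <- rawToChar(sq)
    ops[i] <- list(nz$ops)   # [[<- would drop the element when ops is NULL
  }
  reads <- data.frame(
    read_id = sprintf("%s_read_%05d", d$individual_id, seq_len(ncut)),
    hap_index = haps, hap_start = starts, hap_end = starts + lens - 1L,
    strand = strands, seq = seqs, stringsAsFactors = FALSE)
  structure(reads, ops = ops, individual_id = d$individual_id, params = p,
            class = c("simulated_reads", "data.frame"))
}

COMP_LOOKUP <- local({
  m <- raw(256)
  m[as.integer(charToRaw("ACGTN")) + 1L] <- charToRaw("TGCAN")
  m
})

rev_comp_raw <- function(r) rev(COMP_LOOKUP[as.integer(r) + 1L])

#' Write simulated reads as FASTQ
#'
#' Quality strings are constant Q20 placeholders; the analysis does not use
#' base qualities.
#'
#' @param reads a \code{simulated_reads} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("5", nchar(reads$seq))  # Phred 20
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$read_id)
  out[seq(2L, length(out), 4L)] <- reads$seq
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file path.
#' @return data.frame with \code{read_id} and \code{seq}.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---------------------------------------------------------------------------
# Analytic alignment projection
# ---------------------------------------------------------------------------

# Decompose a haplotype interval [a, b] through the coord_map into pieces.
decompose_interval <- function(cm, a, b) {
  idx <- which(cm$hap_end >= a & cm$hap_start <= b)
  out <- cm[idx, , drop = FALSE]
  clip_l <- pmax(0L, a - out$hap_start)
  clip_r <- pmax(0L, out$hap_end - b)
  out$hap_start <- out$hap_start + clip_l
  out$hap_end <- out$hap_end - clip_r
  out$ref_start <- ifelse(out$inserted, out$ref_start,
                          out$ref_start + clip_l)
  out$ref_end <- ifelse(out$inserted, out$ref_end, out$ref_end - clip_r)
  out
}

# CIGAR runs for one piece of an alignment record: base_op runs split at
# the noise indels falling inside the piece (positions in clean source
# offsets). Deletions at a position precede insertions at the same
# position (the base is removed first, the extra base inserted after it).
piece_runs <- function(lo, hi, base_op, delpos, inspos, hi_rec) {
  dsel <- delpos[delpos >= lo & delpos <= hi]
  isel <- inspos[inspos >= lo & inspos <= hi & inspos < hi_rec]
  nd <- length(dsel); ni <- length(isel)
  if (nd + ni == 0L) return(list(op = base_op, len = hi - lo + 1L))
  ev_pos <- c(dsel, isel)
  ev_ins <- c(rep(FALSE, nd), rep(TRUE, ni))
  o <- order(ev_pos, ev_ins)
  ev_pos <- ev_pos[o]; ev_ins <- ev_ins[o]
  n <- length(ev_pos)
  cur_prev <- c(lo, ev_pos[-n] + 1L)
  mlen <- ev_pos - cur_prev + as.integer(ev_ins)
  xop <- ifelse(ev_ins, "I", if (base_op == "I") "" else "D")
  op <- c(rbind(rep(base_op, n), xop), base_op)
  len <- c(rbind(mlen, rep(1L, n)), hi - ev_pos[n])
  list(op = op, len = as.integer(len))
}

# Build CIGAR run list for one alignment record from its pieces (hap
# coordinates, record-contiguous) and the read's indel noise positions
# (relative to the read's source interval start).
record_cigar <- function(pieces, delpos, inspos, read_src_start) {
  np <- nrow(pieces)
  hi_rec <- pieces$hap_end[np] - read_src_start + 1L
  ops_op <- vector("list", 2L * np)
  ops_len <- vector("list", 2L * np)
  last_ref_end <- NA_integer_
  for (j in seq_len(np)) {
    if (!pieces$inserted[j] && !is.na(last_ref_end)) {
      gap <- pieces$ref_start[j] - last_ref_end - 1L
      if (gap > 0L) {
        ops_op[[2L * j - 1L]] <- "D"
        ops_len[[2L * j - 1L]] <- gap
      }
    }
    pr <- piece_runs(pieces$hap_start[j] - read_src_start + 1L,
                     pieces$hap_end[j] - read_src_start + 1L,
                     if (pieces$inserted[j]) "I" else "M",
                     delpos, inspos, hi_rec)
    ops_op[[2L * j]] <- pr$op
    ops_len[[2L * j]] <- pr$len
    if (!pieces$inserted[j]) last_ref_end <- pieces$ref_end[j]
  }
  op <- unlist(ops_op); len <- unlist(ops_len)
  keep <- len > 0L & op != ""
  op <- op[keep]; len <- len[keep]
  if (length(op) > 1L) {
    same <- op[-1L] == op[-length(op)]
    grp <- cumsum(c(TRUE, !same))
    len <- as.integer(rowsum(len, grp))
    op <- op[!duplicated(grp)]
  }
  list(op = op, len = len)
}

#' Project simulated reads to reference alignments
#'
#' Decomposes each read's source haplotype interval through the haplotype
#' coordinate map into one or more reference-space alignment segments. A
#' read spanning the junction of a tandem duplication yields two segments
#' whose reference coordinates jump backward (the tandem-duplication split
#' signature); reads on a recombinant wild-type haplotype yield a single
#' contiguous segment. Small reference gaps (<= \code{join_tol}) and
#' insertion blocks interior to a segment are absorbed into the CIGAR as D/I
#' operations, as an aligner would represent them; simulated indel noise is
#' reflected in the CIGAR. The longest segment of each read is primary, the
#' others supplementary.
#'
#' @param reads a \code{simulated_reads} object.
#' @param d the \code{diplotype} the reads were simulated from.
#' @param join_tol reference-gap dead zone absorbed into one alignment (bp).
#' @param mapq mapping quality assigned to projected records.
#' @return An object of class \code{alignments}: a data.frame with columns
#'   \code{read_id}, \code{ref_start}, \code{ref_end}, \code{read_start},
#'   \code{read_end} (query coordinates in reference-forward orientation),
#'   \code{read_len}, \code{strand}, \code{mapq}, \code{is_supplementary},
#'   \code{cigar}, \code{seq}.
#' @export
project_alignments <- function(reads, d, join_tol = 50L, mapq = 60L) {
  stopifnot(inherits(reads, "simulated_reads"), inherits(d, "diplotype"))
  ops <- attr(reads, "ops")
  cms <- lapply(d$haplotypes, `[[`, "coord_map")
  res <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    res[[i]] <- project_one(reads$hap_start[i], reads$hap_end[i],
                            ops[[i]], cms[[reads$hap_index[i]]], join_tol)
  }
  nrec <- vapply(res, function(r) length(r$ref_start), integer(1))
  idx <- rep.int(seq_len(nrow(reads)), nrec)
  pull <- function(f) as.integer(unlist(lapply(res, `[[`, f),
                                        use.names = FALSE))
  out <- data.frame(
    read_id = reads$read_id[idx],
    ref_start = pull("ref_start"), ref_end = pull("ref_end"),
    read_start = pull("read_start"), read_end = pull("read_end"),
    read_len = pull("read_len"),
    strand = reads$strand[idx], mapq = as.integer(mapq),
    is_supplementary = unlist(lapply(res, `[[`, "is_supplementary"),
                              use.names = FALSE),
    cigar = unlist(lapply(res, `[[`, "cigar"), use.names = FALSE),
    seq = "", stringsAsFactors = FALSE)
  # sequence slice in reference-forward orientation
  fwd <- reads$seq
  minus <- reads$strand == "-"
  fwd[minus] <- vapply(fwd[minus], function(s)
    rawToChar(rev_comp_raw(charToRaw(s))), character(1), USE.NAMES = FALSE)
  out$seq <- substr(fwd[idx], out$read_start, out$read_end)
  class(out) <- c("alignments", "data.frame")
  out
}

project_one <- function(h1, h2, rel_ops, cm, join_tol) {
  pieces <- decompose_interval(cm, h1, h2)
  # group pieces into alignment records: a new record starts when the
  # reference rewinds or skips by more than join_tol
  grp <- integer(nrow(pieces))
  g <- 1L
  last_ref_end <- NA_integer_
  for (j in seq_len(nrow(pieces))) {
    if (!pieces$inserted[j]) {
      if (!is.na(last_ref_end)) {
        gap <- pieces$ref_start[j] - last_ref_end - 1L
        if (gap < 0L || gap > join_tol) g <- g + 1L
      }
      last_ref_end <- pieces$ref_end[j]
    }
    grp[j] <- g
  }
  L0 <- h2 - h1 + 1L
  if (is.null(rel_ops)) {
    inspos <- delpos <- integer(0)
  } else {
    inspos <- sort(rel_ops[rel_ops[, "kind"] == 2L, "pos"])
    delpos <- sort(rel_ops[rel_ops[, "kind"] == 3L, "pos"])
  }
  read_len <- L0 - length(delpos) + length(inspos)

  v_rs <- v_re <- v_qs <- v_qe <- integer(0)
  v_cig <- character(0)
  for (gg in unique(grp)) {
    pcs <- pieces[grp == gg, , drop = FALSE]
    real <- !pcs$inserted
    if (!any(real)) next  # read entirely inside an insertion: unmapped
    # leading/trailing inserted pieces become clipped read sequence
    first_real <- which(real)[1L]
    last_real <- tail(which(real), 1L)
    pcs <- pcs[first_real:last_real, , drop = FALSE]
    cg <- record_cigar(pcs, delpos, inspos, h1)
    ref_start <- pcs$ref_start[1L]
    ref_end <- pcs$ref_end[nrow(pcs)]
    a <- pcs$hap_start[1L] - h1 + 1L     # clean-offset span of the record
    b <- pcs$hap_end[nrow(pcs)] - h1 + 1L
    # trim leading/trailing deletion ops (noise deletions at record edges)
    while (length(cg$op) && cg$op[1L] == "D") {
      ref_start <- ref_start + cg$len[1L]
      a <- a + cg$len[1L]
      cg$op <- cg$op[-1L]; cg$len <- cg$len[-1L]
    }
    while (length(cg$op) && cg$op[length(cg$op)] == "D") {
      n <- length(cg$op)
      ref_end <- ref_end - cg$len[n]
      b <- b - cg$len[n]
      cg$op <- cg$op[-n]; cg$len <- cg$len[-n]
    }
    if (!length(cg$op)) next
    # read coordinates of clean offsets a..b (reference-forward orientation)
    v_rs <- c(v_rs, ref_start); v_re <- c(v_re, ref_end)
    v_qs <- c(v_qs, a - sum(delpos < a) + sum(inspos < a))
    v_qe <- c(v_qe, b - sum(delpos <= b) + sum(inspos < b))
    v_cig <- c(v_cig, paste0(cg$len, cg$op, collapse = ""))
  }
  if (!length(v_rs))
    return(list(ref_start = integer(0), ref_end = integer(0),
                read_start = integer(0), read_end = integer(0),
                read_len = integer(0), is_supplementary = logical(0),
                cigar = character(0)))
  supp <- seq_along(v_rs) != which.max(v_qe - v_qs)  # primary = longest
  list(ref_start = v_rs, ref_end = v_re, read_start = v_qs, read_end = v_qe,
       read_len = rep.int(read_len, length(v_rs)), is_supplementary = supp,
       cigar = v_cig)
}

# ---------------------------------------------------------------------------
# SNP panel simulation
# ---------------------------------------------------------------------------

# Transmitted haplotype index at given positions for one parent.
transmitted_hap <- function(events, parent, positions) {
  ev <- events[events$parent == parent & events$kind == "ahr_crossover", ,
               drop = FALSE]
  if (!nrow(ev)) {
    start <- 1L
    ne <- events[events$parent == parent, , drop = FALSE]
    if (nrow(ne)) start <- ne$from_hap[1L]
    return(rep(start, length(positions)))
  }
  ev <- ev[order(ev$position), , drop = FALSE]
  hap <- rep(ev$from_hap[1L], length(positions))
  for (k in seq_len(nrow(ev)))
    hap[positions > ev$position[k]] <- ev$to_hap[k]
  hap
}

#' Simulate a 50K-style SNP panel for a trio
#'
#' Marker positions are uniform over the region; parental haplotype alleles
#' are drawn per marker from the population B-allele frequency; offspring
#' genotypes are transmitted according to the design's gamete events
#' (allelic crossovers switch the transmitted parental haplotype at the
#' event position). The truth phase is returned alongside the genotypes.
#'
#' @param design a \code{trio_design}.
#' @param seed integer RNG seed.
#' @param n_markers number of markers (default: one per 5 kb of region).
#' @param region \code{c(start, end)}; defaults to the design's segment.
#' @param baf_range population B-allele frequencies are drawn uniformly
#'   from this range.
#' @return An object of class \code{snp_panel}: list with \code{genotypes}
#'   (data.frame pos/baf/sire/dam/offspring, genotypes as \code{"AA"},
#'   \code{"AB"}, \code{"BB"}), \code{truth_haps} (parental haplotype allele
#'   matrix) and \code{truth_transmitted} (per-marker transmitted haplotype
#'   index for each parent).
#' @export
simulate_snp_panel <- function(design, seed, n_markers = NULL, region = NULL,
                               baf_range = c(0.05, 0.95)) {
  stopifnot(inherits(design, "trio_design"))
  set.seed(seed)
  seg <- design$segment
  if (is.null(region)) region <- c(seg$start, seg$end)
  if (region[1] < seg$start || region[2] > seg$end)
    stop("simulate_snp_panel: region outside segment")
  if (is.null(n_markers))
    n_markers <- max(10L, round((region[2] - region[1] + 1) / 5000))
  if (n_markers < 10L) stop("simulate_snp_panel: need at least 10 markers")
  pos <- sort(sample(seq(region[1], region[2]), n_markers))
  baf <- runif(n_markers, baf_range[1], baf_range[2])
  draw <- function() ifelse(runif(n_markers) < baf, "B", "A")
  haps <- cbind(sire1 = draw(), sire2 = draw(), dam1 = draw(),
                dam2 = draw())
  pat_idx <- transmitted_hap(design$gamete_events, "sire", pos)
  mat_idx <- transmitted_hap(design$gamete_events, "dam", pos)
  pat <- ifelse(pat_idx == 1L, haps[, "sire1"], haps[, "sire2"])
  mat <- ifelse(mat_idx == 1L, haps[, "dam1"], haps[, "dam2"])
  gt <- function(a, b) paste0(pmin(a, b), pmax(a, b))
  genotypes <- data.frame(
    pos = pos, baf = baf,
    sire = gt(haps[, "sire1"], haps[, "sire2"]),
    dam = gt(haps[, "dam1"], haps[, "dam2"]),
    offspring = gt(pat, mat), stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes, truth_haps = haps,
                 truth_transmitted = data.frame(pos = pos, paternal = pat_idx,
                                                maternal = mat_idx),
                 truth_gametes = data.frame(pos = pos, paternal = pat,
                                            maternal = mat)),
            class = "snp_panel")
}

#' Write a trio genotype table as TSV
#'
#' @param panel an \code{snp_panel} (or a compatible genotype data.frame).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  g <- if (inherits(panel, "snp_panel")) panel$genotypes else panel
  write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trio genotype table written by \code{write_genotypes}
#'
#' @param path TSV path with columns pos, sire, dam, offspring.
#' @return data.frame.
#' @export
read_genotypes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
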