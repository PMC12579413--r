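# ---------------------------------------------------------------------------
# Standard-format I/O: FASTA, SAM/BAM, TSV, BED/bedGraph, minimal VCF.
# SAM is the canonical alignment interchange (plain text, writable without
# external tools); BAM and SAM are both readable through Rsamtools.
# ---------------------------------------------------------------------------

#' Write a genome segment as FASTA
#'
#' @param segment a \code{genome_segment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(segment, path) {
  x <- Biostrings::DNAStringSet(segment$sequence)
  names(x) <- sprintf("%s %d-%d", segment$name, segment$start, segment$end)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome segment from FASTA
#'
#' The genomic start coordinate is recovered from a \code{"start-end"}
#' token in the description line when present, else 1.
#'
#' @param path FASTA path (first record used).
#' @return A \code{genome_segment}.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)[1]
  toks <- strsplit(nm, "\\s+")[[1]]
  start <- 1L
  if (length(toks) > 1 && grepl("^[0-9]+-[0-9]+$", toks[2]))
    start <- as.integer(sub("-.*", "", toks[2]))
  genome_segment(toks[1], start, as.character(x[[1]]))
}

cigar_qwidth <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                               after.soft.clipping = FALSE)
}

hard_clip_lens <- function(cigar) {
  lead <- trail <- integer(length(cigar))
  i <- grepl("^[0-9]+H", cigar)
  lead[i] <- as.integer(sub("^([0-9]+)H.*", "\\1", cigar[i]))
  j <- grepl("[0-9]+H$", cigar)
  trail[j] <- as.integer(sub(".*?([0-9]+)H$", "\\1", cigar[j]))
  cbind(lead = lead, trail = trail)
}

reverse_cigar <- function(cigar) {
  vapply(cigar, function(cg) {
    lens <- regmatches(cg, gregexpr("[0-9]+", cg))[[1]]
    ops <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    paste0(rev(paste0(lens, ops)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rev_comp <- function(x) {
  vapply(x, function(s) rawToChar(rev_comp_raw(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# SAM-orientation representation of one alignment record (hard clips for the
# unaligned read portions, so SEQ is the aligned slice only).
sam_fields <- function(aln) {
  lclip <- aln$read_start - 1L
  rclip <- aln$read_len - aln$read_end
  minus <- aln$strand == "-"
  cig <- aln$cigar
  cig[minus] <- reverse_cigar(cig[minus])
  lc <- ifelse(minus, rclip, lclip)
  rc <- ifelse(minus, lclip, rclip)
  cig <- paste0(ifelse(lc > 0L, paste0(lc, "H"), ""), cig,
                ifelse(rc > 0L, paste0(rc, "H"), ""))
  seq <- aln$seq
  seq[minus] <- rev_comp(seq[minus])
  flag <- ifelse(minus, 16L, 0L) + ifelse(aln$is_supplementary, 2048L, 0L)
  data.frame(flag = flag, cigar = cig, seq = seq, stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Plain-text SAM with hard-clipped records (SEQ holds the aligned slice);
#' reads with several segments carry SA tags cross-referencing the others.
#'
#' @param aln an \code{alignments} data.frame.
#' @param segment the reference \code{genome_segment} (for the header).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(aln, segment, path) {
  sf <- sam_fields(aln)
  sa_unit <- sprintf("%s,%d,%s,%s,%d,0;", segment$name, aln$ref_start,
                     aln$strand, sf$cigar, aln$mapq)
  sa <- character(nrow(aln))
  for (rid in unique(aln$read_id[duplicated(aln$read_id)])) {
    idx <- which(aln$read_id == rid)
    for (i in idx)
      sa[i] <- paste0("SA:Z:", paste(sa_unit[setdiff(idx, i)],
                                     collapse = ""))
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", segment$name, segment$end),
    sprintf("@PG\tID:polledtrio\tPN:polledtrio"),
    paste0(
      aln$read_id, "\t", sf$flag, "\t", segment$name, "\t", aln$ref_start,
      "\t", aln$mapq, "\t", sf$cigar, "\t*\t0\t0\t", sf$seq, "\t*",
      ifelse(nzchar(sa), paste0("\t", sa), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' Uses Rsamtools; plain SAM files are converted to BAM internally. Query
#' coordinates are canonicalized to reference-forward orientation so that
#' downstream split-read geometry is strand-agnostic.
#'
#' @param path SAM or BAM file.
#' @return An \code{alignments} data.frame (see
#'   \code{\link{project_alignments}}; \code{seq} holds the aligned slice).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("read_alignments: no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("read_alignments: format error in '", path,
                               "': ", conditionMessage(e)))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "strand", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(b$qname))
    return(structure(data.frame(read_id = character(0)),
                     class = c("alignments", "data.frame")))
  keep <- !is.na(b$pos)
  cigar <- b$cigar[keep]
  pos <- b$pos[keep]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  qw_noclip <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = TRUE)
  qw_soft <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = FALSE)
  hc <- hard_clip_lens(cigar)
  read_len <- qw_soft + hc[, "lead"] + hc[, "trail"]
  sclip_lead <- integer(length(cigar))
  si <- grepl("^([0-9]+H)?[0-9]+S", cigar)
  sclip_lead[si] <- as.integer(sub("^(?:[0-9]+H)?([0-9]+)S.*", "\\1",
                                   cigar[si], perl = TRUE))
  lead <- hc[, "lead"] + sclip_lead
  rs_sam <- lead + 1L
  re_sam <- rs_sam + qw_noclip - 1L
  minus <- as.character(b$strand[keep]) == "-"
  rs <- ifelse(minus, read_len - re_sam + 1L, rs_sam)
  re <- ifelse(minus, read_len - rs_sam + 1L, re_sam)
  # core cigar without clips, in reference-forward orientation
  core <- gsub("(^([0-9]+[HS])+)|(([0-9]+[HS])+$)", "", cigar)
  core[minus] <- reverse_cigar(core[minus])
  seq <- as.character(b$seq[keep])
  seq[minus] <- rev_comp(seq[minus])
  out <- data.frame(
    read_id = b$qname[keep],
    ref_start = pos, ref_end = pos + refw - 1L,
    read_start = rs, read_end = re, read_len = read_len,
    strand = ifelse(minus, "-", "+"),
    mapq = b$mapq[keep],
    is_supplementary = bitwAnd(b$flag[keep], 2048L) > 0L,
    cigar = core, seq = seq, stringsAsFactors = FALSE)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Write breakpoint clusters as TSV
#'
#' @param clusters a \code{breakpoint_clusters} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  write.table(as.data.frame(clusters), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write breakpoint clusters as a minimal structural-variant VCF
#'
#' One VCF 4.2 record per cluster with SVTYPE (DEL/DUP/INV/BND), END and
#' SUPPORT INFO keys.
#'
#' @param clusters a \code{breakpoint_clusters} data.frame.
#' @param segment reference \code{genome_segment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sv_vcf <- function(clusters, segment, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", segment$name, segment$end),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(clusters)) {
    svtype <- c(DEL = "DEL", TANDEM_DUP = "DUP", INV = "INV",
                OTHER = "BND")[clusters$signature]
    pos <- pmin(clusters$consensus_left, clusters$consensus_right)
    end <- pmax(clusters$consensus_left, clusters$consensus_right)
    rows <- sprintf("%s\t%d\tsv%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SUPPORT=%d",
                    segment$name, pos, seq_len(nrow(clusters)), svtype,
                    svtype, end, clusters$support)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write copy-number calls as BED
#'
#' @param calls a \code{cnv_calls} data.frame.
#' @param segment reference \code{genome_segment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(calls, segment, path) {
  lines <- character(0)
  if (nrow(calls))
    lines <- sprintf("%s\t%d\t%d\t%s\t%.3f", segment$name, calls$start - 1L,
                     calls$end, calls$direction, calls$mean_ratio)
  writeLines(lines, path)
  invisible(path)
}

#' Write a depth track as bedGraph-style TSV
#'
#' @param track a \code{depth_track}.
#' @param segment reference \code{genome_segment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, segment, path) {
  writeLines(c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%.4f", segment$name,
                       track$window_start - 1L, track$window_end,
                       track$depth)), path)
  invisible(path)
}
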