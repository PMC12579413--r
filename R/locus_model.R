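#' @importFrom stats median rbinom rlnorm runif dbinom ppois poisson.test
#' @importFrom utils head tail write.table read.delim
NULL

# ---------------------------------------------------------------------------
# Canonical coordinates of the POLLED locus (BTA1, ARS-UCD1.3).
# The duplication unit is taken from the HGVS-style variant notation
# (g.2629116_2709243dup); an alternative printed coordinate set
# (2,629,113-2,709,240) differs by a 3-bp left-alignment ambiguity and is
# not used.
# ---------------------------------------------------------------------------

#' Canonical coordinates of the bovine POLLED locus
#'
#' Returns the coordinate constants used throughout the package: the locus
#' window on BTA1, the Friesian duplication unit (\code{pf_unit_start},
#' \code{pf_unit_end}, \code{pf_unit_length} = 80,128 bp), the positions of
#' the two variants internal to the duplicated copy (the P_T>A SNV at unit
#' offset 1 and the 2-bp TG deletion P_F2D at unit offsets 38-39), the
#' Celtic InDel coordinates, and the Mongolian and Guarani spans.
#'
#' @return A named list of integer coordinates (1-based, inclusive, bp).
#' @export
polled_locus <- function() {
  list(
    locus_start    = 2420000L,
    locus_end      = 2769999L,
    pc_del_start   = 2429326L,
    pc_del_end     = 2429335L,
    pc_dup_start   = 2429109L,
    pc_dup_end     = 2429320L,
    pf_unit_start  = 2629116L,
    pf_unit_end    = 2709243L,
    pf_unit_length = 80128L,
    pf_snv_offset  = 1L,     # P_T>A, first bp of the duplicated copy
    pf_del_offset  = 38L,    # P_F2D, 2-bp TG deletion
    pf_del_length  = 2L,
    pm_delins_start = 2695261L,
    pm_delins_end   = 2695267L,
    pm_dup_start    = 2695889L,
    pm_dup_end      = 2696047L,
    pg_dup_start    = 2614828L,
    pg_dup_end      = 2724315L,
    fv_breakpoint   = 2694883L
  )
}

# ---------------------------------------------------------------------------
# GenomeSegment
# ---------------------------------------------------------------------------

#' Create a genome segment
#'
#' A contiguous reference segment with 1-based inclusive genomic coordinates
#' and an ACGT sequence.
#'
#' @param name segment (chromosome) name.
#' @param start 1-based genomic position of the first base.
#' @param sequence DNA string over {A,C,G,T}.
#' @return An object of class \code{genome_segment}.
#' @export
genome_segment <- function(name, start, sequence) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence))
    stop("genome_segment: sequence alphabet restricted to ACGT")
  start <- as.integer(start)
  if (is.na(start) || start < 1L) stop("genome_segment: start must be >= 1")
  structure(list(name = as.character(name), start = start,
                 end = start + nchar(sequence) - 1L, sequence = sequence),
            class = "genome_segment")
}

#' @export
print.genome_segment <- function(x, ...) {
  cat(sprintf("<genome_segment> %s:%d-%d (%s bp)\n", x$name, x$start, x$end,
              format(nchar(x$sequence), big.mark = ",")))
  invisible(x)
}

seg_sub <- function(segment, s, e) {
  if (s < segment$start || e > segment$end || s > e)
    stop(sprintf("coordinates %d-%d outside segment %d-%d", s, e,
                 segment$start, segment$end))
  substr(segment$sequence, s - segment$start + 1L, e - segment$start + 1L)
}

# ---------------------------------------------------------------------------
# EditOp / AlleleSpec
# ---------------------------------------------------------------------------

EDIT_KINDS <- c("deletion", "insertion", "delins", "snv", "tandem_duplication",
                "dupins")

#' Create a sequence edit operation
#'
#' An edit on reference coordinates. Kinds: \code{deletion} (remove
#' \code{ref_start..ref_end}), \code{snv} (substitute one base),
#' \code{insertion} (insert \code{payload} after \code{ref_start}),
#' \code{delins} (replace the span by \code{payload}), \code{dupins}
#' (insert a copy of the span after \code{ref_end}, tandem), and
#' \code{tandem_duplication} (duplicate the span in place; the new copy may
#' carry \code{internal_edits}).
#'
#' @param kind one of the kinds above.
#' @param ref_start,ref_end 1-based inclusive span (equal for snv/insertion).
#' @param payload inserted/replacement sequence; ignored when
#'   \code{payload_from} is given.
#' @param payload_from optional \code{c(start, end)}: copy the payload from
#'   this reference span at build time (duplication-insertions).
#' @param internal_edits for \code{tandem_duplication} only: a data.frame
#'   with columns \code{offset} (1-based bp within the copy), \code{kind}
#'   (\code{"snv"} or \code{"deletion"}), \code{payload} (replacement base
#'   for snv, \code{""} for deletion) and \code{len} (bases affected).
#' @param orientation duplication orientation; only \code{"+"} is supported.
#' @return An object of class \code{edit_op}.
#' @export
edit_op <- function(kind, ref_start, ref_end = ref_start, payload = "",
                    payload_from = NULL, internal_edits = NULL,
                    orientation = "+") {
  kind <- match.arg(kind, EDIT_KINDS)
  ref_start <- as.integer(ref_start); ref_end <- as.integer(ref_end)
  if (is.na(ref_start) || is.na(ref_end) || ref_start > ref_end)
    stop("edit_op: malformed coordinates (ref_start must be <= ref_end)")
  if (!identical(orientation, "+"))
    stop("edit_op: only '+' orientation duplications are supported")
  payload <- toupper(as.character(payload))
  if (nchar(payload) && grepl("[^ACGT]", payload))
    stop("edit_op: payload alphabet restricted to ACGT")
  if (!is.null(internal_edits)) {
    if (kind != "tandem_duplication")
      stop("edit_op: internal_edits only allowed for tandem_duplication")
    internal_edits <- as.data.frame(internal_edits)
    stopifnot(all(c("offset", "kind", "payload", "len") %in%
                    names(internal_edits)))
    internal_edits <- internal_edits[order(internal_edits$offset), ,
                                     drop = FALSE]
    unit_len <- ref_end - ref_start + 1L
    ends <- internal_edits$offset + internal_edits$len - 1L
    if (any(internal_edits$offset < 1L) || any(ends > unit_len))
      stop("edit_op: internal_edits offsets outside 1..copy length")
    if (nrow(internal_edits) > 1L &&
        any(internal_edits$offset[-1L] <= ends[-nrow(internal_edits)]))
      stop("edit_op: internal_edits must be non-overlapping")
  }
  structure(list(kind = kind, ref_start = ref_start, ref_end = ref_end,
                 payload = payload, payload_from = payload_from,
                 internal_edits = internal_edits, orientation = orientation),
            class = "edit_op")
}

#' Length of the structural change described by an edit
#'
#' For duplications and deletions this is the affected reference span
#' (\code{ref_end - ref_start + 1}); for insertions and
#' duplication-insertions it is the inserted payload length; for
#' \code{delins} it is the payload length, with the signed net length change
#' and the replaced span attached as attributes \code{net} and \code{span}.
#'
#' @param edit an \code{edit_op}.
#' @return Length in bp (integer), possibly with attributes (see above).
#' @export
sv_length <- function(edit) {
  stopifnot(inherits(edit, "edit_op"))
  span <- edit$ref_end - edit$ref_start + 1L
  pay <- if (!is.null(edit$payload_from))
    as.integer(edit$payload_from[2L] - edit$payload_from[1L] + 1L)
  else nchar(edit$payload)
  switch(edit$kind,
    deletion = span,
    tandem_duplication = span,
    snv = 1L,
    insertion = as.integer(pay),
    dupins = span,
    delins = {
      out <- as.integer(pay)
      attr(out, "net") <- as.integer(pay - span)
      attr(out, "span") <- span
      out
    })
}

#' Create an allele specification
#'
#' @param allele_id allele label (\code{"p"}, \code{"P_C"}, \code{"P_F"},
#'   \code{"P_M"}, \code{"P_G"} or a custom label).
#' @param edits list of \code{edit_op}s, non-overlapping; sorted internally
#'   by \code{ref_start}.
#' @param dominance \code{"polled"} (dominant) or \code{"wildtype"}.
#' @return An object of class \code{allele_spec}.
#' @export
allele_spec <- function(allele_id, edits = list(),
                        dominance = c("polled", "wildtype")) {
  dominance <- match.arg(dominance)
  if (length(edits)) {
    stopifnot(all(vapply(edits, inherits, logical(1), "edit_op")))
    edits <- edits[order(vapply(edits, `[[`, integer(1), "ref_start"))]
    if (length(edits) > 1L) {
      s <- vapply(edits, `[[`, integer(1), "ref_start")
      e <- vapply(edits, `[[`, integer(1), "ref_end")
      if (any(s[-1L] <= e[-length(e)]))
        stop("allele_spec: edits must be non-overlapping")
    }
  }
  structure(list(allele_id = allele_id, edits = edits, dominance = dominance),
            class = "allele_spec")
}

#' @export
print.allele_spec <- function(x, ...) {
  cat(sprintf("<allele_spec> %s (%s), %d edit(s)\n", x$allele_id,
              x$dominance, length(x$edits)))
  for (e in x$edits)
    cat(sprintf("  %s %d-%d\n", e$kind, e$ref_start, e$ref_end))
  invisible(x)
}

#' Built-in POLLED allele specifications
#'
#' Returns the allele specification for one of the described POLLED
#' variants, on ARS-UCD1.3 coordinates:
#' \itemize{
#'   \item \code{p}: wild-type horned allele, no edits.
#'   \item \code{P_C} (Celtic): the 10-bp deletion at 2,429,326-2,429,335
#'     replaced by a 212-bp copy of 2,429,109-2,429,320 (net +202 bp).
#'   \item \code{P_F} (Friesian): tandem duplication of
#'     2,629,116-2,709,243 (80,128 bp); the new copy carries the P_T>A SNV
#'     at its first bp and the 2-bp TG deletion (P_F2D) at bp 38.
#'   \item \code{P_M} (Mongolian): 7-bp delins (TCTGAA) at
#'     2,695,261-2,695,267 plus a 159-bp duplication-insertion of
#'     2,695,889-2,696,047.
#'   \item \code{P_G} (Guarani): tandem duplication of
#'     2,614,828-2,724,315.
#' }
#'
#' @param id allele label.
#' @return An \code{allele_spec}.
#' @export
polled_allele <- function(id = c("p", "P_C", "P_F", "P_M", "P_G")) {
  id <- match.arg(id)
  L <- polled_locus()
  switch(id,
    p = allele_spec("p", list(), "wildtype"),
    P_C = allele_spec("P_C", list(
      edit_op("delins", L$pc_del_start, L$pc_del_end,
              payload_from = c(L$pc_dup_start, L$pc_dup_end))), "polled"),
    P_F = allele_spec("P_F", list(
      edit_op("tandem_duplication", L$pf_unit_start, L$pf_unit_end,
              internal_edits = data.frame(
                offset = c(L$pf_snv_offset, L$pf_del_offset),
                kind = c("snv", "deletion"),
                payload = c("A", ""),
                len = c(1L, L$pf_del_length)))), "polled"),
    P_M = allele_spec("P_M", list(
      edit_op("delins", L$pm_delins_start, L$pm_delins_end,
              payload = "TCTGAA"),
      edit_op("dupins", L$pm_dup_start, L$pm_dup_end)), "polled"),
    P_G = allele_spec("P_G", list(
      edit_op("tandem_duplication", L$pg_dup_start, L$pg_dup_end)),
      "polled"))
}

# ---------------------------------------------------------------------------
# Haplotype construction
# ---------------------------------------------------------------------------

new_block <- function(hap_start, hap_end, ref_start, ref_end, copy_index,
                      inserted = FALSE, altered = FALSE) {
  data.frame(hap_start = as.integer(hap_start), hap_end = as.integer(hap_end),
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             copy_index = as.integer(copy_index), inserted = inserted,
             altered = altered)
}

# Apply internal edits to a duplication unit; returns the edited copy
# sequence and its mapping blocks expressed in reference coordinates
# (copy_index is assigned by the caller).
edited_copy <- function(unit_seq, unit_start, internal_edits) {
  unit_len <- nchar(unit_seq)
  if (is.null(internal_edits) || !nrow(internal_edits)) {
    return(list(seq = unit_seq,
                map = data.frame(ref_start = unit_start,
                                 ref_end = unit_start + unit_len - 1L,
                                 altered = FALSE)))
  }
  pieces <- character(0)
  map <- NULL
  cur <- 1L
  for (i in seq_len(nrow(internal_edits))) {
    off <- internal_edits$offset[i]
    len <- internal_edits$len[i]
    if (off > cur) {
      pieces <- c(pieces, substr(unit_seq, cur, off - 1L))
      map <- rbind(map, data.frame(ref_start = unit_start + cur - 1L,
                                   ref_end = unit_start + off - 2L,
                                   altered = FALSE))
    }
    if (internal_edits$kind[i] == "snv") {
      pieces <- c(pieces, internal_edits$payload[i])
      map <- rbind(map, data.frame(ref_start = unit_start + off - 1L,
                                   ref_end = unit_start + off + len - 2L,
                                   altered = TRUE))
      cur <- off + len
    } else if (internal_edits$kind[i] == "deletion") {
      cur <- off + len
    } else stop("unsupported internal edit kind")
  }
  if (cur <= unit_len) {
    pieces <- c(pieces, substr(unit_seq, cur, unit_len))
    map <- rbind(map, data.frame(ref_start = unit_start + cur - 1L,
                                 ref_end = unit_start + unit_len - 1L,
                                 altered = FALSE))
  }
  list(seq = paste(pieces, collapse = ""), map = map)
}

#' Build a haplotype from a reference segment and an allele specification
#'
#' Applies the allele's edits left to right and returns the edited sequence
#' together with a block coordinate map linking every haplotype position to
#' a reference position and a copy index (0 = original copy, >= 1 =
#' duplicated copies; pure insertions carry the left-flank anchor and an
#' \code{inserted} flag).
#'
#' @param segment a \code{genome_segment}.
#' @param spec an \code{allele_spec}; all edits must lie within the segment.
#' @return An object of class \code{haplotype}.
#' @export
build_haplotype <- function(segment, spec) {
  stopifnot(inherits(segment, "genome_segment"), inherits(spec, "allele_spec"))
  for (e in spec$edits)
    if (e$ref_start < segment$start || e$ref_end > segment$end)
      stop("build_haplotype: edit outside segment bounds")
  pieces <- character(0)
  blocks <- list()
  undo <- list()
  hap_cursor <- 0L
  ref_cursor <- segment$start

  push <- function(seq, ref_start, ref_end, copy_index, inserted = FALSE,
                   altered = FALSE) {
    n <- nchar(seq)
    if (n == 0L) return(invisible(NULL))
    pieces[[length(pieces) + 1L]] <<- seq
    blocks[[length(blocks) + 1L]] <<- new_block(
      hap_cursor + 1L, hap_cursor + n, ref_start, ref_end, copy_index,
      inserted, altered)
    hap_cursor <<- hap_cursor + n
    invisible(NULL)
  }
  flush_ref <- function(upto) {
    if (ref_cursor <= upto) {
      push(seg_sub(segment, ref_cursor, upto), ref_cursor, upto, 0L)
      ref_cursor <<- upto + 1L
    }
    invisible(NULL)
  }
  get_payload <- function(e) {
    if (!is.null(e$payload_from))
      seg_sub(segment, e$payload_from[1L], e$payload_from[2L])
    else e$payload
  }

  for (e in spec$edits) {
    if (e$kind == "deletion") {
      flush_ref(e$ref_start - 1L)
      undo[[length(undo) + 1L]] <- list(
        ref_start = e$ref_start, ref_end = e$ref_end,
        sequence = seg_sub(segment, e$ref_start, e$ref_end))
      ref_cursor <- e$ref_end + 1L
    } else if (e$kind == "snv") {
      flush_ref(e$ref_start - 1L)
      undo[[length(undo) + 1L]] <- list(
        ref_start = e$ref_start, ref_end = e$ref_end,
        sequence = seg_sub(segment, e$ref_start, e$ref_end))
      push(e$payload, e$ref_start, e$ref_end, 0L, altered = TRUE)
      ref_cursor <- e$ref_end + 1L
    } else if (e$kind == "insertion") {
      flush_ref(e$ref_start)
      push(get_payload(e), e$ref_start, e$ref_start,
           if (is.null(e$payload_from)) 0L else 1L, inserted = TRUE)
    } else if (e$kind == "delins") {
      flush_ref(e$ref_start - 1L)
      undo[[length(undo) + 1L]] <- list(
        ref_start = e$ref_start, ref_end = e$ref_end,
        sequence = seg_sub(segment, e$ref_start, e$ref_end))
      push(get_payload(e), e$ref_start - 1L, e$ref_start - 1L,
           if (is.null(e$payload_from)) 0L else 1L, inserted = TRUE)
      ref_cursor <- e$ref_end + 1L
    } else if (e$kind == "dupins") {
      flush_ref(e$ref_end)
      push(seg_sub(segment, e$ref_start, e$ref_end), e$ref_end, e$ref_end,
           1L, inserted = TRUE)
    } else if (e$kind == "tandem_duplication") {
      flush_ref(e$ref_end)  # copy 0 is unchanged reference
      unit <- seg_sub(segment, e$ref_start, e$ref_end)
      cp <- edited_copy(unit, e$ref_start, e$internal_edits)
      # copy-1 mapping blocks (split around internal deletions)
      off <- 1L
      for (j in seq_len(nrow(cp$map))) {
        w <- cp$map$ref_end[j] - cp$map$ref_start[j] + 1L
        push(substr(cp$seq, off, off + w - 1L), cp$map$ref_start[j],
             cp$map$ref_end[j], 1L, altered = cp$map$altered[j])
        off <- off + w
      }
    } else stop("unsupported edit kind: ", e$kind)
  }
  flush_ref(segment$end)

  h <- structure(list(
    allele_id = spec$allele_id,
    sequence = paste(unlist(pieces), collapse = ""),
    coord_map = do.call(rbind, blocks),
    segment_name = segment$name, segment_start = segment$start,
    segment_end = segment$end, spec = spec, undo = undo),
    class = "haplotype")
  validate_haplotype(h)
  h
}

#' Validate a haplotype's coordinate map
#'
#' Checks that the blocks tile \code{1..nchar(sequence)} without gaps or
#' overlaps and that non-inserted blocks have equal haplotype and reference
#' widths. Called after every construction; exported for use in tests.
#'
#' @param h a \code{haplotype}.
#' @return \code{h}, invisibly; errors if invalid.
#' @export
validate_haplotype <- function(h) {
  cm <- h$coord_map
  n <- nchar(h$sequence)
  if (cm$hap_start[1L] != 1L || cm$hap_end[nrow(cm)] != n)
    stop("coord_map does not span the haplotype")
  if (nrow(cm) > 1L && any(cm$hap_start[-1L] != cm$hap_end[-nrow(cm)] + 1L))
    stop("coord_map blocks do not tile the haplotype")
  w_h <- cm$hap_end - cm$hap_start
  w_r <- cm$ref_end - cm$ref_start
  if (any(!cm$inserted & w_h != w_r))
    stop("block haplotype/reference widths differ")
  invisible(h)
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype> %s: %s bp, %d block(s) [%s:%d-%d]\n",
              x$allele_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$coord_map), x$segment_name, x$segment_start,
              x$segment_end))
  invisible(x)
}

#' Map a haplotype position to reference coordinates
#'
#' @param h a \code{haplotype}.
#' @param hap_pos position in \code{1..nchar(h$sequence)}.
#' @return A list with \code{ref_pos}, \code{copy_index} and \code{inserted}
#'   (positions inside pure insertions report the left-flank reference
#'   coordinate with \code{inserted = TRUE}).
#' @export
liftover <- function(h, hap_pos) {
  stopifnot(inherits(h, "haplotype"))
  hap_pos <- as.integer(hap_pos)
  if (is.na(hap_pos) || hap_pos < 1L || hap_pos > nchar(h$sequence))
    stop("liftover: position out of range")
  cm <- h$coord_map
  i <- which(cm$hap_start <= hap_pos & cm$hap_end >= hap_pos)[1L]
  if (cm$inserted[i])
    list(ref_pos = cm$ref_start[i], copy_index = cm$copy_index[i],
         inserted = TRUE)
  else
    list(ref_pos = cm$ref_start[i] + (hap_pos - cm$hap_start[i]),
         copy_index = cm$copy_index[i], inserted = FALSE)
}

#' Reconstruct the reference sequence from a built haplotype
#'
#' Inverts \code{\link{build_haplotype}}: copy-0 blocks contribute their
#' sequence directly and spans removed or substituted by edits are restored
#' from the undo records captured at build time. The result is byte-exact.
#'
#' @param h a \code{haplotype} produced by \code{build_haplotype}.
#' @return The reference sequence as a character string.
#' @export
revert_haplotype <- function(h) {
  stopifnot(inherits(h, "haplotype"))
  chunks <- list()
  cm <- h$coord_map
  keep <- !cm$inserted & cm$copy_index == 0L & !cm$altered
  for (i in which(keep)) {
    chunks[[length(chunks) + 1L]] <- list(
      ref_start = cm$ref_start[i],
      seq = substr(h$sequence, cm$hap_start[i], cm$hap_end[i]))
  }
  for (u in h$undo)
    chunks[[length(chunks) + 1L]] <- list(ref_start = u$ref_start,
                                          seq = u$sequence)
  ord <- order(vapply(chunks, `[[`, integer(1), "ref_start"))
  chunks <- chunks[ord]
  pos <- h$segment_start
  res <- character(length(chunks))
  for (i in seq_along(chunks)) {
    if (chunks[[i]]$ref_start != pos)
      stop("revert_haplotype: reference coverage has a gap at ", pos)
    res[i] <- chunks[[i]]$seq
    pos <- pos + nchar(chunks[[i]]$seq)
  }
  if (pos != h$segment_end + 1L)
    stop("revert_haplotype: reconstructed length mismatch")
  paste(res, collapse = "")
}

# ---------------------------------------------------------------------------
# Recombination products
# ---------------------------------------------------------------------------

# Position within the edited copy aligned to a given unit offset.
copy_aligned_offset <- function(internal_edits, offset) {
  if (is.null(internal_edits) || !nrow(internal_edits)) return(offset)
  shift <- 0L
  for (i in seq_len(nrow(internal_edits))) {
    ie <- internal_edits[i, ]
    if (ie$kind != "deletion") next
    if (offset >= ie$offset + ie$len) shift <- shift + ie$len
    else if (offset >= ie$offset) return(ie$offset - shift)  # snap past del
  }
  offset - shift
}

#' Non-allelic homologous recombination product across a tandem duplication
#'
#' Models an unequal crossover between the two copies of a tandem
#' duplication in copy-alignment space: the product keeps the copy-0 prefix
#' up to \code{crossover_offset - 1} and continues with the copy-1 sequence
#' from the homologous aligned position onward, removing one unit's worth of
#' sequence. For the Friesian allele, any crossover offset beyond the last
#' internal variant (offset > 39) yields a product byte-identical to the
#' wild-type haplotype.
#'
#' @param h a \code{haplotype} carrying exactly one tandem duplication.
#' @param crossover_offset 1-based offset within the duplication unit.
#' @return A \code{haplotype} for the single-copy hybrid product.
#' @export
nahr_product <- function(h, crossover_offset) {
  stopifnot(inherits(h, "haplotype"))
  dup <- Filter(function(e) e$kind == "tandem_duplication", h$spec$edits)
  if (length(dup) != 1L)
    stop("nahr_product: haplotype must carry exactly one tandem duplication")
  dup <- dup[[1L]]
  unit_len <- dup$ref_end - dup$ref_start + 1L
  o <- as.integer(crossover_offset)
  if (is.na(o) || o < 1L || o > unit_len)
    stop("nahr_product: crossover_offset outside 1..unit length")
  ref_seq <- revert_haplotype(h)
  segment <- genome_segment(h$segment_name, h$segment_start, ref_seq)
  unit <- seg_sub(segment, dup$ref_start, dup$ref_end)
  cp <- edited_copy(unit, dup$ref_start, dup$internal_edits)
  o1 <- copy_aligned_offset(dup$internal_edits, o)

  prefix <- seg_sub(segment, segment$start, dup$ref_start + o - 2L)
  suffix <- if (dup$ref_end < segment$end)
    seg_sub(segment, dup$ref_end + 1L, segment$end) else ""
  tail_cp <- substr(cp$seq, o1, nchar(cp$seq))
  sequence <- paste0(prefix, tail_cp, suffix)

  # Blocks: copy-0 prefix, copy-1-derived unit remainder (split around any
  # internal deletions at offsets >= o), copy-0 suffix.
  blocks <- list()
  hap_cursor <- 0L
  add <- function(width, ref_start, ref_end, copy_index, altered = FALSE) {
    if (width <= 0L) return(invisible(NULL))
    blocks[[length(blocks) + 1L]] <<- new_block(
      hap_cursor + 1L, hap_cursor + width, ref_start, ref_end, copy_index,
      FALSE, altered)
    hap_cursor <<- hap_cursor + width
  }
  add(nchar(prefix), segment$start, dup$ref_start + o - 2L, 0L)
  # copy-1 map rows clipped at the aligned crossover point
  cum <- 0L
  for (j in seq_len(nrow(cp$map))) {
    w <- cp$map$ref_end[j] - cp$map$ref_start[j] + 1L
    row_start_cp <- cum + 1L; row_end_cp <- cum + w
    cum <- cum + w
    if (row_end_cp < o1) next
    clip <- max(o1, row_start_cp) - row_start_cp
    add(w - clip, cp$map$ref_start[j] + clip, cp$map$ref_end[j], 1L,
        cp$map$altered[j])
  }
  add(nchar(suffix), dup$ref_end + 1L, segment$end, 0L)

  undo <- list()  # no reference bases are lost relative to the product's map
  prod <- structure(list(
    allele_id = paste0(h$allele_id, "_nahr"),
    sequence = sequence, coord_map = do.call(rbind, blocks),
    segment_name = h$segment_name, segment_start = h$segment_start,
    segment_end = h$segment_end,
    spec = allele_spec(paste0(h$allele_id, "_nahr"), list(), "wildtype"),
    undo = undo), class = "haplotype")
  validate_haplotype(prod)
  prod
}

# Haplotype position of a reference coordinate on the copy-0 map.
hap_pos_of_ref <- function(h, ref_pos) {
  cm <- h$coord_map
  i <- which(!cm$inserted & cm$copy_index == 0L &
               cm$ref_start <= ref_pos & cm$ref_end >= ref_pos)
  if (!length(i)) return(NA_integer_)
  i <- i[1L]
  cm$hap_start[i] + (ref_pos - cm$ref_start[i])
}

#' Allelic homologous recombination product of two haplotypes
#'
#' Returns the recombinant that takes haplotype A up to and including the
#' reference breakpoint and haplotype B strictly after it, with a merged
#' coordinate map. The breakpoint must map to the original (copy 0)
#' reference on both haplotypes.
#'
#' @param hapA,hapB \code{haplotype}s built on the same segment.
#' @param breakpoint_ref reference coordinate of the crossover.
#' @return A \code{haplotype}.
#' @export
ahr_product <- function(hapA, hapB, breakpoint_ref) {
  stopifnot(inherits(hapA, "haplotype"), inherits(hapB, "haplotype"))
  bp <- as.integer(breakpoint_ref)
  posA <- hap_pos_of_ref(hapA, bp)
  posB <- hap_pos_of_ref(hapB, bp)
  if (is.na(posA) || is.na(posB))
    stop("ahr_product: breakpoint has no copy-0 reference mapping on both ",
         "haplotypes")
  shift <- posA - posB
  cmA <- hapA$coord_map
  cmB <- hapB$coord_map
  keepA <- cmA[cmA$hap_start <= posA, , drop = FALSE]
  keepA$hap_end <- pmin(keepA$hap_end, posA)
  keepA$ref_end <- ifelse(keepA$inserted, keepA$ref_end,
                          keepA$ref_start + (keepA$hap_end - keepA$hap_start))
  keepB <- cmB[cmB$hap_end > posB, , drop = FALSE]
  clip <- pmax(0L, posB + 1L - keepB$hap_start)
  keepB$hap_start <- keepB$hap_start + clip
  keepB$ref_start <- ifelse(keepB$inserted, keepB$ref_start,
                            keepB$ref_start + clip)
  keepB$hap_start <- keepB$hap_start + shift
  keepB$hap_end <- keepB$hap_end + shift
  sequence <- paste0(substr(hapA$sequence, 1L, posA),
                     substr(hapB$sequence, posB + 1L, nchar(hapB$sequence)))
  undo <- c(
    Filter(function(u) u$ref_end <= bp, hapA$undo),
    Filter(function(u) u$ref_start > bp, hapB$undo))
  prod <- structure(list(
    allele_id = paste0(hapA$allele_id, "x", hapB$allele_id),
    sequence = sequence, coord_map = rbind(keepA, keepB),
    segment_name = hapA$segment_name, segment_start = hapA$segment_start,
    segment_end = hapA$segment_end,
    spec = allele_spec(paste0(hapA$allele_id, "x", hapB$allele_id), list(),
                       "wildtype"),
    undo = undo), class = "haplotype")
  validate_haplotype(prod)
  prod
}

# ---------------------------------------------------------------------------
# Variant geometry
# ---------------------------------------------------------------------------

allele_span <- function(a) {
  s <- vapply(a$edits, `[[`, integer(1), "ref_start")
  e <- vapply(a$edits, `[[`, integer(1), "ref_end")
  c(min(s), max(e))
}

#' Distance between the proximal coordinates of two alleles
#'
#' Reports the distance between the proximal (lowest) edit coordinates of
#' the two alleles, optionally rounded to a multiple of \code{rounding} bp.
#' If one allele's edit span is contained in the other's, the distance is 0
#' and the attribute \code{containment} is set.
#'
#' @param a,b \code{allele_spec}s with at least one edit each.
#' @param rounding round to the nearest multiple of this many bp (0 = none).
#' @return Distance in bp, with attribute \code{containment} (logical).
#' @export
variant_distance <- function(a, b, rounding = 0) {
  stopifnot(inherits(a, "allele_spec"), inherits(b, "allele_spec"))
  if (!length(a$edits) || !length(b$edits))
    stop("variant_distance: allele without edits (wild type) has no span")
  sa <- allele_span(a); sb <- allele_span(b)
  contained <- (sa[1] >= sb[1] && sa[2] <= sb[2]) ||
    (sb[1] >= sa[1] && sb[2] <= sa[2])
  d <- if (contained) 0L else abs(sa[1] - sb[1])
  if (rounding > 0) d <- round(d / rounding) * rounding
  structure(as.integer(d), containment = contained)
}

# ---------------------------------------------------------------------------
# HGVS-like serialization
# ---------------------------------------------------------------------------

#' Format an edit operation as an HGVS-like string
#'
#' @param edit an \code{edit_op}.
#' @return A character scalar such as \code{"g.2629116_2709243dup"}.
#' @export
format_hgvs <- function(edit) {
  stopifnot(inherits(edit, "edit_op"))
  span <- if (edit$ref_start == edit$ref_end)
    sprintf("g.%d", edit$ref_start)
  else sprintf("g.%d_%d", edit$ref_start, edit$ref_end)
  switch(edit$kind,
    deletion = paste0(span, "del"),
    snv = sprintf("g.%dN>%s", edit$ref_start, edit$payload),
    insertion = paste0(span, "ins", edit$payload),
    delins = paste0(span, "delins",
                    if (!is.null(edit$payload_from))
                      sprintf("[copy g.%d_%d]", edit$payload_from[1L],
                              edit$payload_from[2L]) else edit$payload),
    dupins = paste0(span, "dupins"),
    tandem_duplication = paste0(span, "dup"))
}
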