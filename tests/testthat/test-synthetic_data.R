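# Reference generation, trio designs, read simulation with truth
# provenance, analytic alignment projection, SNP panels.

test_that("make_reference is deterministic, repeat-free and hits the
           requested GC", {
  a <- make_reference(20000, seed = 7, gc_fraction = 0.42,
                      max_exact_repeat = 30)
  b <- make_reference(20000, seed = 7, gc_fraction = 0.42,
                      max_exact_repeat = 30)
  expect_identical(a$sequence, b$sequence)
  # brute-force repeat oracle on a small sequence: compare all substring
  # pairs of length k
  brute_repeat <- function(seq, k) {
    subs <- substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq))
    anyDuplicated(subs) > 0
  }
  small <- make_reference(2000, seed = 11, max_exact_repeat = 20)
  expect_false(brute_repeat(small$sequence, 20))
  expect_identical(has_repeat(small$sequence, 20),
                   brute_repeat(small$sequence, 20))
  # a planted repeat is caught by the screen
  planted <- paste0(small$sequence, substr(small$sequence, 101, 130))
  expect_true(has_repeat(planted, 30))
  expect_true(brute_repeat(planted, 30))
  gc <- mean(strsplit(a$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.42), 0.02)
})

test_that("polled_reference anchors the diagnostic bases", {
  seg <- locus_seg()
  L <- polled_locus()
  o <- function(p) p - seg$start + 1L
  expect_identical(substr(seg$sequence, o(L$pf_unit_start),
                          o(L$pf_unit_start)), "T")
  expect_identical(substr(seg$sequence, o(L$pf_unit_start + 37L),
                          o(L$pf_unit_start + 38L)), "TG")
})

test_that("design_trio realizes the named scenarios", {
  seg <- locus_seg()
  L <- polled_locus()
  wt_seq <- locus_p()$sequence

  d <- design_trio("HF_expected", seg)
  expect_identical(d$sire$haplotypes[[1]]$allele_id, "P_F")
  expect_identical(d$offspring$haplotypes[[1]]$allele_id, "P_F")

  d3 <- design_trio("HF_H3H4", seg, params = list(nahr_offset = 40000))
  # offspring POLLED-locus genotype p/p: paternal gamete byte-identical to
  # the wild type
  expect_identical(d3$offspring$haplotypes[[1]]$sequence, wt_seq)
  expect_error(design_trio("HF_H3H4", seg, params = list(nahr_offset = 20)),
               "diagnostic")

  d1 <- design_trio("HF_H1", seg)
  expect_identical(nchar(d1$offspring$haplotypes[[1]]$sequence),
                   nchar(wt_seq) + 40000L)

  d2 <- design_trio("HF_H2", seg)
  expect_identical(nchar(d2$offspring$haplotypes[[1]]$sequence),
                   nchar(wt_seq) - L$pf_unit_length - 10000L)

  fv <- design_trio("FV_ahr_wildtype", seg)
  expect_identical(fv$dam$haplotypes[[1]]$allele_id, "P_F")
  expect_identical(fv$dam$haplotypes[[2]]$allele_id, "P_C")  # trans phase
  expect_identical(fv$offspring$haplotypes[[2]]$sequence, wt_seq)
  expect_identical(fv$gamete_events$position, L$fv_breakpoint)

  cis <- design_trio("FV_cis_fusion", seg)
  expect_identical(nchar(cis$offspring$haplotypes[[2]]$sequence),
                   nchar(wt_seq) + 202L + 80126L)
  expect_error(design_trio("FV_ahr_wildtype", seg,
                           params = list(breakpoint = L$pc_del_start)),
               "breakpoint")
})

test_that("simulate_reads meets the coverage target, is deterministic and
           noiseless reads are exact substrings", {
  seg <- locus_seg()
  d <- design_trio("HF_expected", seg)
  p0 <- read_sim_params(coverage = 5, mismatch_rate = 0, ins_rate = 0,
                        del_rate = 0)
  reads <- simulate_reads(d$offspring, p0, seed = 21)
  ref_len <- seg$end - seg$start + 1L
  total <- sum(nchar(reads$seq))
  expect_lt(abs(total - 5 * ref_len) / (5 * ref_len), 0.1)
  # noiseless limit: every read is an exact (possibly reverse-complemented)
  # substring of its source haplotype
  for (i in sample(nrow(reads), 25)) {
    h <- d$offspring$haplotypes[[reads$hap_index[i]]]
    src <- substr(h$sequence, reads$hap_start[i], reads$hap_end[i])
    obs <- reads$seq[i]
    if (reads$strand[i] == "-")
      obs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(obs)))
    expect_identical(obs, src)
  }
  fwd <- reads[reads$strand == "+", ]
  i <- which.max(fwd$hap_end - fwd$hap_start)
  h <- d$offspring$haplotypes[[fwd$hap_index[i]]]
  expect_identical(fwd$seq[i],
                   substr(h$sequence, fwd$hap_start[i], fwd$hap_end[i]))

  # byte-identical FASTQ under a fixed seed
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(d$offspring, p0, seed = 22), f1)
  write_fastq(simulate_reads(d$offspring, p0, seed = 22), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(read_sim_params(coverage = 0), "coverage")
})

test_that("projection yields the tandem-duplication split signature and
           contiguity for recombinant haplotypes", {
  seg <- locus_seg()
  L <- polled_locus()
  pf <- locus_pf()
  d <- diplotype("x", "sire", pf, pf)
  # hand-placed noiseless read spanning the copy0/copy1 junction
  junction <- L$pf_unit_end - seg$start + 1L
  reads <- structure(
    data.frame(read_id = "r1", hap_index = 1L,
               hap_start = junction - 3000L, hap_end = junction + 3000L,
               strand = "+",
               seq = substr(pf$sequence, junction - 3000L,
                            junction + 3000L),
               stringsAsFactors = FALSE),
    ops = list(NULL), individual_id = "x",
    params = read_sim_params(1), class = c("simulated_reads", "data.frame"))
  aln <- project_alignments(reads, d)
  expect_identical(nrow(aln), 2L)
  expect_identical(aln$ref_end[1], L$pf_unit_end)
  expect_identical(aln$ref_start[2], L$pf_unit_start)
  expect_identical(sum(aln$is_supplementary), 1L)

  # read fully inside copy 0: one segment, identity mapping
  reads$hap_start <- junction - 5000L; reads$hap_end <- junction - 1000L
  reads$seq <- substr(pf$sequence, junction - 5000L, junction - 1000L)
  aln1 <- project_alignments(reads, d)
  expect_identical(nrow(aln1), 1L)
  expect_identical(aln1$ref_end - aln1$ref_start,
                   aln1$read_end - aln1$read_start)

  # read crossing the P_F2D site gets the 2-bp deletion in its CIGAR
  reads$hap_start <- junction + 10L; reads$hap_end <- junction + 2000L
  reads$seq <- substr(pf$sequence, junction + 10L, junction + 2000L)
  aln2 <- project_alignments(reads, d)
  expect_identical(nrow(aln2), 1L)
  expect_match(aln2$cigar, "2D")

  # recombinant wild-type haplotype: single contiguous segment across the
  # former junction region
  d3 <- design_trio("HF_H3H4", seg)
  reads$hap_start <- junction - 3000L; reads$hap_end <- junction + 3000L
  reads$seq <- substr(d3$offspring$haplotypes[[1]]$sequence,
                      junction - 3000L, junction + 3000L)
  aln3 <- project_alignments(reads, d3$offspring)
  expect_identical(nrow(aln3), 1L)
  expect_identical(aln3$cigar, "6001M")
})

test_that("truth conservation: noiseless projected segments reconstruct the
           haplotype interval exactly", {
  seg <- locus_seg()
  d <- design_trio("HF_expected", seg)
  p0 <- read_sim_params(coverage = 1, mismatch_rate = 0, ins_rate = 0,
                        del_rate = 0)
  reads <- simulate_reads(d$offspring, p0, seed = 31)
  aln <- project_alignments(reads, d$offspring)
  # per read: sum of aligned query spans plus clipped insertion pieces
  # equals the read length; sequence slices concatenate to the read
  for (rid in sample(unique(aln$read_id), 30)) {
    a <- aln[aln$read_id == rid, , drop = FALSE]
    a <- a[order(a$read_start), , drop = FALSE]
    i <- which(reads$read_id == rid)
    fwd <- reads$seq[i]
    if (reads$strand[i] == "-")
      fwd <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(fwd)))
    expect_identical(
      paste(substring(fwd, a$read_start, a$read_end), collapse = ""),
      paste(a$seq, collapse = ""))
    # aligned spans tile the read except clipped inserted-block pieces
    expect_true(all(diff(a$read_start) > 0))
  }
})

test_that("coverage is Poisson-like and uniform over copy-neutral
           sequence", {
  seg <- locus_seg()
  L <- polled_locus()
  wt <- locus_p()
  d <- diplotype("w", "dam", wt, wt)
  reads <- simulate_reads(d, read_sim_params(coverage = 12), seed = 41)
  aln <- project_alignments(reads, d)
  tr <- compute_depth(aln, c(L$locus_start, L$locus_end),
                      window = 1000, step = 1000)
  expect_lt(abs(mean(tr$depth) - 12) / 12, 0.1)
  expect_lt(abs(median(tr$ratio) - 1), 0.1)
})

test_that("simulate_snp_panel transmits alleles per design and records
           truth", {
  seg <- locus_seg()
  d <- design_trio("HF_expected", seg)
  panel <- simulate_snp_panel(d, seed = 5)
  expect_gte(nrow(panel$genotypes), 10L)
  expect_true(all(diff(panel$genotypes$pos) > 0))
  # no events: fully Mendelian-consistent by construction
  rep <- mendelian_consistency(panel$genotypes)
  expect_identical(rep$conflicts, 0L)
  expect_identical(rep$verdict, "pass")

  fv <- design_trio("FV_ahr_wildtype", seg)
  pfv <- simulate_snp_panel(fv, seed = 6)
  # the maternal transmitted haplotype switches exactly once, at the
  # designed breakpoint
  tt <- pfv$truth_transmitted
  sw <- which(diff(tt$maternal) != 0)
  expect_identical(length(sw), 1L)
  bp <- polled_locus()$fv_breakpoint
  expect_true(tt$pos[sw] <= bp && tt$pos[sw + 1L] > bp)
  expect_error(simulate_snp_panel(d, seed = 1, n_markers = 5), "10")
  expect_error(simulate_snp_panel(d, seed = 1,
                                  region = c(seg$start - 10, seg$end)),
               "region")
})
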