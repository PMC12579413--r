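# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small 4-kb segment with a 1-kb tandem duplication mirroring the Friesian
# structure (SNV at copy offset 1, 2-bp deletion at copy offset 8).
toy_segment <- function() memo("toy_segment",
  make_reference(4000, seed = 3, gc_fraction = 0.42, max_exact_repeat = 30,
                 start = 1000, name = "toy"))

toy_dup_spec <- function() allele_spec("toy_dup", list(
  edit_op("tandem_duplication", 2000, 2999,
          internal_edits = data.frame(
            offset = c(1L, 8L), kind = c("snv", "deletion"),
            payload = c("A", ""), len = c(1L, 2L)))))

toy_wt <- function() memo("toy_wt",
  build_haplotype(toy_segment(), allele_spec("p", list(), "wildtype")))

toy_dup_hap <- function() memo("toy_dup_hap",
  build_haplotype(toy_segment(), toy_dup_spec()))

# Full-locus fixtures (built once; ~0.5 Mb of sequence work).
locus_seg <- function() memo("locus_seg", polled_reference(seed = 424242))
locus_p <- function() memo("locus_p",
  build_haplotype(locus_seg(), polled_allele("p")))
locus_pf <- function() memo("locus_pf",
  build_haplotype(locus_seg(), polled_allele("P_F")))
locus_pc <- function() memo("locus_pc",
  build_haplotype(locus_seg(), polled_allele("P_C")))

# One-row alignment segment for split-scan unit tests.
mk_seg <- function(read_id, rs, re, qs, qe, strand = "+", mapq = 60L,
                   supp = FALSE) {
  data.frame(read_id = read_id, ref_start = rs, ref_end = re,
             read_start = qs, read_end = qe, read_len = qe + 100L,
             strand = strand, mapq = mapq, is_supplementary = supp,
             cigar = sprintf("%dM", re - rs + 1L), seq = "",
             stringsAsFactors = FALSE)
}
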