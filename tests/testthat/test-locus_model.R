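# Sequence algebra of the POLLED alleles: edit lengths, haplotype
# construction, liftover, recombination products, variant geometry.

test_that("sv_length reproduces the printed variant sizes", {
  pf <- polled_allele("P_F")
  expect_identical(sv_length(pf$edits[[1]]), 80128L)

  pc <- polled_allele("P_C")
  len <- sv_length(pc$edits[[1]])
  expect_identical(as.integer(len), 212L)       # the 212-bp insertion
  expect_identical(attr(len, "net"), 202L)      # minus the 10-bp deletion
  expect_identical(attr(len, "span"), 10L)

  expect_identical(sv_length(edit_op("deletion", 100, 100)), 1L)
})

test_that("edit_op validates coordinates, alphabet and orientation", {
  expect_error(edit_op("deletion", 200, 100), "coordinates")
  expect_error(edit_op("insertion", 100, payload = "ACGX"), "alphabet")
  expect_error(edit_op("tandem_duplication", 1, 10, orientation = "-"),
               "orientation")
  expect_error(edit_op("tandem_duplication", 1, 10,
                       internal_edits = data.frame(
                         offset = 11L, kind = "snv", payload = "A",
                         len = 1L)),
               "offsets")
  expect_error(allele_spec("x", list(edit_op("deletion", 5, 10),
                                     edit_op("deletion", 8, 12))),
               "non-overlapping")
})

test_that("build_haplotype applies edits with exact length accounting", {
  seg <- toy_segment()
  wt <- toy_wt()
  expect_identical(wt$sequence, seg$sequence)
  expect_identical(nrow(wt$coord_map), 1L)
  expect_identical(wt$coord_map$copy_index, 0L)

  # toy Friesian analog: 1000-bp unit duplicated, copy 1 is 2 bp shorter
  h <- toy_dup_hap()
  expect_identical(nchar(h$sequence), 4000L + 998L)
  # string-construction oracle for the full sequence
  unit <- substr(seg$sequence, 1001, 2000)
  copy1 <- unit
  substr(copy1, 1, 1) <- "A"
  copy1 <- paste0(substr(copy1, 1, 7), substr(copy1, 10, 1000))
  oracle <- paste0(substr(seg$sequence, 1, 2000), copy1,
                   substr(seg$sequence, 2001, 4000))
  expect_identical(h$sequence, oracle)
})

test_that("built-in P_F and P_C haplotypes match the derived lengths and a
           string oracle", {
  seg <- locus_seg()
  L <- polled_locus()
  pf <- locus_pf()
  # 80,128-bp unit minus the 2-bp P_F2D deletion
  expect_identical(nchar(pf$sequence), nchar(seg$sequence) + 80126L)
  # independent string construction of the P_F haplotype
  ref <- seg$sequence
  o <- function(p) p - seg$start + 1L
  unit <- substr(ref, o(L$pf_unit_start), o(L$pf_unit_end))
  copy1 <- unit
  substr(copy1, 1, 1) <- "A"
  copy1 <- paste0(substr(copy1, 1, 37), substr(copy1, 40, 80128))
  oracle <- paste0(substr(ref, 1, o(L$pf_unit_end)), copy1,
                   substr(ref, o(L$pf_unit_end) + 1L, nchar(ref)))
  expect_identical(pf$sequence, oracle)

  pc <- locus_pc()
  expect_identical(nchar(pc$sequence), nchar(seg$sequence) + 202L)
  oracle_pc <- paste0(
    substr(ref, 1, o(L$pc_del_start) - 1L),
    substr(ref, o(L$pc_dup_start), o(L$pc_dup_end)),
    substr(ref, o(L$pc_del_end) + 1L, nchar(ref)))
  expect_identical(pc$sequence, oracle_pc)
})

test_that("liftover maps haplotype positions through the block map", {
  seg <- locus_seg()
  L <- polled_locus()
  wt <- locus_p()
  expect_identical(liftover(wt, 5L),
                   list(ref_pos = seg$start + 4L, copy_index = 0L,
                        inserted = FALSE))
  pf <- locus_pf()
  # first base after the junction re-enters the duplication start
  junction <- L$pf_unit_end - seg$start + 1L   # hap pos of last copy-0 base
  lo <- liftover(pf, junction + 1L)
  expect_identical(lo$ref_pos, L$pf_unit_start)
  expect_identical(lo$copy_index, 1L)
  # last base of a segment ending at the unit end maps to (unit end, copy 1)
  seg2 <- genome_segment("trim", seg$start,
                         substr(seg$sequence, 1, junction))
  pf2 <- build_haplotype(seg2, polled_allele("P_F"))
  lo2 <- liftover(pf2, nchar(pf2$sequence))
  expect_identical(lo2$ref_pos, L$pf_unit_end)
  expect_identical(lo2$copy_index, 1L)
  expect_error(liftover(wt, 0L), "range")
})

test_that("round trip: building then reverting reproduces the reference
           byte-exactly for every built-in allele", {
  seg <- locus_seg()
  for (id in c("p", "P_C", "P_F", "P_M", "P_G")) {
    h <- build_haplotype(seg, polled_allele(id))
    expect_identical(revert_haplotype(h), seg$sequence, label = id)
    expect_silent(validate_haplotype(h))
  }
})

test_that("nahr_product reconstructs the wild type beyond the internal
           variants and retains them for proximal crossovers", {
  wt <- toy_wt()
  h <- toy_dup_hap()
  # offsets past the last internal edit (deletion at 8-9): identity
  for (o in c(10L, 11L, 250L, 999L, 1000L))
    expect_identical(nahr_product(h, o)$sequence, wt$sequence,
                     label = paste("offset", o))
  # offset 1: the whole hybrid is copy 1 -> SNV and deletion retained
  p1 <- nahr_product(h, 1L)
  expect_identical(nchar(p1$sequence), 3998L)
  expect_false(identical(p1$sequence, wt$sequence))
  expect_identical(substr(p1$sequence, 1001, 1001), "A")
  # offset between the edits (e.g. 5): deletion retained, SNV not
  p5 <- nahr_product(h, 5L)
  expect_identical(nchar(p5$sequence), 3998L)
  expect_identical(substr(p5$sequence, 1001, 1001),
                   substr(wt$sequence, 1001, 1001))
  expect_error(nahr_product(wt, 10), "tandem duplication")
  expect_error(nahr_product(h, 0), "offset")
  expect_error(nahr_product(h, 1001), "offset")
})

test_that("nahr_product on the real P_F haplotype obeys the 80,128-bp
           reconstruction rule", {
  wt <- locus_p()
  pf <- locus_pf()
  for (o in c(40L, 10000L, 80128L))
    expect_identical(nahr_product(pf, o)$sequence, wt$sequence,
                     label = paste("offset", o))
  p20 <- nahr_product(pf, 20L)   # between the SNV and P_F2D
  expect_false(identical(p20$sequence, wt$sequence))
  expect_identical(nchar(p20$sequence), nchar(wt$sequence) - 2L)
})

test_that("ahr_product joins haplotypes at an allelic breakpoint", {
  L <- polled_locus()
  wt <- locus_p()
  pf <- locus_pf()
  pc <- locus_pc()
  # the study's crossover: skips both polled variants
  rec <- ahr_product(pf, pc, L$fv_breakpoint)
  expect_identical(rec$sequence, wt$sequence)
  # the complementary product fuses both variants in cis
  cis <- ahr_product(pc, pf, L$fv_breakpoint)
  expect_identical(nchar(cis$sequence), nchar(wt$sequence) + 202L + 80126L)
  expect_true(any(cis$coord_map$inserted))          # Celtic insertion
  expect_true(any(cis$coord_map$copy_index == 1L))  # duplicated copy
  # recombining identical wild types is the identity
  expect_identical(ahr_product(wt, wt, L$fv_breakpoint)$sequence,
                   wt$sequence)
  # breakpoint inside the Celtic deletion has no mapping on the P_C side
  expect_error(ahr_product(pf, pc, L$pc_del_start + 2L), "mapping")
})

test_that("AHR products partition reference positions between the two
           recombinants", {
  seg <- toy_segment()
  spec_a <- allele_spec("a", list(edit_op("deletion", 1200, 1249)))
  spec_b <- allele_spec("b", list(edit_op("deletion", 3300, 3349)))
  ha <- build_haplotype(seg, spec_a)
  hb <- build_haplotype(seg, spec_b)
  for (bp in c(1500L, 2500L, 3000L)) {
    ab <- ahr_product(ha, hb, bp)
    ba <- ahr_product(hb, ha, bp)
    covered <- function(h) {
      cm <- h$coord_map[!h$coord_map$inserted, ]
      unlist(Map(seq.int, cm$ref_start, cm$ref_end))
    }
    both <- c(covered(ab), covered(ba))
    # outside the two deletion spans, every position occurs exactly twice
    outside <- setdiff(seg$start:seg$end, c(1200:1249, 3300:3349))
    tab <- table(both[both %in% outside])
    expect_true(all(tab == 2L), label = paste("breakpoint", bp))
  }
})

test_that("variant_distance reports proximal distances, rounding and
           containment", {
  pc <- polled_allele("P_C")
  pf <- polled_allele("P_F")
  pm <- polled_allele("P_M")
  expect_identical(as.integer(variant_distance(pc, pf)), 199790L)
  expect_identical(as.integer(variant_distance(pc, pf, rounding = 10000)),
                   200000L)
  expect_identical(as.integer(variant_distance(pf, pf)), 0L)
  d <- variant_distance(pf, pm)
  expect_identical(as.integer(d), 0L)
  expect_true(attr(d, "containment"))
  expect_error(variant_distance(polled_allele("p"), pf), "span")
})

test_that("HGVS-style formatting round-trips the printed notation", {
  pf <- polled_allele("P_F")
  expect_identical(format_hgvs(pf$edits[[1]]), "g.2629116_2709243dup")
  pg <- polled_allele("P_G")
  expect_identical(format_hgvs(pg$edits[[1]]), "g.2614828_2724315dup")
})
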