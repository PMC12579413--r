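# ---------------------------------------------------------------------------
# End-to-end pipeline: simulate a trio scenario, detect structural and
# genotypic evidence in the offspring, and classify it.
# ---------------------------------------------------------------------------

#' Gather an offspring evidence bundle from alignments and a SNP panel
#'
#' Runs the split-read scan, the depth scan, the diagnostic-site read
#' counting, the trio Mendelian check and the haplotype-switch analysis,
#' and assembles the result into an \code{\link{evidence_bundle}}.
#'
#' @param aln offspring \code{alignments}.
#' @param region \code{c(start, end)} scanned reference span.
#' @param panel an \code{snp_panel} (or NULL to skip the switch analysis).
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{bundle} (an \code{evidence_bundle}),
#'   \code{mendelian} (a \code{mendelian_report} or NULL) and
#'   \code{track} (the \code{depth_track}).
#' @export
gather_evidence <- function(aln, region, panel = NULL,
                            config = pipeline_config()) {
  clusters <- scan_splitreads(aln, min_mapq = config$min_mapq,
                              min_anchor = config$min_anchor,
                              join_tol = config$join_tol,
                              tol_bp = config$tol_bp,
                              min_support = config$min_support)
  # the duplication unit (plus margin) is where copy number is expected to
  # differ between POLLED alleles; keep it out of the baseline estimate
  L <- polled_locus()
  track <- compute_depth(aln, region, window = config$window,
                         step = config$step,
                         baseline_exclude = c(L$pf_unit_start - 10000L,
                                              L$pf_unit_end + 10000L))
  cnv <- call_regions(track, min_length = config$min_length,
                      gain_thr = config$gain_thr,
                      loss_thr = config$loss_thr, alpha = config$alpha,
                      merge_gap = config$merge_gap)
  pc <- count_diagnostic_reads(aln, "P_C_site", min_mapq = config$min_mapq)
  pf2d <- count_diagnostic_reads(aln, "P_F2D_site",
                                 min_mapq = config$min_mapq)
  switches <- list()
  mendel <- NULL
  if (!is.null(panel)) {
    mendel <- mendelian_consistency(panel$genotypes)
    origin <- assign_parental_origin(panel$genotypes)
    haps <- panel$truth_haps
    pos <- panel$genotypes$pos
    switches$sire <- detect_switches(
      origin, data.frame(pos = pos, hap1 = haps[, "sire1"],
                         hap2 = haps[, "sire2"]), "sire",
      min_run = config$min_run)
    switches$dam <- detect_switches(
      origin, data.frame(pos = pos, hap1 = haps[, "dam1"],
                         hap2 = haps[, "dam2"]), "dam",
      min_run = config$min_run)
  }
  list(bundle = evidence_bundle(clusters, cnv, pc, pf2d, switches,
                                min_depth = config$min_depth,
                                track = track),
       mendelian = mendel, track = track)
}

#' Pipeline configuration
#'
#' Collects the tunable thresholds of the detection stages with their
#' defaults: split-read junction jitter \code{tol_bp} 20 bp, minimum
#' cluster support 2 reads, minimum mapping quality 10, minimum segment
#' anchor 100 bp, alignment-join dead zone 50 bp, depth windows 200/100 bp,
#' CNV ratio thresholds 1.4/0.6 with minimum span 1 kbp and Poisson filter
#' level 0.001, switch-run absorption 2 markers, diagnostic zygosity depth
#' gate 10 reads, SNP panel density 1 marker / 5 kb.
#'
#' @param ... named overrides of the defaults listed above.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(tol_bp = 20L, min_support = 2L, min_mapq = 10L,
              min_anchor = 100L, join_tol = 50L, window = 200L,
              step = 100L, gain_thr = 1.4, loss_thr = 0.6,
              min_length = 1000L, alpha = 0.01, merge_gap = 10000L,
              min_run = 2L, min_depth = 10L, panel_spacing = 5000L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("pipeline_config: unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full trio analysis on a simulated scenario
#'
#' Simulates the scenario (reference, trio, offspring long reads with
#' projected alignments, SNP panel), gathers the offspring evidence and
#' classifies it with the decision rules of the matching trio family.
#' Reads are simulated for the offspring — the parental genotypes enter
#' the classification as established facts of the design, mirroring the
#' study where the parents' genotypes were known from diagnostics before
#' the offspring was investigated.
#'
#' @param scenario a scenario label accepted by \code{\link{design_trio}}.
#' @param seed integer seed driving every random stage.
#' @param coverage target offspring coverage (fold; default 20).
#' @param params scenario parameters passed to \code{\link{design_trio}}.
#' @param read_params optional \code{read_sim_params} overriding
#'   \code{coverage}.
#' @param config a \code{\link{pipeline_config}}.
#' @param ref_length simulated reference length (bp).
#' @param outdir optional directory; when given, FASTA/FASTQ/SAM/TSV/BED/
#'   VCF outputs and a verdict report are written there.
#' @return An object of class \code{polled_verdict}.
#' @export
run_polled_pipeline <- function(scenario, seed, coverage = 20,
                                params = list(), read_params = NULL,
                                config = pipeline_config(),
                                ref_length = 390000L, outdir = NULL) {
  segment <- polled_reference(seed, length = ref_length)
  design <- design_trio(scenario, segment, params)
  rp <- read_params %||% read_sim_params(coverage = coverage)
  reads <- simulate_reads(design$offspring, rp, seed + 1L)
  aln <- project_alignments(reads, design$offspring,
                            join_tol = config$join_tol)
  panel <- simulate_snp_panel(
    design, seed + 2L,
    n_markers = max(10L, round((segment$end - segment$start + 1) /
                                 config$panel_spacing)))
  L <- polled_locus()
  region <- c(max(segment$start, L$locus_start),
              min(segment$end, L$locus_end))
  ev <- gather_evidence(aln, region, panel, config)
  call <- if (startsWith(scenario, "FV"))
    classify_fv(ev$bundle, dam_trans = TRUE)
  else classify_hf(ev$bundle)
  verdict <- structure(list(
    scenario = scenario, seed = seed, config = config,
    n_reads = nrow(reads), coverage = rp$coverage,
    design = design, evidence = ev$bundle, track = ev$track,
    mendelian = ev$mendelian, call = call,
    expected_label = design$expected_label), class = "polled_verdict")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(segment, file.path(outdir, "reference.fasta"))
    write_fastq(reads, file.path(outdir, "offspring.fastq"))
    write_sam(aln, segment, file.path(outdir, "offspring.sam"))
    write_genotypes(panel, file.path(outdir, "trio_genotypes.tsv"))
    write.table(panel$truth_transmitted,
                file.path(outdir, "truth_transmitted.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_clusters(ev$bundle$split_clusters,
                   file.path(outdir, "split_clusters.tsv"))
    write_sv_vcf(ev$bundle$split_clusters, segment,
                 file.path(outdir, "sv_calls.vcf"))
    write_bed(ev$bundle$cnv_calls, segment, file.path(outdir, "cnv.bed"))
    write_bedgraph(ev$track, segment, file.path(outdir, "depth.bedgraph"))
    writeLines(utils::capture.output(print(verdict)),
               file.path(outdir, "verdict.txt"))
  }
  verdict
}

#' @export
print.polled_verdict <- function(x, ...) {
  cat(sprintf("POLLED locus trio analysis — scenario %s (seed %d)\n",
              x$scenario, x$seed))
  cat(sprintf("  offspring reads: %d (~%.1fx)\n", x$n_reads, x$coverage))
  if (!is.null(x$mendelian))
    cat(sprintf("  parentage: %s (%d/%d markers in conflict)\n",
                x$mendelian$verdict, x$mendelian$conflicts,
                x$mendelian$n_testable))
  b <- x$evidence
  cat(sprintf("  split clusters (support >= 2): %d\n",
              nrow(b$split_clusters)))
  cat(sprintf("  CNV calls (>= 1 kbp, significant): %d\n",
              nrow(b$cnv_calls)))
  pr_call <- function(cl) if (cl$no_call) sprintf("no call (%s)", cl$reason)
    else sprintf("%s (conf %.2f)", cl$genotype, cl$confidence)
  cat(sprintf("  P_C diagnostic: %s [%d ref / %d var]\n", pr_call(b$pc_call),
              b$pc_counts$ref_supporting, b$pc_counts$variant_supporting))
  cat(sprintf("  P_F2D diagnostic: %s [%d ref / %d var]\n",
              pr_call(b$pf_call), b$pf2d_counts$ref_supporting,
              b$pf2d_counts$variant_supporting))
  for (p in names(b$switches)) {
    sw <- b$switches[[p]]
    if (!is.null(sw) && nrow(sw))
      cat(sprintf("  %s haplotype switch at ~%.0f (interval %d-%d)\n", p,
                  sw$point_estimate[1], sw$interval_start[1],
                  sw$interval_end[1]))
  }
  cat("verdict:\n")
  print(x$call)
  if (!is.na(x$expected_label))
    cat(sprintf("(designed truth: %s)\n", x$expected_label))
  invisible(x)
}
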