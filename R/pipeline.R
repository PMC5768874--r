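# End-to-end workflow plumbing: demo fixture bundles and the
# panel -> simulate -> qc -> call -> bench -> cna pipeline with a
# machine-readable summary.

#' Default end-to-end run configuration
#'
#' @param seed Master seed; every stochastic stage receives a seed derived
#'   from it.
#' @param n_genes,roi_per_gene,roi_len Synthetic reference layout.
#' @param intergenic_len Spacer between gene loci (bp).
#' @param n_pairs Read pairs per simulated sample.
#' @param vafs Somatic variant allele fractions simulated in the tumor.
#' @param n_variants Number of somatic variants.
#' @param cna_ratios Named copy ratios applied to tumor genes (the demo
#'   spikes mirror amplified ratios 4.90, 2.25 and 1.32).
#' @param deamination_rate,repair FFPE model for the tumor sample.
#' @param mispriming_rate,duplicate_rate Capture model nuisance rates.
#' @param tau_alpha Thompson-Tau significance for the CNA stage.
#' @param design Panel design configuration.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_genes = 12L, roi_per_gene = 2L,
                       roi_len = 300L, intergenic_len = 500L,
                       n_pairs = 20000L, vafs = c(0.05, 0.10, 0.15, 0.25, 0.40),
                       n_variants = 20L,
                       cna_ratios = c(GENE001 = 4.90, GENE002 = 2.25,
                                      GENE003 = 1.32),
                       deamination_rate = 0, repair = "excision_on",
                       mispriming_rate = 0.05, duplicate_rate = 0.02,
                       tau_alpha = 0.01, design = design_config()) {
  structure(as.list(environment()), class = "run_config")
}

read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in intersect(names(y), names(cfg))) cfg[[k]] <- y[[k]]
  cfg
}

#' Generate the canned demo fixture bundle
#'
#' Writes a synthetic reference FASTA and ROI BED, a designed probe panel
#' TSV/FASTA, a somatic truth VCF spanning VAFs 5-40%, a copy-ratio spec
#' (4.90 / 2.25 / 1.32), and FFPE repair-on and repair-off read sets with
#' truth files. Deterministic for a fixed seed.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param config A [run_config()].
#' @return Named list of file paths, invisibly.
#' @export
make_demo_fixtures <- function(out_dir, seed = 1L, config = run_config(seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- seed
  ref <- make_reference(config$n_genes, config$roi_per_gene, config$roi_len,
                        seed = derive_seed(seed, "reference"),
                        intergenic_len = config$intergenic_len)
  paths <- list(ref = file.path(out_dir, "reference.fa"),
                rois = file.path(out_dir, "rois.bed"),
                panel = file.path(out_dir, "panel.tsv"),
                panel_fasta = file.path(out_dir, "panel.fa"),
                truth_vcf = file.path(out_dir, "truth.vcf"),
                cna_spec = file.path(out_dir, "cna_spec.tsv"))
  write_genome(ref$genome, paths$ref)
  write_rois(ref$rois, paths$rois)
  des <- design_panel(ref$rois, ref$genome, config$design)
  write_panel(des$panel, paths$panel, fasta = paths$panel_fasta)
  variants <- simulate_variants(ref$genome, ref$rois, config$n_variants,
                                vafs = config$vafs, origin = "somatic",
                                seed = derive_seed(seed, "variants"))
  write_variants_vcf(variants, paths$truth_vcf, "demo_tumor")
  cna <- data.frame(gene = names(config$cna_ratios),
                    copy_ratio = unname(config$cna_ratios),
                    stringsAsFactors = FALSE)
  write.table(cna, paths$cna_spec, sep = "\t", quote = FALSE, row.names = FALSE)
  for (rep_mode in c("excision_on", "off")) {
    sim <- simulate_library(ref$genome, des$panel, ref$rois, variants, cna,
                            ffpe = ffpe_model(deamination_rate = 0.02,
                                              repair = rep_mode),
                            cm = capture_model(),
                            n_pairs = min(config$n_pairs, 5000L),
                            seed = derive_seed(seed, "ffpe"))
    write_sim_outputs(sim, out_dir, paste0("ffpe_repair_", rep_mode))
  }
  invisible(paths)
}

#' Run the full workflow end to end
#'
#' panel design, tumor/control library simulation, QC, somatic calling,
#' benchmarking against the simulated truth, and copy-number calling, in
#' order, writing all intermediate files plus a machine-readable
#' `summary.json`. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [run_config()], or a YAML path.
#' @param out_dir Output directory.
#' @param panel_path Optional pre-built panel TSV (skips the design stage).
#' @return The summary list, invisibly.
#' @export
run_end_to_end <- function(config = run_config(), out_dir, panel_path = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  seed <- config$seed
  summary <- list(seed = seed)

  ref <- stage("reference", {
    r <- make_reference(config$n_genes, config$roi_per_gene, config$roi_len,
                        seed = derive_seed(seed, "reference"),
                        intergenic_len = config$intergenic_len)
    write_genome(r$genome, file.path(out_dir, "reference.fa"))
    write_rois(r$rois, file.path(out_dir, "rois.bed"))
    r
  })
  panel <- stage("panel", {
    if (!is.null(panel_path)) {
      if (!file.exists(panel_path)) stopf("panel file not found: %s", panel_path)
      read_panel(panel_path)
    } else {
      des <- design_panel(ref$rois, ref$genome, config$design)
      write_panel(des$panel, file.path(out_dir, "panel.tsv"))
      if (!nrow(des$panel)) stopf("panel design selected no probes")
      summary$panel <- list(n_probes = nrow(des$panel), n_gaps = nrow(des$gaps))
      des$panel
    }
  })
  sims <- stage("simulate", {
    variants <- simulate_variants(ref$genome, ref$rois, config$n_variants,
                                  vafs = config$vafs, origin = "somatic",
                                  seed = derive_seed(seed, "variants"))
    cna <- data.frame(gene = names(config$cna_ratios),
                      copy_ratio = unname(config$cna_ratios),
                      stringsAsFactors = FALSE)
    cmod <- capture_model(mispriming_rate = config$mispriming_rate,
                          duplicate_rate = config$duplicate_rate)
    tumor <- simulate_library(ref$genome, panel, ref$rois, variants, cna,
                              ffpe = ffpe_model(config$deamination_rate,
                                                config$repair),
                              cm = cmod, n_pairs = config$n_pairs,
                              seed = derive_seed(seed, "tumor"))
    control <- simulate_library(ref$genome, panel, ref$rois, NULL, NULL,
                                cm = cmod, n_pairs = config$n_pairs,
                                seed = derive_seed(seed, "control"))
    write_sim_outputs(tumor, out_dir, "tumor")
    write_sim_outputs(control, out_dir, "control")
    write_variants_vcf(variants, file.path(out_dir, "truth.vcf"), "tumor")
    list(tumor = tumor, control = control, variants = variants, cna = cna)
  })
  qc <- stage("qc", {
    out <- lapply(list(tumor = sims$tumor, control = sims$control), function(s)
      qc_report(s$pairs, panel, ref$rois))
    write_qc_report(out$tumor, file.path(out_dir, "tumor_qc.json"))
    write_qc_report(out$control, file.path(out_dir, "control_qc.json"))
    summary$qc <- lapply(out, function(r)
      list(pct_on_target = round(r$pct_on_target, 4),
           mean_coverage = round(r$mean_on_target_coverage, 2),
           fold80 = round(r$fold80, 4),
           mean_insert = round(r$insert$mean, 2),
           duplicate_rate = round(r$duplicate_rate, 4)))
    out
  })
  calls <- stage("call", {
    tp <- pileup_sites(sims$tumor, sims$variants)
    np <- pileup_sites(sims$control, sims$variants)
    sc <- call_somatic(tp, np)
    fl <- filter_somatic_report(sc, min_depth = 40L, min_alt_reads = 2L)
    kept <- fl$kept[fl$kept$status == "somatic", , drop = FALSE]
    if (nrow(kept)) {
      out_v <- kept[, c("chrom", "pos", "ref", "alt")]
      out_v$vaf <- kept$vaf; out_v$origin <- "somatic"
      write_variants_vcf(out_v, file.path(out_dir, "calls.vcf"), "tumor")
    }
    summary$call <- list(n_candidate = nrow(sc), n_reported = nrow(kept))
    kept
  })
  bench <- stage("bench", {
    test <- if (nrow(calls)) calls[, c("chrom", "pos", "ref", "alt")] else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE)
    cmp <- compare_callsets(test, sims$variants, ref$rois, ref$genome)
    tn_universe <- sum(ref$rois$end - ref$rois$start + 2L * ref$rois$flank)
    acc <- accuracy_metrics(cmp, tn_universe)
    jsonlite::write_json(acc, file.path(out_dir, "benchmark.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$bench <- acc[c("tp", "fn", "fp", "sensitivity", "specificity", "ppv")]
    acc
  })
  cna_res <- stage("cna", {
    roi_depth <- function(s) {
      cov <- coverage_track(classify_on_target(s$pairs, panel, ref$rois),
                            ref$rois)
      tapply(cov, names(cov), mean)[ref$rois$roi_id]
    }
    td <- roi_depth(sims$tumor); cd <- roi_depth(sims$control)
    res <- call_cnas(td, cd, ref$rois$gene, tau_config(alpha = config$tau_alpha))
    write_cna_calls(res, file.path(out_dir, "cna_calls.tsv"),
                    file.path(out_dir, "cna_trace.tsv"))
    flg <- res$calls[res$calls$flagged, , drop = FALSE]
    summary$cna <- list(n_flagged = nrow(flg),
                         flagged_genes = flg$gene,
                         ratios = round(flg$ratio, 3))
    res
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
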