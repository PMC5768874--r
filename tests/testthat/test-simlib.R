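test_that("synthetic reference generation is seed-deterministic", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  r1 <- make_reference(130, 2, 300, seed = 7)
  r2 <- make_reference(130, 2, 300, seed = 7)
  write_genome(r1$genome, f1); write_genome(r2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(as.character(r1$genome),
                         as.character(make_reference(130, 2, 300, seed = 8)$genome)))
  # single gene -> single-record FASTA, one-gene BED
  r3 <- make_reference(1, 1, 200, seed = 1)
  expect_equal(length(r3$genome), 1L)
  expect_equal(unique(r3$rois$gene), "GENE001")
  expect_error(make_reference(1, 1, 0), "> 0")
  # GC close to the configured fraction
  gc <- gc_fraction(as.character(r1$genome[[1]]))
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("clean simulation reproduces the reference exactly", {
  w <- fix_grid_world()
  sim <- simulate_library(w$ref$genome, w$panel, w$ref$rois, n_pairs = 300,
                          seq_error = 0, seed = 3)
  g <- w$ref$genome
  for (i in seq_len(nrow(sim$pairs))) {
    p <- sim$pairs[i, ]
    mol <- as.character(Biostrings::subseq(g[[p$chrom]], p$m_start + 1L, p$m_end))
    r2_expect <- if (p$template == "+") substr(mol, 1L, nchar(p$r2_seq))
    else substr(revcomp(mol), 1L, nchar(p$r2_seq))
    expect_identical(p$r2_seq, r2_expect)
  }
})

test_that("read pairs begin with their probe and satisfy the insert truth", {
  w <- fix_grid_world()
  sim <- simulate_library(w$ref$genome, w$panel, w$ref$rois, n_pairs = 2000,
                          seq_error = 0, seed = 11)
  p <- sim$pairs
  plen <- w$panel$end[match(p$probe_id, w$panel$id)] -
    w$panel$start[match(p$probe_id, w$panel$id)]
  expect_true(all(substr(p$r1_seq, 1L, plen) ==
                    w$panel$sequence[match(p$probe_id, w$panel$id)]))
  # insert truth: anchor and ligated end reproduce the stored insert
  expect_true(all(p$insert == abs(p$anchor - p$lig_end)))
  # FASTQ pair counts equal truth-record count
  d <- tempfile(); paths <- write_sim_outputs(sim, d)
  expect_equal(nrow(read_fastq(paths[["r1"]])), nrow(p))
  expect_equal(nrow(read_fastq(paths[["r2"]])), nrow(p))
  sam <- readLines(paths[["sam"]])
  expect_equal(sum(!startsWith(sam, "@")), 2L * nrow(p))
})

test_that("capture model yields ~100 nt mean insert bounded by ~600", {
  ref <- make_reference(1, 1, 30000, seed = 5)
  panel <- panel_from_grid(ref$rois, ref$genome, 100, 25)
  sim <- simulate_library(ref$genome, panel, ref$rois, n_pairs = 15000, seed = 6)
  expect_lt(abs(mean(sim$pairs$insert) - 100), 10)
  expect_lte(max(sim$pairs$insert), 600)
})

test_that("variant allele fractions are recovered binomially", {
  w <- fix_grid_world()
  vars <- simulate_variants(w$ref$genome, w$ref$rois, 6,
                            vafs = c(0.05, 0.25, 0.5), seed = 31)
  sim <- simulate_library(w$ref$genome, w$panel, w$ref$rois, vars,
                          n_pairs = 30000, seed = 32)
  pu <- pileup_sites(sim, vars)
  expect_true(all(pu$depth >= 500))
  for (i in seq_len(nrow(pu))) {
    ci <- qbinom(c(0.005, 0.995), pu$depth[i], vars$vaf[i])
    expect_gte(pu$alt_count[i], ci[1])
    expect_lte(pu$alt_count[i], ci[2])
  }
  # vaf = 0 is disallowed; all-reference simulation has no alt calls
  expect_error(simulate_library(w$ref$genome, w$panel, w$ref$rois,
                                transform(vars, vaf = 0), seed = 1),
               "vaf")
})

test_that("FFPE damage model follows the repair mode", {
  w <- fix_grid_world()
  # repair off, rate 1: every template C in the extension reads as T
  sim_off <- simulate_library(w$ref$genome, w$panel, w$ref$rois,
                              ffpe = ffpe_model(1, "off"), n_pairs = 400,
                              seq_error = 0, seed = 7)
  p <- sim_off$pairs[sim_off$pairs$template == "+", ]
  ext <- substr(p$r2_seq, 1L, pmax(1L, pmin(nchar(p$r2_seq), p$insert)))
  expect_equal(sum(nchar(gsub("[^C]", "", ext))), 0L)
  # excision repair: no transition bases are emitted at all
  sim_on <- simulate_library(w$ref$genome, w$panel, w$ref$rois,
                             ffpe = ffpe_model(0.05, "excision_on"),
                             n_pairs = 1500, seq_error = 0, seed = 7)
  expect_equal(sum(mismatch_spectrum(sim_on)$count), 0L)
  # and damaged molecules shrink: inserts shorter on average than repair-off
  sim_off2 <- simulate_library(w$ref$genome, w$panel, w$ref$rois,
                               ffpe = ffpe_model(0.05, "off"),
                               n_pairs = 1500, seq_error = 0, seed = 7)
  expect_lt(mean(sim_on$pairs$insert), mean(sim_off2$pairs$insert))
  # probe off the reference is rejected by name
  bad_panel <- w$panel
  bad_panel$end[3] <- 10^7; bad_panel$start[3] <- 10^7 - 25L
  expect_error(simulate_library(w$ref$genome, bad_panel, w$ref$rois),
               bad_panel$id[3])
})

test_that("ROI coverage simulation scales depth by copy ratio", {
  # Poisson limit: sample mean within 3 SE of the configured mean
  cv <- simulate_roi_coverage(100, 2, mean_depth = 1000, dispersion = Inf,
                              seed = 1, n_samples = 1, roi_bias_sd = 0)
  se <- sqrt(1000 / length(cv$depth))
  expect_lt(abs(mean(cv$depth) - 1000), 3 * se)
  # a 4.90x gene scales its ROI mean accordingly
  cna <- data.frame(gene = "GENE001", copy_ratio = 4.90)
  cv2 <- simulate_roi_coverage(100, 4, mean_depth = 800, dispersion = 50,
                               cnas = cna, seed = 2, n_samples = 2,
                               control_cols = 1, roi_bias_sd = 0)
  amp <- cv2$rois$gene == "GENE001"
  ratio <- mean(cv2$depth[amp, 2]) / mean(cv2$depth[!amp, 2])
  expect_lt(abs(ratio - 4.90) / 4.90, 0.15)
  # control column untouched
  ratio_ctl <- mean(cv2$depth[amp, 1]) / mean(cv2$depth[!amp, 1])
  expect_lt(abs(ratio_ctl - 1), 0.15)
  # different seeds differ
  expect_false(identical(simulate_roi_coverage(10, 2, 100, 10, seed = 1)$depth,
                         simulate_roi_coverage(10, 2, 100, 10, seed = 2)$depth))
})

test_that("gene-ratio generator spikes the requested genes", {
  gr <- simulate_gene_ratios(130, 0.05, seed = 9)
  expect_equal(sum(gr$spiked), 3L)
  expect_equal(gr$log2_ratio[1] - 2.29, unname(
    simulate_gene_ratios(130, 0.05, spikes = c(GENE001 = 0), seed = 9)$log2_ratio[1]))
  expect_identical(gr, simulate_gene_ratios(130, 0.05, seed = 9))
})
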