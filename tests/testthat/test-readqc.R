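test_that("quality masking respects the strict Phred floor", {
  q30 <- strrep("?", 10) # Phred 30
  seqs <- strrep("A", 10)
  expect_identical(quality_mask(seqs, q30, 28L), seqs)
  # one base at Q27 (ASCII 33+27 = '<') is masked; Q28 ('=') is retained
  q <- paste0(strrep("?", 4), "<", strrep("?", 5))
  expect_identical(quality_mask("ACGTACGTAC", q, 28L), "ACGTNCGTAC")
  q28 <- paste0(strrep("?", 4), "=", strrep("?", 5))
  expect_identical(quality_mask("ACGTACGTAC", q28, 28L), "ACGTACGTAC")
  expect_error(quality_mask("ACGT", "???"), "differ in length")
  # file interface preserves read count
  w <- fix_grid_world()
  sim <- simulate_library(w$ref$genome, w$panel, w$ref$rois, n_pairs = 50,
                          seed = 1)
  d <- tempfile(); paths <- write_sim_outputs(sim, d)
  out <- tempfile(fileext = ".fastq")
  quality_mask_fastq(paths[["r1"]], out, 28L)
  expect_equal(nrow(read_fastq(out)), nrow(sim$pairs))
})

test_that("probe tagging matches R1 prefixes exactly and reports ties", {
  panel <- data.frame(id = c("P1", "P2", "P3"),
                      chrom = "chr1", start = c(0L, 30L, 60L),
                      end = c(20L, 50L, 80L), strand = "+",
                      anchor = c(19L, 49L, 79L),
                      sequence = c("ACGTACGTACGTACGTACGT",
                                   "GGGGCCCCAAAATTTTGGCC",
                                   "ACGTACGTACGTACGTACGT"),
                      roi_id = "roi0001", stringsAsFactors = FALSE)
  reads <- c(paste0("GGGGCCCCAAAATTTTGGCC", "AAAA"), # P2
             strrep("T", 30),                        # none
             paste0("ACGTACGTACGTACGTACGT", "TT"))   # P1/P3 tie
  tags <- probe_tag(reads, panel)
  expect_identical(tags, c("P2", NA, "ambiguous"))
  expect_error(probe_tag(reads, panel[0, ]), "empty")
  # one mismatch is recovered under a mismatch budget
  mm <- paste0("GGGGCCCCAAAATTTTGGCA", "AAAA")
  expect_identical(probe_tag(mm, panel, max_mismatch = 1L), "P2")
  expect_identical(probe_tag(mm, panel, max_mismatch = 0L), NA_character_)
})

test_that("on-target classification applies the four criteria in order", {
  rois <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                     gene = "G", flank = 50L, roi_id = "roi0001")
  panel <- data.frame(id = "P1", chrom = "chr1", start = 1200L, end = 1225L,
                      strand = "+", anchor = 1224L,
                      sequence = strrep("A", 25), roi_id = "roi0001",
                      stringsAsFactors = FALSE)
  base <- data.frame(probe_id = "P1", chrom = "chr1",
                     r1_start = 1200L, r1_end = 1350L, r1_strand = "+",
                     r2_start = 1250L, r2_end = 1345L, r2_strand = "-",
                     stringsAsFactors = FALSE)
  ok <- classify_on_target(base, panel, rois)
  expect_true(ok$on_target)
  expect_equal(ok$insert, 1350L - 1200L - 25L)

  # same pair but 1.6 kb insert -> off ("insert>1.5kb")
  big <- base; big$r2_end <- big$r1_start + 1625L + 25L
  off1 <- classify_on_target(big, panel, rois)
  expect_false(off1$on_target); expect_equal(off1$reason, "insert>1.5kb")

  # opposite orientation -> off ("orientation")
  flip <- base; flip$r1_strand <- "-"; flip$r2_strand <- "+"
  off2 <- classify_on_target(flip, panel, rois)
  expect_false(off2$on_target); expect_equal(off2$reason, "orientation")

  # outside the probe's ROI -> off; no probe -> off
  away <- base
  away$r1_start <- 9000L; away$r1_end <- 9150L
  away$r2_start <- 9050L; away$r2_end <- 9145L
  expect_equal(classify_on_target(away, panel, rois)$reason, "outside_roi")
  untag <- base; untag$probe_id <- NA_character_
  expect_equal(classify_on_target(untag, panel, rois)$reason, "no_probe")
})

test_that("duplicate marking groups by probe and fragment end", {
  mk <- function(n, r2s = 1250L, r2e = 1400L) data.frame(
    probe_id = "P1", r1_strand = "+", r1_start = 1200L, r1_end = 1350L,
    r2_start = rep(r2s, n), r2_end = rep(r2e, n),
    r1_qual = strrep("?", 10), r2_qual = strrep("?", 10),
    stringsAsFactors = FALSE)
  two <- mark_duplicates(mk(2))
  expect_equal(sum(two$duplicate), 1L)
  shifted <- mark_duplicates(rbind(mk(1), mk(1, r2e = 1401L)))
  expect_equal(sum(shifted$duplicate), 0L)
  three <- mark_duplicates(mk(3))
  expect_equal(sum(three$duplicate), 2L)
  # highest summed base quality retained
  hq <- mk(2)
  hq$r1_qual[2] <- strrep("I", 10) # Q40
  marked <- mark_duplicates(hq)
  expect_true(marked$duplicate[1])
  expect_false(marked$duplicate[2])
})

test_that("fold 80 base penalty matches its definition and oracle", {
  expect_equal(fold80(rep(137, 1000)), 1)
  expect_equal(fold80(c(rep(50, 8), rep(100, 2))), 1.2)
  expect_error(fold80(rep(0, 10)), "all-zero")
  set.seed(13)
  for (i in 1:50) {
    cov <- rpois(sample(20:400, 1), sample(c(3, 40, 300), 1))
    if (!any(cov > 0)) next
    expect_equal(fold80(cov), oracle_fold80(cov))
  }
})

test_that("coverage threshold fractions are monotone and exact", {
  expect_equal(unname(coverage_fractions(rep(150, 10), 100L)), 1.0)
  expect_equal(unname(coverage_fractions(rep(1, 10), 2L)), 0.0)
  expect_equal(unname(coverage_fractions(c(0, 10, 200, 200), 100L)), 0.5)
  fr <- coverage_fractions(rpois(500, 60), c(2L, 10L, 50L, 100L))
  expect_true(all(diff(fr) <= 0))
})

test_that("insert statistics summarize proper pairs", {
  one <- data.frame(r1_strand = "+", r2_strand = "-", insert = 100L)
  st <- insert_stats(one)
  expect_equal(st$mean, 100); expect_equal(st$n, 1L)
  none <- data.frame(r1_strand = "+", r2_strand = "+", insert = 100L)
  expect_equal(insert_stats(none)$n, 0L)
  # simulator defaults give ~100 nt
  ref <- make_reference(1, 1, 30000, seed = 5)
  panel <- panel_from_grid(ref$rois, ref$genome, 100, 25)
  sim <- simulate_library(ref$genome, panel, ref$rois, n_pairs = 8000, seed = 6)
  cl <- classify_on_target(sim$pairs, panel, ref$rois)
  st2 <- insert_stats(cl)
  expect_lt(abs(st2$mean - 100), 12)
})

test_that("paired subsampling keeps both mates or neither, deterministically", {
  w <- fix_grid_world()
  sim <- simulate_library(w$ref$genome, w$panel, w$ref$rois, n_pairs = 10000,
                          seed = 17)
  expect_identical(subsample_pairs(sim, 1, seed = 1)$pairs, sim$pairs)
  expect_equal(nrow(subsample_pairs(sim, 0, seed = 1)$pairs), 0L)
  half <- subsample_pairs(sim, 0.5, seed = 2)
  ci <- qbinom(c(0.005, 0.995), nrow(sim$pairs), 0.5)
  expect_gte(nrow(half$pairs), ci[1]); expect_lte(nrow(half$pairs), ci[2])
  expect_identical(half$pairs, subsample_pairs(sim, 0.5, seed = 2)$pairs)
  # file interface: mates stay synchronized
  d <- tempfile(); paths <- write_sim_outputs(sim, d)
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  subsample_pairs(paths[["r1"]], 0.3, seed = 3, r2_path = paths[["r2"]],
                  out_r1 = o1, out_r2 = o2)
  k1 <- read_fastq(o1); k2 <- read_fastq(o2)
  expect_equal(nrow(k1), nrow(k2))
  expect_identical(sub("/1$", "", k1$id), sub("/2$", "", k2$id))
  # desynchronized mate files are rejected
  expect_error(subsample_pairs(o1, 0.5, seed = 1, r2_path = paths[["r2"]],
                               out_r1 = tempfile(), out_r2 = tempfile()),
               "desynchronized")
})

test_that("on-target fraction agrees exactly with simulator truth", {
  ref <- make_reference(10, 2, 300, seed = 42, intergenic_len = 2000)
  panel <- design_panel(ref$rois, ref$genome)$panel
  sim <- simulate_library(ref$genome, panel, ref$rois, n_pairs = 4000,
                          seed = 9, seq_error = 0,
                          cm = capture_model(mispriming_rate = 0.07,
                                             duplicate_rate = 0.03))
  pairs <- sim$pairs
  pairs$probe_id <- probe_tag(pairs$r1_seq, panel)
  cl <- classify_on_target(pairs, panel, ref$rois)
  expect_identical(cl$on_target, sim$pairs$on_target)
  rep <- qc_report(sim$pairs, panel, ref$rois)
  expect_equal(rep$pct_on_target, mean(sim$pairs$on_target))
  expect_true(rep$fold80 >= 1)
  expect_true(all(unlist(rep$coverage_fractions) >= 0 &
                    unlist(rep$coverage_fractions) <= 1))
  out <- tempfile(fileext = ".json")
  write_qc_report(rep, out)
  expect_true(jsonlite::validate(paste(readLines(out), collapse = "")))
})
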