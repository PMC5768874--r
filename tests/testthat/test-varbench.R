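test_that("germline genotyper recovers the obvious genotypes", {
  pu <- data.frame(depth = c(1000L, 1000L, 1000L, 0L),
                   alt_count = c(0L, 500L, 1000L, 0L))
  gt <- call_germline(pu, error_rate = 1e-3, germline_prior = 1e-3)
  expect_equal(gt$genotype, c("0/0", "0/1", "1/1", "./."))
  expect_true(all(gt$posterior[1:3] > 0.99))
  # 30 alt of 1000 at error 1e-3: no germline genotype explains the data
  # well (direct posterior computation shows hom-ref is the argmax but with
  # an extreme likelihood penalty versus a free allele-fraction model)
  odd <- call_germline(data.frame(depth = 1000L, alt_count = 30L))
  lik_best_gt <- dbinom(30, 1000, switch(odd$genotype, `0/0` = 1e-3,
                                         `0/1` = 0.5, `1/1` = 1 - 1e-3))
  lik_free <- dbinom(30, 1000, 30 / 1000)
  expect_lt(lik_best_gt / lik_free, 1e-6) # candidate somatic, not germline
  expect_error(call_germline(pu, germline_prior = 0), "priors")
})

test_that("tumor/normal network separates somatic from germline", {
  # alt absent in a deep normal, 25% in tumor -> somatic even at prior 1e-6
  tum <- data.frame(depth = 1000L, alt_count = 250L)
  nor <- data.frame(depth = 1000L, alt_count = 1L)
  som <- call_somatic(tum, nor, somatic_prior = 1e-6)
  expect_equal(som$status, "somatic")
  expect_gt(som$posterior, 0.99)
  # 50% in both tumor and normal -> germline
  both <- call_somatic(data.frame(depth = 1000L, alt_count = 502L),
                       data.frame(depth = 1000L, alt_count = 497L))
  expect_equal(both$status, "germline")
  # tumor-only at a common SNP (germline prior 0.5) at 50% VAF -> germline:
  # the posterior comparison is dominated by the prior ratio because the
  # likelihoods of the het and somatic hypotheses coincide at f = 0.5
  tonly <- call_somatic(data.frame(depth = 1000L, alt_count = 500L),
                        normal = NULL, germline_prior = 0.5,
                        somatic_prior = 1e-6)
  expect_equal(tonly$status, "germline")
  # reference sites stay reference
  refsite <- call_somatic(data.frame(depth = 1000L, alt_count = 1L),
                          data.frame(depth = 1000L, alt_count = 0L))
  expect_equal(refsite$status, "reference")
})

test_that("somatic reporting filter enforces depth and read support", {
  calls <- data.frame(depth = c(39L, 40L, 400L, 100L),
                      alt_count = c(10L, 2L, 120L, 1L))
  fl <- filter_somatic_report(calls, min_depth = 40L, min_alt_reads = 2L)
  expect_equal(nrow(fl$kept), 2L)
  expect_setequal(fl$removed$filter_reason, c("depth<40X", "alt_reads<2"))
  empty <- filter_somatic_report(calls[0, ])
  expect_equal(nrow(empty$kept), 0L)
})

test_that("callset comparison matches alleles after normalization", {
  truth <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  calls <- truth
  rois <- data.frame(chrom = "chr1", start = 0L, end = 1000L, gene = "G",
                     flank = 50L)
  cmp <- compare_callsets(calls, truth, rois)
  expect_equal(c(cmp$tp, cmp$fn, cmp$fp), c(1L, 0L, 0L))
  calls2 <- rbind(calls, data.frame(chrom = "chr1", pos = 200L, ref = "G",
                                    alt = "C"))
  cmp2 <- compare_callsets(calls2, truth, rois)
  expect_equal(c(cmp2$tp, cmp2$fn, cmp2$fp), c(1L, 0L, 1L))

  # representation pair: the same deletion written right-shifted vs
  # left-aligned still matches after normalization against the reference
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("ACGT", 25), "GGTTTTAC", strrep("ACGT", 25))))
  # reference has TTTT at 0-based 102..105; deleting one T is the same
  # variant wherever it is written inside the run
  right <- data.frame(chrom = "chr1", pos = 104L, ref = "TT", alt = "T")
  left <- data.frame(chrom = "chr1", pos = 101L, ref = "GT", alt = "G")
  roisg <- data.frame(chrom = "chr1", start = 0L, end = 208L, gene = "G",
                      flank = 0L)
  cmp3 <- compare_callsets(right, left, roisg, genome)
  expect_equal(c(cmp3$tp, cmp3$fn, cmp3$fp), c(1L, 0L, 0L))
  nr <- normalize_variants(right, genome)
  expect_equal(nr$pos, 101L)
  expect_equal(nr$ref, "GT"); expect_equal(nr$alt, "G")

  # ROI restriction drops calls outside the flanked intervals
  far <- rbind(calls, data.frame(chrom = "chr1", pos = 5000L, ref = "A",
                                 alt = "G"))
  cmp4 <- compare_callsets(far, truth, rois)
  expect_equal(cmp4$fp, 0L)
})

test_that("comparison is symmetric under test/truth swap", {
  set.seed(5)
  mk <- function(n, offset = 0L) data.frame(
    chrom = "chr1", pos = sample(1000L, n) + offset, ref = "A", alt = "T",
    stringsAsFactors = FALSE)
  a <- mk(30); b <- mk(25, offset = 500L)
  ab <- compare_callsets(a, b)
  ba <- compare_callsets(b, a)
  expect_equal(ab$tp, ba$tp)
  expect_equal(ab$fn, ba$fp)
  expect_equal(ab$fp, ba$fn)
})

test_that("accuracy metrics reproduce printed worked examples", {
  # PPV from TP=36, FP=1; sensitivity from TP=35, FN=1
  m1 <- accuracy_metrics(list(tp = 36, fn = 0, fp = 1), 419528)
  expect_equal(m1$ppv, 97.3)
  expect_equal(m1$sensitivity, 100.0)
  m2 <- accuracy_metrics(list(tp = 35, fn = 1, fp = 2), 419528)
  expect_equal(m2$sensitivity, 97.2)
  expect_equal(m2$ppv, 94.6)
  m3 <- accuracy_metrics(list(tp = 36, fn = 0, fp = 6), 419528)
  expect_equal(m3$ppv, 85.7)
  # detected fraction 131/137 -> 0.96
  m4 <- accuracy_metrics(list(tp = 131, fn = 6, fp = 0), 419528)
  expect_equal(m4$detected_fraction, 0.96)
  # TN universe: callable ROI bases minus truth positions
  expect_equal(m4$tn, 419528 - 137)
  # the as-printed specificity formula divides by TN + FN; the
  # conventional one by TN + FP
  m5 <- accuracy_metrics(list(tp = 0, fn = 100, fp = 0), 1100,
                         specificity_formula = "as_printed")
  expect_equal(m5$specificity, round(100 * 1000 / 1100, 1))
  m6 <- accuracy_metrics(list(tp = 0, fn = 100, fp = 10), 1100,
                         specificity_formula = "conventional")
  expect_equal(m6$specificity, round(100 * 1000 / 1010, 1))
  # sensitivity undefined with no truth positives
  expect_true(is.na(accuracy_metrics(list(tp = 0, fn = 0, fp = 5), 100)$sensitivity))
})

test_that("C>T/A>G ratio counts deamination-signature substitutions", {
  all_ct <- data.frame(ref = c("C", "C"), alt = c("T", "T"))
  expect_equal(ct_ag_ratio(all_ct), 100)
  none <- data.frame(ref = c("A", "T"), alt = c("C", "G"))
  expect_equal(ct_ag_ratio(none), 0)
  mixed <- data.frame(ref = c("C", "G", "A", "T"), alt = c("T", "A", "C", "G"))
  expect_equal(ct_ag_ratio(mixed), 50)
  expect_true(is.na(ct_ag_ratio(mixed[0, ])))
  # indels are excluded from the SNV universe
  with_indel <- rbind(mixed, data.frame(ref = "CT", alt = "C"))
  expect_equal(ct_ag_ratio(with_indel), 50)
})

test_that("excision repair lowers the C>T/A>G ratio at equal seeds", {
  w <- fix_grid_world()
  spectra <- lapply(c("off", "excision_on"), function(mode) {
    sim <- simulate_library(w$ref$genome, w$panel, w$ref$rois,
                            ffpe = ffpe_model(0.01, mode), n_pairs = 2500,
                            seq_error = 5e-4, seed = 55)
    mismatch_spectrum(sim, max_pairs = 2500L)
  })
  ratio <- vapply(spectra, function(ms) {
    v <- ms[rep(seq_len(nrow(ms)), ms$count), c("ref", "alt")]
    ct_ag_ratio(v)
  }, 0)
  expect_gt(ratio[1], ratio[2]) # repair off strictly higher
})

test_that("VCF round trip preserves variants", {
  v <- data.frame(chrom = "chr1", pos = c(9L, 99L), ref = c("A", "CT"),
                  alt = c("G", "C"), vaf = c(0.25, 0.05),
                  origin = "somatic", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, f)
  back <- read_variants(f)
  expect_equal(back$pos, v$pos)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$vaf, v$vaf)
})
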