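# Probe-aware read pre-processing, on-target classification, duplicate
# marking, and panel coverage/uniformity/insert metrics.

#' QC configuration
#'
#' @param quality_floor Phred floor: bases with quality strictly below this
#'   are masked to N before alignment/analysis.
#' @param off_target_insert Insert (bp) above which a pair is called
#'   off-target regardless of position (default 1.5 kb).
#' @param coverage_thresholds Coverage thresholds (X) reported as fractions
#'   of ROI bases at or above each value.
#' @param min_recommended_coverage Mean coverage (X) below which variant
#'   sensitivity degrades appreciably; recorded in the report.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(quality_floor = 28L, off_target_insert = 1500L,
                      coverage_thresholds = c(2L, 10L, 20L, 50L, 100L),
                      min_recommended_coverage = 200L) {
  if (quality_floor < 0) stopf("quality_floor must be >= 0")
  if (off_target_insert <= 0) stopf("off_target_insert must be > 0")
  structure(list(quality_floor = as.integer(quality_floor),
                 off_target_insert = as.integer(off_target_insert),
                 coverage_thresholds = sort(as.integer(coverage_thresholds)),
                 min_recommended_coverage = as.integer(min_recommended_coverage)),
            class = "qc_config")
}

#' Mask low-quality bases
#'
#' Replaces bases whose Phred quality is strictly below `floor` with `N`,
#' preserving read length and qualities (masking rather than trimming keeps
#' pair coordinates intact).
#'
#' @param seqs Character vector of read sequences (or a data.frame from
#'   [read_fastq()]).
#' @param quals Character vector of Phred+33 quality strings.
#' @param floor Phred floor (bases `< floor` are masked).
#' @return Character vector of masked sequences (or the data.frame with
#'   `seq` replaced).
#' @export
quality_mask <- function(seqs, quals = NULL, floor = 28L) {
  if (is.data.frame(seqs)) {
    seqs$seq <- quality_mask(seqs$seq, seqs$qual, floor)
    return(seqs)
  }
  if (length(seqs) != length(quals))
    stopf("sequence/quality vectors differ in length")
  if (any(nchar(seqs) != nchar(quals)))
    stopf("sequence and quality strings differ in length at read %d",
          which(nchar(seqs) != nchar(quals))[1L])
  vapply(seq_along(seqs), function(i) {
    q <- utf8ToInt(quals[i]) - 33L
    low <- q < floor
    if (!any(low)) return(seqs[i])
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    b[low] <- "N"
    paste(b, collapse = "")
  }, "")
}

#' Mask low-quality bases in a FASTQ file
#' @param in_path,out_path FASTQ paths.
#' @param floor Phred floor.
#' @return `out_path`, invisibly.
#' @export
quality_mask_fastq <- function(in_path, out_path, floor = 28L) {
  fq <- read_fastq(in_path)
  fq <- quality_mask(fq, floor = floor)
  x <- Biostrings::DNAStringSet(setNames(fq$seq, fq$id))
  Biostrings::writeXStringSet(x, out_path, format = "fastq",
                              qualities = Biostrings::BStringSet(fq$qual),
                              compress = endsWith(out_path, ".gz"))
  invisible(out_path)
}

#' Identify the generating probe of Read 1
#'
#' Matches the R1 prefix against the probe metadata file (probe sequences):
#' OS-Seq Read 1 begins with the synthetic primer-probe that generated it.
#' A prefix matching more than one probe is `"ambiguous"`; no match is `NA`.
#'
#' @param r1_seqs Character vector of Read 1 sequences.
#' @param panel Panel data.frame.
#' @param max_mismatch Mismatch budget when matching the prefix.
#' @return Character vector: probe id, `"ambiguous"`, or `NA`.
#' @export
probe_tag <- function(r1_seqs, panel, max_mismatch = 0L) {
  if (is.null(panel) || nrow(panel) == 0L) stopf("empty probe panel")
  lens <- sort(unique(nchar(panel$sequence)))
  out <- rep(NA_character_, length(r1_seqs))
  nhit <- integer(length(r1_seqs))
  for (L in lens) {
    sub <- panel[nchar(panel$sequence) == L, , drop = FALSE]
    lut <- setNames(sub$id, sub$sequence)
    pre <- substr(r1_seqs, 1L, L)
    hit <- lut[pre]
    ok <- !is.na(hit) & nchar(r1_seqs) >= L
    nhit[ok] <- nhit[ok] + 1L
    out[ok & nhit == 1L] <- hit[ok & nhit == 1L]
    # several probes sharing one sequence can never be told apart
    dupseq <- unique(sub$sequence[duplicated(sub$sequence)])
    if (length(dupseq)) nhit[ok & pre %in% dupseq] <- 2L
  }
  if (max_mismatch > 0L) {
    miss <- which(nhit == 0L)
    if (length(miss)) {
      pdict <- strsplit(panel$sequence, "", fixed = TRUE)
      plen <- nchar(panel$sequence)
      for (i in miss) {
        rb <- strsplit(r1_seqs[i], "", fixed = TRUE)[[1L]]
        mm <- vapply(seq_len(nrow(panel)), function(j) {
          if (length(rb) < plen[j]) return(Inf)
          sum(rb[seq_len(plen[j])] != pdict[[j]])
        }, 0)
        cand <- which(mm <= max_mismatch)
        if (length(cand) == 1L) { out[i] <- panel$id[cand]; nhit[i] <- 1L }
        else if (length(cand) > 1L) nhit[i] <- length(cand)
      }
    }
  }
  out[nhit > 1L] <- "ambiguous"
  out
}

#' Classify pairs as on- or off-target
#'
#' A pair is on-target iff its generating probe was identified, the mate
#' orientation is consistent with the probe strand, the alignment falls
#' within the probe's ROI (enlarged by the ROI flank), and the insert
#' between read and probe does not exceed the off-target limit (1.5 kb by
#' default). The first failed criterion is recorded as the reason.
#'
#' For a tagged pair the insert is the R1-start..R2-end reference span minus
#' the probe length (the captured template between primer and adapter);
#' for untagged pairs it is the raw span.
#'
#' @param pairs data.frame with `probe_id, chrom, r1_start, r1_end,
#'   r1_strand, r2_start, r2_end, r2_strand` (0-based half-open).
#' @param panel Panel data.frame.
#' @param rois ROI data.frame.
#' @param config A [qc_config()].
#' @return `pairs` with `insert`, `on_target` and `reason` columns.
#' @export
classify_on_target <- function(pairs, panel, rois, config = qc_config()) {
  rois <- validate_rois(rois)
  pm <- match(pairs$probe_id, panel$id)
  plen <- ifelse(is.na(pm), 0L, panel$end[pm] - panel$start[pm])
  span_lo <- pmin(pairs$r1_start, pairs$r2_start)
  span_hi <- pmax(pairs$r1_end, pairs$r2_end)
  pairs$insert <- span_hi - span_lo - plen
  reason <- rep(NA_character_, nrow(pairs))

  no_probe <- is.na(pm) | pairs$probe_id %in% "ambiguous"
  reason[no_probe] <- "no_probe"
  # orientation: R1 on the probe strand, R2 opposite
  bad_orient <- !no_probe &
    (pairs$r1_strand != panel$strand[pm] | pairs$r2_strand == pairs$r1_strand)
  reason[bad_orient] <- "orientation"
  # within the probe's ROI (+/- flank)
  ri <- match(panel$roi_id[pm], rois$roi_id)
  lo <- rois$start[ri] - rois$flank[ri]
  hi <- rois$end[ri] + rois$flank[ri]
  same_chrom <- !is.na(ri) & pairs$chrom == rois$chrom[ri]
  in_roi <- same_chrom & span_lo < hi & span_hi > lo
  bad_roi <- !no_probe & !bad_orient & !in_roi
  reason[bad_roi] <- "outside_roi"
  big <- !no_probe & !bad_orient & !bad_roi & pairs$insert > config$off_target_insert
  reason[big] <- "insert>1.5kb"
  pairs$on_target <- is.na(reason)
  pairs$reason <- reason
  pairs
}

#' Mark PCR duplicates
#'
#' Pairs sharing (probe id, R2 fragment-end position, orientation) collapse
#' to a single retained pair; the pair with the highest summed base quality
#' is kept. R1 starts are fixed by the probe in OS-Seq libraries, so a
#' both-end key would over-collapse; the adapter-ligated fragment end is
#' the informative coordinate.
#'
#' @param pairs data.frame with `probe_id, r1_strand, r2_start, r2_end`
#'   and optionally `r1_qual, r2_qual`.
#' @return `pairs` with a logical `duplicate` column.
#' @export
mark_duplicates <- function(pairs) {
  frag_end <- ifelse(pairs$r1_strand == "-", pairs$r2_start, pairs$r2_end)
  key <- paste(pairs$probe_id, frag_end, pairs$r1_strand, sep = "|")
  qualsum <- if (!is.null(pairs$r1_qual))
    vapply(paste0(pairs$r1_qual, pairs$r2_qual),
           function(q) sum(utf8ToInt(q)) - 33L * nchar(q), 0, USE.NAMES = FALSE)
  else rep(0, nrow(pairs))
  ord <- order(key, -qualsum)
  dup <- duplicated(key[ord])
  pairs$duplicate <- FALSE
  pairs$duplicate[ord] <- dup
  pairs
}

#' Per-base coverage over ROI bases
#'
#' Counts aligned read bases (R1 and R2 separately) over each ROI base,
#' from on-target, non-duplicate pairs if those columns are present.
#'
#' @param pairs Classified pair data.frame.
#' @param rois ROI data.frame.
#' @return Integer vector of per-base coverage over the concatenated ROI
#'   bases (named by roi_id).
#' @export
coverage_track <- function(pairs, rois) {
  rois <- validate_rois(rois)
  use <- rep(TRUE, nrow(pairs))
  if ("on_target" %in% names(pairs)) use <- use & pairs$on_target
  if ("duplicate" %in% names(pairs)) use <- use & !pairs$duplicate
  p <- pairs[use, , drop = FALSE]
  out <- integer(0)
  for (r in seq_len(nrow(rois))) {
    n <- rois$end[r] - rois$start[r]
    delta <- integer(n + 1L)
    for (col in list(c("r1_start", "r1_end"), c("r2_start", "r2_end"))) {
      s <- p[[col[1L]]]; e <- p[[col[2L]]]
      sel <- p$chrom == rois$chrom[r] & e > rois$start[r] & s < rois$end[r]
      if (!any(sel)) next
      cs <- pmax(s[sel], rois$start[r]) - rois$start[r]
      ce <- pmin(e[sel], rois$end[r]) - rois$start[r]
      delta_add <- tabulate(cs + 1L, nbins = n + 1L) - tabulate(ce + 1L, nbins = n + 1L)
      delta <- delta + delta_add
    }
    cov <- cumsum(delta)[seq_len(n)]
    names(cov) <- rep(rois$roi_id[r], n)
    out <- c(out, cov)
  }
  out
}

#' Fold 80 base penalty
#'
#' The fold change of non-zero read coverage needed to bring 80% of the ROI
#' bases up to the observed mean coverage: mean of the non-zero per-base
#' coverage divided by its 20th percentile (lower value at rank
#' `ceiling(0.2 n)` over the ascending non-zero values). Perfect uniformity
#' gives 1.
#'
#' @param coverage Per-base coverage vector over ROI bases.
#' @return Dimensionless penalty, >= 1 for any non-degenerate track.
#' @export
fold80 <- function(coverage) {
  nz <- coverage[coverage > 0]
  if (!length(nz)) stopf("fold 80 base penalty undefined: all-zero coverage")
  p20 <- sort(nz)[ceiling(0.2 * length(nz))]
  unname(mean(nz) / p20)
}

#' Fraction of ROI bases at or above coverage thresholds
#' @param coverage Per-base coverage vector.
#' @param thresholds Sorted coverage thresholds (X).
#' @return Named numeric vector of fractions (monotone non-increasing).
#' @export
coverage_fractions <- function(coverage, thresholds = c(2L, 10L, 20L, 50L, 100L)) {
  setNames(vapply(thresholds, function(t) mean(coverage >= t), 0),
           paste0(">=", thresholds, "X"))
}

#' Insert-size statistics over proper pairs
#'
#' @param pairs Classified pair data.frame with an `insert` column; only
#'   proper pairs (both mates on one chromosome, opposite strands) are used.
#' @param binwidth Histogram bin width (bp).
#' @return List with `n`, `mean`, `max` and a `histogram` data.frame; an
#'   empty report (n = 0) if there are no proper pairs.
#' @export
insert_stats <- function(pairs, binwidth = 10L) {
  proper <- rep(TRUE, nrow(pairs))
  if (!is.null(pairs$r1_strand)) proper <- pairs$r1_strand != pairs$r2_strand
  ins <- pairs$insert[proper & !is.na(pairs$insert)]
  if (!length(ins))
    return(list(n = 0L, mean = NA_real_, max = NA_real_,
                histogram = data.frame(bin = numeric(), count = integer())))
  bin <- floor(ins / binwidth) * binwidth
  tab <- table(bin)
  list(n = length(ins), mean = mean(ins), max = max(ins),
       histogram = data.frame(bin = as.numeric(names(tab)) + binwidth / 2,
                              count = as.integer(tab)))
}

#' Subsample read pairs
#'
#' Keeps each pair with probability `p`, both mates or neither,
#' deterministically for a fixed seed (paired downsampling for
#' sensitivity-versus-coverage experiments).
#'
#' @param x An `osseq_sim` object, a pair data.frame, or an R1 FASTQ path.
#' @param p Keep probability in \[0,1\].
#' @param seed Integer seed.
#' @param r2_path,out_r1,out_r2 FASTQ paths when `x` is an R1 FASTQ path.
#' @return Object of the same kind as `x` with a subset of pairs.
#' @export
subsample_pairs <- function(x, p, seed = 1L, r2_path = NULL,
                            out_r1 = NULL, out_r2 = NULL) {
  if (p < 0 || p > 1) stopf("keep probability must lie in [0,1]")
  if (inherits(x, "osseq_sim")) {
    x$pairs <- subsample_pairs(x$pairs, p, seed)
    return(x)
  }
  if (is.data.frame(x))
    return(with_seed(seed, x[runif(nrow(x)) < p, , drop = FALSE]))
  r1 <- read_fastq(x); r2 <- read_fastq(r2_path)
  if (nrow(r1) != nrow(r2) ||
      any(sub("/[12]$", "", r1$id) != sub("/[12]$", "", r2$id)))
    stopf("desynchronized mate files: %s / %s", x, r2_path)
  keep <- with_seed(seed, runif(nrow(r1)) < p)
  wr <- function(fq, path) {
    s <- Biostrings::DNAStringSet(setNames(fq$seq, fq$id))
    Biostrings::writeXStringSet(s, path, format = "fastq",
                                qualities = Biostrings::BStringSet(fq$qual),
                                compress = endsWith(path, ".gz"))
  }
  wr(r1[keep, ], out_r1); wr(r2[keep, ], out_r2)
  invisible(c(out_r1, out_r2))
}

#' Assemble a per-sample QC report
#'
#' Computes the panel metrics over ROI bases from on-target, non-duplicate
#' pairs: mean on-target coverage, on-target fraction (denominator = all
#' aligned pairs, ambiguous probes included), fold 80 base penalty,
#' coverage-threshold fractions, insert statistics and duplicate rate.
#'
#' @param pairs Pair data.frame (tagged or raw simulator truth).
#' @param panel Panel data.frame.
#' @param rois ROI data.frame.
#' @param config A [qc_config()].
#' @return List of class `qc_report`.
#' @export
qc_report <- function(pairs, panel, rois, config = qc_config()) {
  pairs <- classify_on_target(pairs, panel, rois, config)
  pairs <- mark_duplicates(pairs)
  cov <- coverage_track(pairs, rois)
  covnz <- any(cov > 0)
  rep <- list(
    n_pairs = nrow(pairs),
    pct_on_target = mean(pairs$on_target),
    duplicate_rate = mean(pairs$duplicate),
    mean_on_target_coverage = mean(cov),
    fold80 = if (covnz) fold80(cov) else NA_real_,
    coverage_fractions = coverage_fractions(cov, config$coverage_thresholds),
    insert = insert_stats(pairs[pairs$on_target & !pairs$duplicate, , drop = FALSE]),
    min_recommended_coverage = config$min_recommended_coverage,
    below_recommended = mean(cov) < config$min_recommended_coverage)
  class(rep) <- "qc_report"
  rep
}

#' Write a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- unclass(report)
  out$insert$histogram <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
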