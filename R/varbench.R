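# Minimal Bayesian germline and tumor/normal variant calling on pileups,
# somatic reporting filters, callset benchmarking, and FFPE damage-ratio
# analysis.  The caller is intentionally minimal (binomial read likelihoods,
# fixed error rate): it makes the toolkit testable end to end and is not a
# numerical equivalent of full production callers.

#' Build site pileups from simulated reads
#'
#' Tallies, at each requested SNV site, the molecules (fragments) or reads
#' overlapping the site and how many carry the alternate allele, using the
#' simulator truth provenance. Counting fragments keeps alternate-allele
#' counts exactly binomial in the allele fraction (mates of one pair are
#' not independent observations).
#'
#' @param sim An `osseq_sim` object.
#' @param sites data.frame `chrom, pos, ref, alt` (0-based).
#' @param unit `"pair"` (fragments) or `"read"`.
#' @return data.frame `chrom, pos, ref, alt, depth, alt_count, ref_count`.
#' @export
pileup_sites <- function(sim, sites, unit = c("pair", "read")) {
  unit <- match.arg(unit)
  p <- sim$pairs
  if (!is.null(p$duplicate_of)) p <- p[is.na(p$duplicate_of), , drop = FALSE]
  out <- sites[, c("chrom", "pos", "ref", "alt")]
  out$depth <- 0L; out$alt_count <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    tag <- sprintf("%s:%d:%s>%s", s$chrom, s$pos, s$ref, s$alt)
    if (unit == "pair") {
      ov <- p$chrom == s$chrom & p$m_start <= s$pos & p$m_end > s$pos
      n <- sum(ov)
      alt <- sum(ov & grepl(tag, p$alleles, fixed = TRUE))
    } else {
      ov1 <- p$chrom == s$chrom & p$r1_start <= s$pos & p$r1_end > s$pos
      ov2 <- p$chrom == s$chrom & p$r2_start <= s$pos & p$r2_end > s$pos
      n <- sum(ov1) + sum(ov2)
      carry <- grepl(tag, p$alleles, fixed = TRUE)
      alt <- sum(ov1 & carry) + sum(ov2 & carry)
    }
    out$depth[i] <- n
    out$alt_count[i] <- alt
  }
  out$ref_count <- out$depth - out$alt_count
  out
}

#' Germline genotyping from a pileup
#'
#' Posterior over \{hom-ref, het, hom-alt\} with binomial read likelihoods
#' (alternate-allele fraction `error_rate`, 0.5, `1 - error_rate`) and
#' Hardy-Weinberg priors from the germline allele frequency.
#'
#' @param pileup data.frame with `depth`, `alt_count` (one or more rows).
#' @param error_rate Per-read error rate.
#' @param germline_prior Prior germline allele frequency (scalar or
#'   per-site vector).
#' @return data.frame with `genotype` (`"0/0"`, `"0/1"`, `"1/1"`, or
#'   `"./."` at zero depth), `posterior` and `vaf`.
#' @export
call_germline <- function(pileup, error_rate = 1e-3, germline_prior = 1e-3) {
  g <- rep_len(germline_prior, nrow(pileup))
  if (any(g <= 0 | g >= 1)) stopf("priors must lie in (0,1)")
  gt <- character(nrow(pileup)); post <- numeric(nrow(pileup))
  for (i in seq_len(nrow(pileup))) {
    d <- pileup$depth[i]; a <- pileup$alt_count[i]
    if (d <= 0) { gt[i] <- "./."; post[i] <- NA_real_; next }
    lp <- c(`0/0` = dbinom(a, d, error_rate, log = TRUE) + 2 * log(1 - g[i]),
            `0/1` = dbinom(a, d, 0.5, log = TRUE) + log(2 * g[i] * (1 - g[i])),
            `1/1` = dbinom(a, d, 1 - error_rate, log = TRUE) + 2 * log(g[i]))
    pp <- exp(lp - max(lp)); pp <- pp / sum(pp)
    gt[i] <- names(which.max(pp)); post[i] <- max(pp)
  }
  cbind(pileup, data.frame(genotype = gt, posterior = post,
                           vaf = ifelse(pileup$depth > 0,
                                        pileup$alt_count / pileup$depth, NA_real_),
                           stringsAsFactors = FALSE))
}

#' Tumor/normal (or tumor-only) somatic scoring
#'
#' Two-node Bayesian network: the tumor inherits the normal genotype and may
#' additionally incur a de novo somatic mutation. Hypotheses are reference
#' (sequencing error only), germline het, germline hom, and somatic (normal
#' is reference; tumor allele fraction free). With no normal pileup the
#' germline component is imputed from the germline prior alone. Each site is
#' labelled by maximum posterior.
#'
#' @param tumor Pileup data.frame for the tumor sample.
#' @param normal Optional pileup data.frame for the matched normal (same
#'   site order).
#' @param error_rate Per-read error rate.
#' @param germline_prior Germline allele frequency prior (scalar or
#'   per-site, e.g. from a population database table).
#' @param somatic_prior Prior probability of a somatic mutation at a site
#'   (e.g. from a somatic hotspot table).
#' @return data.frame with `status` (`reference`/`germline`/`somatic`),
#'   `posterior` and `vaf` (tumor allele fraction estimate).
#' @export
call_somatic <- function(tumor, normal = NULL, error_rate = 1e-3,
                         germline_prior = 1e-3, somatic_prior = 1e-6) {
  g <- rep_len(germline_prior, nrow(tumor))
  s <- rep_len(somatic_prior, nrow(tumor))
  if (any(g <= 0 | g >= 1) || any(s <= 0 | s >= 1))
    stopf("priors must lie in (0,1)")
  status <- character(nrow(tumor)); post <- numeric(nrow(tumor))
  for (i in seq_len(nrow(tumor))) {
    dt <- tumor$depth[i]; at <- tumor$alt_count[i]
    if (dt <= 0) { status[i] <- "no_call"; post[i] <- NA_real_; next }
    f_som <- max(at / dt, 2 * error_rate) # profile tumor allele fraction
    lt <- function(f) dbinom(at, dt, f, log = TRUE)
    ln <- function(f) { # normal likelihood, or 0 when imputed from priors
      if (is.null(normal)) return(0)
      dn <- normal$depth[i]; an <- normal$alt_count[i]
      if (dn <= 0) return(0)
      dbinom(an, dn, f, log = TRUE)
    }
    lp <- c(reference = lt(error_rate) + ln(error_rate) +
              2 * log(1 - g[i]) + log(1 - s[i]),
            germline_het = lt(0.5) + ln(0.5) + log(2 * g[i] * (1 - g[i])),
            germline_hom = lt(1 - error_rate) + ln(1 - error_rate) + 2 * log(g[i]),
            somatic = lt(f_som) + ln(error_rate) +
              2 * log(1 - g[i]) + log(s[i]))
    pp <- exp(lp - max(lp)); pp <- pp / sum(pp)
    lab <- names(which.max(pp))
    status[i] <- c(reference = "reference", germline_het = "germline",
                   germline_hom = "germline", somatic = "somatic")[lab]
    post[i] <- max(pp)
  }
  cbind(tumor[, setdiff(names(tumor), c("status", "posterior"))],
        data.frame(status = status, posterior = post,
                   vaf = ifelse(tumor$depth > 0, tumor$alt_count / tumor$depth,
                                NA_real_), stringsAsFactors = FALSE))
}

#' Somatic reporting filter
#'
#' Retains calls with multiple read support occurring above an overall
#' depth threshold (40X by default); removal reasons are recorded.
#'
#' @param calls Call data.frame with `depth` and `alt_count`.
#' @param min_depth Minimum overall depth (X).
#' @param min_alt_reads Minimum alternate reads ("multiple read support").
#' @return List with `kept` and `removed` (with `filter_reason`).
#' @export
filter_somatic_report <- function(calls, min_depth = 40L, min_alt_reads = 2L) {
  if (!nrow(calls))
    return(list(kept = calls, removed = cbind(calls, filter_reason = character(0))))
  reason <- rep(NA_character_, nrow(calls))
  reason[calls$alt_count < min_alt_reads] <- sprintf("alt_reads<%d", min_alt_reads)
  reason[calls$depth < min_depth] <- sprintf("depth<%dX", min_depth)
  keep <- is.na(reason)
  removed <- calls[!keep, , drop = FALSE]
  removed$filter_reason <- reason[!keep]
  list(kept = calls[keep, , drop = FALSE], removed = removed)
}

#' Normalize variant representation
#'
#' Trims redundant shared bases to the minimal representation and
#' left-aligns indels against the reference so equivalent representations
#' match during benchmarking.
#'
#' @param variants Variant data.frame (`chrom, pos, ref, alt`, 0-based).
#' @param genome Optional reference (required for left-alignment; without
#'   it only minimal-representation trimming is applied).
#' @return Normalized variant data.frame.
#' @export
normalize_variants <- function(variants, genome = NULL) {
  if (!nrow(variants)) return(variants)
  if (!is.null(genome)) genome <- as_genome(genome)
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]; ref <- variants$ref[i]; alt <- variants$alt[i]
    chromseq <- if (!is.null(genome)) genome[[variants$chrom[i]]] else NULL
    # left-align: chop equal trailing bases, extending left from the
    # reference when an allele empties; stop when ends differ
    repeat {
      nr <- nchar(ref); na <- nchar(alt)
      if (nr > 0L && na > 0L &&
          (if (is.null(chromseq)) nr > 1L && na > 1L else nr > 1L || na > 1L) &&
          substr(ref, nr, nr) == substr(alt, na, na)) {
        ref <- substr(ref, 1L, nr - 1L); alt <- substr(alt, 1L, na - 1L)
      } else if (nr == 0L || na == 0L) {
        if (is.null(chromseq) || pos <= 0L) {
          # cannot extend further; re-anchor on the following base
          if (!is.null(chromseq)) {
            nxt <- as.character(Biostrings::subseq(chromseq, pos + 1L, pos + 1L))
            ref <- paste0(nxt, ref); alt <- paste0(nxt, alt)
          }
          break
        }
        prev <- as.character(Biostrings::subseq(chromseq, pos, pos)) # 0-based pos-1
        ref <- paste0(prev, ref); alt <- paste0(prev, alt)
        pos <- pos - 1L
      } else break
    }
    # trim common prefix to the minimal representation
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    variants$pos[i] <- pos; variants$ref[i] <- ref; variants$alt[i] <- alt
  }
  variants
}

#' Compare a test callset against a truth callset
#'
#' Restricted to the ROI universe enlarged by each ROI's flank, both sets
#' are normalized and matched on position and alleles (genotype ignored in
#' allele-match mode, the squash-ploidy convention). TP = truth variants
#' matched by a call; FN = unmatched truth; FP = unmatched calls.
#'
#' @param test,truth Variant data.frames or VCF paths.
#' @param rois ROI data.frame (or `NULL` for no restriction).
#' @param genome Optional reference for indel left-alignment.
#' @param mode Matching mode; `"allele"` matches position + ref + alt.
#' @return List of class `benchmark_counts`: `tp, fn, fp` and the matched /
#'   unmatched tables.
#' @export
compare_callsets <- function(test, truth, rois = NULL, genome = NULL,
                             mode = c("allele")) {
  mode <- match.arg(mode)
  test <- normalize_variants(read_variants(test), genome)
  truth <- normalize_variants(read_variants(truth), genome)
  if (!is.null(rois)) {
    rois <- validate_rois(rois)
    inroi <- function(v) {
      keep <- logical(nrow(v))
      for (r in seq_len(nrow(rois)))
        keep <- keep | (v$chrom == rois$chrom[r] &
                          v$pos >= rois$start[r] - rois$flank[r] &
                          v$pos < rois$end[r] + rois$flank[r])
      v[keep, , drop = FALSE]
    }
    test <- inroi(test); truth <- inroi(truth)
  }
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  tp_mask <- key(truth) %in% key(test)
  fp_mask <- !(key(test) %in% key(truth))
  structure(list(tp = sum(tp_mask), fn = sum(!tp_mask), fp = sum(fp_mask),
                 matched = truth[tp_mask, , drop = FALSE],
                 missed = truth[!tp_mask, , drop = FALSE],
                 spurious = test[fp_mask, , drop = FALSE]),
            class = "benchmark_counts")
}

#' Accuracy metrics with the panel's TN universe
#'
#' Sensitivity = TP/(TP+FN), PPV = TP/(TP+FP), both as percentages rounded
#' to one decimal. The true-negative universe is the number of callable ROI
#' bases minus the truth positions. Specificity defaults to the as-printed
#' formula TN/(TN+FN); the conventional TN/(TN+FP) is available and the
#' choice is recorded in the result.
#'
#' @param counts A `benchmark_counts` (or list with `tp, fn, fp`).
#' @param tn_universe_bases Number of callable ROI bases.
#' @param specificity_formula `"as_printed"` (TN/(TN+FN)) or
#'   `"conventional"` (TN/(TN+FP)).
#' @return List with `tp, fn, fp, tn`, `sensitivity`, `specificity`, `ppv`
#'   (percent, 1 decimal) and `detected_fraction` (2 decimals).
#' @export
accuracy_metrics <- function(counts, tn_universe_bases = NULL,
                             specificity_formula = c("as_printed", "conventional")) {
  specificity_formula <- match.arg(specificity_formula)
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp
  stopifnot(tp >= 0, fn >= 0, fp >= 0)
  sens <- if (tp + fn > 0) round(100 * tp / (tp + fn), 1) else NA_real_
  ppv <- if (tp + fp > 0) round(100 * tp / (tp + fp), 1) else NA_real_
  tn <- spec <- NA_real_
  if (!is.null(tn_universe_bases)) {
    tn <- tn_universe_bases - (tp + fn)
    spec <- switch(specificity_formula,
                   as_printed = round(100 * tn / (tn + fn), 1),
                   conventional = round(100 * tn / (tn + fp), 1))
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = sens, specificity = spec, ppv = ppv,
       detected_fraction = if (tp + fn > 0) round(tp / (tp + fn), 2) else NA_real_,
       specificity_formula = specificity_formula)
}

#' C>T/A>G transition ratio
#'
#' Percentage of SNVs that are C>T (or G>A on the opposite strand) — the
#' signature of FFPE cytosine deamination. Used to compare repair-on versus
#' repair-off processing.
#'
#' @param variants SNV data.frame with `ref`, `alt` (single bases).
#' @return Percentage in \[0,100\], `NA` for an empty set.
#' @export
ct_ag_ratio <- function(variants) {
  snv <- variants[nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, ,
                  drop = FALSE]
  if (!nrow(snv)) return(NA_real_)
  100 * mean((snv$ref == "C" & snv$alt == "T") |
               (snv$ref == "G" & snv$alt == "A"))
}

#' Tally mismatch substitutions from simulated reads against the reference
#'
#' Pileup-free damage readout: compares emitted read bases with the
#' reference over aligned positions and tabulates substitution types in
#' plus-strand coordinates, orienting each read's bases by its strand.
#'
#' @param sim An `osseq_sim` object.
#' @param max_pairs Cap on pairs scanned (for speed).
#' @return data.frame `ref, alt, count` over observed substitutions.
#' @export
mismatch_spectrum <- function(sim, max_pairs = 5000L) {
  p <- head(sim$pairs, max_pairs)
  genome <- sim$genome
  counts <- new.env(parent = emptyenv())
  bump <- function(r, a) {
    k <- paste0(r, ">", a)
    assign(k, (counts[[k]] %||% 0L) + 1L, envir = counts)
  }
  scan_read <- function(chrom, start, end, strand, seqs) {
    refseq <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
    obs <- if (strand == "-") revcomp(seqs) else seqs
    if (nchar(obs) != nchar(refseq)) return(invisible())
    rb <- strsplit(refseq, "", fixed = TRUE)[[1L]]
    ob <- strsplit(obs, "", fixed = TRUE)[[1L]]
    d <- which(rb != ob & ob != "N")
    for (j in d) bump(rb[j], ob[j])
  }
  for (i in seq_len(nrow(p))) {
    scan_read(p$chrom[i], p$r1_start[i], p$r1_end[i], p$r1_strand[i], p$r1_seq[i])
    scan_read(p$chrom[i], p$r2_start[i], p$r2_end[i], p$r2_strand[i], p$r2_seq[i])
  }
  ks <- ls(counts)
  if (!length(ks)) return(data.frame(ref = character(), alt = character(),
                                     count = integer(), stringsAsFactors = FALSE))
  data.frame(ref = substr(ks, 1L, 1L), alt = substr(ks, 3L, 3L),
             count = vapply(ks, function(k) counts[[k]], 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
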