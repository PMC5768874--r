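# Primer-probe panel design: candidate scoring, pool cross-checks and
# greedy per-window selection tiling both strands of each ROI.

#' Panel design configuration
#'
#' Tunables for probe tiling and the empirical candidate scoring scheme.
#' Each scoring component is normalized to \[0,1\] before weighting, so a
#' perfect candidate scores `sum(weights)`.
#'
#' @param target_spacing_per_strand Target distance between consecutive probe
#'   anchors on each strand (bp). One probe per 100 bp per strand tiles both
#'   strands at roughly one probe per 50 bp combined.
#' @param probe_length `c(min, max)` probe length in nt.
#' @param tm_window Acceptable melting-temperature window, degrees C; probes
#'   must be compatible with a common annealing temperature.
#' @param gc_window Acceptable GC fraction window.
#' @param max_homopolymer Longest tolerated homopolymer run (bp).
#' @param max_dimer_run Longest tolerated self/hetero 3'-complementarity run
#'   (bp) before the secondary-structure component is penalized.
#' @param snp_mask Optional data.frame `chrom, pos` (0-based) of masked
#'   polymorphic positions probes should avoid.
#' @param specificity_k k-mer length used for genome-wide uniqueness of the
#'   probe 3' end.
#' @param score_threshold Minimum total score for a candidate to be
#'   selectable.
#' @param weights Named non-negative weights for the components
#'   `tm, gc, homopolymer, structure, snp, specificity, position, coverage`.
#' @param candidate_step Anchor step (bp) when enumerating candidates inside
#'   a tiling window.
#' @param salt_params List with `Na` (molar monovalent cation) and `conc`
#'   (molar total oligo concentration) for the melting-temperature model.
#' @return A list of class `design_config`.
#' @export
design_config <- function(target_spacing_per_strand = 100L,
                          probe_length = c(22L, 28L),
                          tm_window = c(58, 66),
                          gc_window = c(0.30, 0.70),
                          max_homopolymer = 4L,
                          max_dimer_run = 6L,
                          snp_mask = NULL,
                          specificity_k = 16L,
                          score_threshold = 6,
                          weights = c(tm = 1, gc = 1, homopolymer = 1,
                                      structure = 1, snp = 1, specificity = 1,
                                      position = 1, coverage = 1),
                          candidate_step = 5L,
                          salt_params = list(Na = 0.05, conc = 2.5e-7)) {
  if (target_spacing_per_strand <= 0) stopf("spacing must be > 0")
  if (any(weights < 0)) stopf("scoring weights must be >= 0")
  stopifnot(length(probe_length) == 2L, probe_length[1L] <= probe_length[2L])
  structure(list(target_spacing_per_strand = as.integer(target_spacing_per_strand),
                 probe_length = as.integer(probe_length), tm_window = tm_window,
                 gc_window = gc_window, max_homopolymer = as.integer(max_homopolymer),
                 max_dimer_run = as.integer(max_dimer_run), snp_mask = snp_mask,
                 specificity_k = as.integer(specificity_k),
                 score_threshold = score_threshold, weights = weights,
                 candidate_step = as.integer(candidate_step),
                 salt_params = salt_params),
            class = "design_config")
}

# Unified nearest-neighbor stacking parameters (SantaLucia 1998):
# dH kcal/mol, dS cal/(mol K), for the 10 unique Watson-Crick NN stacks,
# keyed by the top-strand dinucleotide.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
            GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
            GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor duplex model with unified stacking parameters,
#' terminal initiation terms, a salt entropy correction
#' (0.368 * (N-1) * ln\[Na+\]) and the usual oligo concentration term
#' (CT/4 for non-self-complementary duplexes).
#'
#' @param sequence Probe sequence, 5'->3', ACGT only.
#' @param salt_params List with `Na` (molar) and `conc` (molar oligo
#'   concentration); defaults 50 mM Na+, 250 nM oligo.
#' @return Melting temperature in degrees C.
#' @export
#' @examples
#' compute_tm("ACGTACGTACGTACGTACGT")
compute_tm <- function(sequence, salt_params = list(Na = 0.05, conc = 2.5e-7)) {
  check_dna(sequence)
  n <- nchar(sequence)
  if (n < 2L) stopf("sequence too short for a nearest-neighbor estimate")
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  nn <- paste0(b[-n], b[-1L])
  dh <- sum(.nn_dh[nn])
  ds <- sum(.nn_ds[nn])
  # initiation at each terminus
  for (t in b[c(1L, n)]) {
    if (t %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(salt_params$Na)
  R <- 1.9872
  1000 * dh / (ds + R * log(salt_params$conc / 4)) - 273.15
}

# Count genome-wide occurrences (both strands) of the probe's 3'-terminal
# k-mer. A simple exact-multiplicity index built once per genome.
#' Build a k-mer multiplicity index for specificity scoring
#' @param genome Reference genome (`DNAStringSet`, character, or FASTA path).
#' @param k k-mer length.
#' @return An environment mapping k-mer to genome-wide count (both strands).
#' @export
kmer_index <- function(genome, k = 16L) {
  genome <- as_genome(genome)
  all_km <- character(0)
  for (i in seq_along(genome)) {
    for (s in c(as.character(genome[[i]]), revcomp(as.character(genome[[i]])))) {
      n <- nchar(s)
      if (n < k) next
      km <- substring(s, 1:(n - k + 1L), k:n)
      all_km <- c(all_km, km[!grepl("N", km, fixed = TRUE)])
    }
  }
  r <- rle(sort(all_km))
  dup <- r$values[r$lengths > 1L]
  env <- new.env(parent = emptyenv(), size = max(29L, length(dup)))
  # only multiplicities > 1 are stored; genome-derived k-mers absent from
  # the table are unique by construction
  duplens <- r$lengths[r$lengths > 1L]
  for (j in seq_along(dup)) assign(dup[j], duplens[j], envir = env)
  attr(env, "k") <- as.integer(k)
  env
}

kmer_count <- function(index, kmer) index[[kmer]] %||% 1L

#' Score a candidate probe
#'
#' Empirical design score combining intrinsic sequence features (melting
#' temperature, GC content, homopolymers, secondary structure) and genomic
#' features (masked SNP overlap, genome-wide uniqueness of the 3'-terminal
#' k-mer, relative position within the ROI, and new ROI coverage gained).
#' Each component lies in \[0,1\]; the total is the weighted sum.
#'
#' @param candidate List or one-row data.frame with `chrom, start, end,
#'   strand, sequence` (0-based half-open footprint).
#' @param config A [design_config()].
#' @param genome_index k-mer index from [kmer_index()] (or `NULL` to skip
#'   the specificity component, which then scores 1).
#' @param roi Optional ROI row (`start`, `end`) for the position component.
#' @param covered Optional logical vector over the ROI (TRUE = base already
#'   covered) for the coverage-gain component.
#' @return List with `score` and named `components`.
#' @export
score_candidate <- function(candidate, config, genome_index = NULL,
                            roi = NULL, covered = NULL) {
  s <- candidate$sequence
  if (grepl("[^ACGT]", s)) {
    comp <- setNames(numeric(length(config$weights)), names(config$weights))
    return(list(score = 0, components = comp, tm = NA_real_))
  }
  n <- nchar(s)
  band <- function(x, win, scale) {
    d <- max(0, win[1L] - x, x - win[2L])
    max(0, 1 - d / scale)
  }
  tm <- compute_tm(s, config$salt_params)
  comp <- c(tm = band(tm, config$tm_window, 10),
            gc = band(gc_fraction(s), config$gc_window, 0.2))
  run <- max_homopolymer_run(s)
  comp["homopolymer"] <- if (run <= config$max_homopolymer) 1 else
    max(0, 1 - (run - config$max_homopolymer) / config$max_homopolymer)
  dim_run <- comp_run_3p(s, s)
  comp["structure"] <- if (dim_run < config$max_dimer_run) 1 else
    max(0, 1 - (dim_run - config$max_dimer_run + 1L) / 4)
  comp["snp"] <- 1
  if (!is.null(config$snp_mask)) {
    m <- config$snp_mask
    hit <- any(m$chrom == candidate$chrom & m$pos >= candidate$start &
                 m$pos < candidate$end)
    if (hit) comp["snp"] <- 0
  }
  comp["specificity"] <- 1
  if (!is.null(genome_index)) {
    k <- attr(genome_index, "k")
    if (n >= k) { # uniqueness of the 3'-terminal k-mer, both strands counted
      cnt <- kmer_count(genome_index, substr(s, n - k + 1L, n))
      comp["specificity"] <- if (cnt <= 1L) 1 else 1 / cnt
    }
  }
  comp["position"] <- 1
  if (!is.null(roi)) {
    d_edge <- min(candidate$start - (roi$start - n), roi$end + n - candidate$end)
    comp["position"] <- max(0, min(1, d_edge / n))
  }
  comp["coverage"] <- 1
  if (!is.null(covered) && !is.null(roi)) {
    idx <- max(candidate$start, roi$start):min(candidate$end - 1L, roi$end - 1L) - roi$start + 1L
    idx <- idx[idx >= 1L & idx <= length(covered)]
    comp["coverage"] <- if (length(idx)) mean(!covered[idx]) else 0
  }
  comp <- comp[names(config$weights)]
  list(score = sum(config$weights * comp), components = comp, tm = tm)
}

# Longest run of consecutive Watson-Crick complementary bases terminating at
# the 3' end of `a` when annealed antiparallel to `b` at any register.
comp_run_3p <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(revcomp1(b), "", fixed = TRUE)[[1L]]
  na <- length(x); nb <- length(y)
  best <- 0L
  for (j in seq_len(nb)) {
    r <- 0L
    while (r < na && (j - r) >= 1L && x[na - r] == y[j - r]) r <- r + 1L
    if (r > best) best <- r
  }
  best
}

#' Flag potential primer-primer interactions within a pool
#'
#' Scans all probe pairs for 3'-end complementarity runs at or above
#' `min_run` (primer-dimer risk in a multiplexed capture pool). The flag is
#' symmetric in the pair.
#'
#' @param probes Panel data.frame (or character vector of sequences).
#' @param min_run Run length (bp) at or above which a pair is flagged.
#' @return data.frame `id_a, id_b, run` of flagged pairs.
#' @export
check_pool_interactions <- function(probes, min_run = 6L) {
  seqs <- if (is.data.frame(probes)) probes$sequence else probes
  ids <- if (is.data.frame(probes)) probes$id else paste0("probe", seq_along(seqs))
  if (length(seqs) < 2L) stopf("need >= 2 probes to evaluate pool interactions")
  out <- list()
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (i >= j) next
    run <- max(comp_run_3p(seqs[i], seqs[j]), comp_run_3p(seqs[j], seqs[i]))
    if (run >= min_run)
      out[[length(out) + 1L]] <- data.frame(id_a = ids[i], id_b = ids[j],
                                            run = run, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(id_a = character(), id_b = character(),
                                      run = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

extract_probe_seq <- function(genome, chrom, start, end, strand) {
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-") revcomp(s) else s
}

#' Design a primer-probe panel tiling both strands of each ROI
#'
#' Greedy selection: each ROI strand is split into windows of the target
#' spacing; within a window, candidate probes (anchors stepped by
#' `candidate_step`, lengths spanning `probe_length`) are scored and the
#' highest-scoring candidate at or above `score_threshold` is selected.
#' Windows with no passing candidate are recorded as coverage gaps.
#' Deterministic: ties break to the leftmost anchor, then the + strand.
#'
#' @param rois ROI data.frame (see [read_rois()]).
#' @param genome Reference (`DNAStringSet`, character vector, or FASTA path).
#' @param config A [design_config()].
#' @return List of class `osseq_panel_design` with `panel` (probe
#'   data.frame) and `gaps` (windows without a passing probe).
#' @export
design_panel <- function(rois, genome, config = design_config()) {
  genome <- as_genome(genome)
  rois <- validate_rois(rois)
  if (any(!(rois$chrom %in% names(genome))))
    stopf("ROI chromosome absent from reference")
  if (any(rois$end > Biostrings::width(genome)[match(rois$chrom, names(genome))]))
    stopf("ROI exceeds reference bounds")
  gidx <- kmer_index(genome, config$specificity_k)
  spacing <- config$target_spacing_per_strand
  lens <- unique(round(seq(config$probe_length[1L], config$probe_length[2L],
                           length.out = min(3L, diff(config$probe_length) + 1L))))
  probes <- list(); gaps <- list()
  chrom_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(rois))) {
    roi <- rois[r, ]
    if (is.null(chrom_cache[[roi$chrom]]))
      chrom_cache[[roi$chrom]] <- as.character(genome[[roi$chrom]])
    chrom_seq <- chrom_cache[[roi$chrom]]
    roi_len <- roi$end - roi$start
    covered <- rep(FALSE, roi_len)
    win_starts <- seq(roi$start, roi$end - 1L, by = spacing)
    for (strand in c("+", "-")) {
      for (w in win_starts) {
        w_end <- min(w + spacing, roi$end)
        best <- NULL
        for (a in seq(w, w_end - 1L, by = config$candidate_step)) {
          for (L in lens) {
            # footprint placed inside the ROI; anchor (3' extension start)
            # faces the window position
            if (strand == "+") { p_start <- a - L + 1L; p_end <- a + 1L }
            else { p_start <- a; p_end <- a + L }
            if (p_start < roi$start || p_end > roi$end) next
            seqs <- substr(chrom_seq, p_start + 1L, p_end)
            if (strand == "-") seqs <- revcomp1(seqs)
            cand <- list(chrom = roi$chrom, start = p_start, end = p_end,
                         strand = strand, sequence = seqs)
            sc <- score_candidate(cand, config, gidx, roi = roi, covered = covered)
            if (sc$score >= config$score_threshold &&
                (is.null(best) || sc$score > best$score + 1e-12)) {
              best <- c(cand, list(score = sc$score, tm = sc$tm, anchor = a))
            }
          }
        }
        if (is.null(best)) {
          gaps[[length(gaps) + 1L]] <- data.frame(
            roi_id = roi$roi_id, chrom = roi$chrom, window_start = w,
            window_end = w_end, strand = strand, stringsAsFactors = FALSE)
        } else {
          probes[[length(probes) + 1L]] <- data.frame(
            chrom = best$chrom, start = best$start, end = best$end,
            strand = best$strand, anchor = best$anchor, sequence = best$sequence,
            roi_id = roi$roi_id, gene = roi$gene, score = best$score,
            tm = best$tm, stringsAsFactors = FALSE)
          cov_idx <- (best$start:(best$end - 1L)) - roi$start + 1L
          cov_idx <- cov_idx[cov_idx >= 1L & cov_idx <= roi_len]
          covered[cov_idx] <- TRUE
        }
      }
    }
  }
  panel <- if (length(probes)) do.call(rbind, probes) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), anchor = integer(), sequence = character(),
               roi_id = character(), gene = character(), score = numeric(),
               tm = numeric(), stringsAsFactors = FALSE)
  if (nrow(panel)) {
    panel <- panel[order(panel$chrom, panel$anchor, panel$strand), , drop = FALSE]
    panel$id <- sprintf("P%05d", seq_len(nrow(panel)))
    panel <- panel[, c("id", "chrom", "start", "end", "strand", "anchor",
                       "sequence", "roi_id", "gene", "score", "tm")]
    rownames(panel) <- NULL
  } else panel$id <- character()
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(roi_id = character(), chrom = character(), window_start = integer(),
               window_end = integer(), strand = character(), stringsAsFactors = FALSE)
  structure(list(panel = panel, gaps = gaps, config = config),
            class = "osseq_panel_design")
}

#' Construct an idealized grid panel
#'
#' Places one probe every `spacing` bp on each strand of every ROI without
#' scoring (anchors on an exact grid). Useful for simulation experiments
#' where the capture geometry, not the scoring scheme, is under study.
#'
#' @param rois ROI data.frame.
#' @param genome Reference genome.
#' @param spacing Anchor spacing per strand (bp).
#' @param probe_length Probe length (nt).
#' @return Panel data.frame.
#' @export
panel_from_grid <- function(rois, genome, spacing = 100L, probe_length = 25L) {
  genome <- as_genome(genome)
  rois <- validate_rois(rois)
  L <- as.integer(probe_length)
  out <- list()
  for (r in seq_len(nrow(rois))) {
    roi <- rois[r, ]
    anchors <- seq(roi$start + L, roi$end - L - 1L, by = spacing)
    if (!length(anchors)) next
    for (strand in c("+", "-")) {
      p_start <- if (strand == "+") anchors - L + 1L else anchors
      p_end <- p_start + L
      seqs <- vapply(seq_along(anchors), function(i)
        extract_probe_seq(genome, roi$chrom, p_start[i], p_end[i], strand), "")
      out[[length(out) + 1L]] <- data.frame(
        chrom = roi$chrom, start = p_start, end = p_end, strand = strand,
        anchor = anchors, sequence = seqs, roi_id = roi$roi_id,
        gene = roi$gene, score = NA_real_, tm = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, out)
  panel <- panel[order(panel$chrom, panel$anchor, panel$strand), , drop = FALSE]
  panel$id <- sprintf("P%05d", seq_len(nrow(panel)))
  rownames(panel) <- NULL
  panel[, c("id", "chrom", "start", "end", "strand", "anchor", "sequence",
            "roi_id", "gene", "score", "tm")]
}
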