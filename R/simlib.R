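# OS-Seq library simulator: fragmentation, FFPE deamination with
# excision-only repair, single-strand adapter ligation, probe capture with
# a geometric site-choice model, and paired-end read emission with full
# truth provenance.  Also direct per-ROI coverage-matrix simulation for
# copy-number experiments.

#' Fragmentation model
#' @param mean_length Mean fragment length, bp (sheared input DNA).
#' @param sd Standard deviation, bp.
#' @param min_length Minimum fragment length, bp (truncation point).
#' @return List of class `fragment_model`.
#' @export
fragment_model <- function(mean_length = 550, sd = 50, min_length = 100) {
  if (!(mean_length >= min_length && min_length > 0))
    stopf("need mean_length >= min_length > 0")
  structure(list(mean_length = mean_length, sd = sd, min_length = min_length),
            class = "fragment_model")
}

#' FFPE damage model
#'
#' Cytosine deamination to uracil on single-stranded templates, observed as
#' C>T (G>A on the opposite strand) transitions when no repair is applied.
#' With `repair = "excision_on"` damaged bases are removed by excision only:
#' synthesis terminates at the uracil site instead of emitting the
#' transition base (no corrective repair).
#'
#' @param deamination_rate Per-C probability of deamination per strand.
#' @param repair `"excision_on"` or `"off"`.
#' @param single_strand_fraction Fraction of input molecules denatured
#'   (single-stranded) before ligation; recorded as provenance.
#' @return List of class `ffpe_model`.
#' @export
ffpe_model <- function(deamination_rate = 0, repair = c("excision_on", "off"),
                       single_strand_fraction = 0.5) {
  repair <- match.arg(repair)
  if (deamination_rate < 0 || deamination_rate > 1)
    stopf("deamination_rate must lie in [0,1]")
  if (single_strand_fraction < 0 || single_strand_fraction > 1)
    stopf("single_strand_fraction must lie in [0,1]")
  structure(list(deamination_rate = deamination_rate, repair = repair,
                 single_strand_fraction = single_strand_fraction),
            class = "ffpe_model")
}

#' Probe capture model
#'
#' The probe binding site closest to the adapter-ligated fragment end is not
#' always the site used: the distance from the ligated end to the first
#' eligible site is ~Uniform(0, spacing) (anchors fall anywhere relative to
#' a random fragment end) and the index of the site actually used beyond
#' that is Geometric(p), truncated to the sites the fragment contains.
#' With spacing 100 bp/strand and p = 2/3 the mean insert is ~100 nt.
#'
#' @param site_spacing_per_strand Probe anchor spacing per strand, bp.
#' @param capture_prob Probability `p` that the nearest eligible site is
#'   used; successive sites follow Geometric(p).
#' @param max_insert Maximum insert size emitted, bp.
#' @param mispriming_rate Fraction of captured molecules generated by
#'   spurious (off-target) priming at a random genomic locus.
#' @param duplicate_rate PCR duplicate rate: fraction of pairs re-emitted as
#'   duplicates sharing probe and fragment end.
#' @return List of class `capture_model`.
#' @export
capture_model <- function(site_spacing_per_strand = 100L, capture_prob = 2 / 3,
                          max_insert = 600L, mispriming_rate = 0,
                          duplicate_rate = 0) {
  if (!(capture_prob > 0 && capture_prob <= 1))
    stopf("capture_prob must lie in (0,1]")
  structure(list(site_spacing_per_strand = as.integer(site_spacing_per_strand),
                 capture_prob = capture_prob, max_insert = as.integer(max_insert),
                 mispriming_rate = mispriming_rate, duplicate_rate = duplicate_rate),
            class = "capture_model")
}

#' Generate a synthetic reference genome and ROI panel
#'
#' Lays `n_genes` gene loci along one synthetic chromosome, each with
#' `roi_per_gene` exon-sized ROIs, with random uniform-composition sequence
#' (GC ~ 0.5 unless configured). Deterministic for a fixed seed.
#'
#' @param n_genes Number of gene loci.
#' @param roi_per_gene ROIs (exons) per gene.
#' @param roi_len ROI length, bp.
#' @param seed Integer seed.
#' @param intron_len Gap between ROIs of one gene, bp.
#' @param intergenic_len Gap between gene loci, bp.
#' @param gc GC fraction of the simulated sequence.
#' @return List with `genome` (DNAStringSet) and `rois` (data.frame).
#' @export
make_reference <- function(n_genes, roi_per_gene = 2L, roi_len = 300L, seed = 1L,
                           intron_len = 200L, intergenic_len = 500L, gc = 0.5) {
  if (n_genes <= 0 || roi_per_gene <= 0 || roi_len <= 0)
    stopf("n_genes, roi_per_gene and roi_len must all be > 0")
  with_seed(seed, {
    gene_span <- roi_per_gene * roi_len + (roi_per_gene - 1L) * intron_len
    total <- n_genes * (gene_span + intergenic_len) + intergenic_len
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqchr <- paste(sample(names(p), total, replace = TRUE, prob = p),
                    collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(seqchr, "chr1"))
    rois <- list()
    pos <- intergenic_len
    for (g in seq_len(n_genes)) {
      gene <- sprintf("GENE%03d", g)
      for (e in seq_len(roi_per_gene)) {
        rois[[length(rois) + 1L]] <- data.frame(
          chrom = "chr1", start = pos, end = pos + roi_len, gene = gene,
          flank = 50L, stringsAsFactors = FALSE)
        pos <- pos + roi_len + if (e < roi_per_gene) intron_len else 0L
      }
      pos <- pos + intergenic_len
    }
    rois <- validate_rois(do.call(rbind, rois))
    list(genome = genome, rois = rois)
  })
}

#' Simulate variant specifications
#'
#' Draws SNV positions inside ROIs and assigns allele fractions, producing
#' the truth set for a simulated sample.
#'
#' @param genome Reference genome.
#' @param rois ROI data.frame.
#' @param n Number of variants.
#' @param vafs Allele fractions to cycle through.
#' @param origin `"somatic"` or `"germline"` label.
#' @param seed Integer seed.
#' @return Variant data.frame (`chrom, pos, ref, alt, vaf, kind, origin`).
#' @export
simulate_variants <- function(genome, rois, n, vafs = c(0.05, 0.10, 0.15, 0.25, 0.40),
                              origin = "somatic", seed = 1L) {
  genome <- as_genome(genome)
  with_seed(seed, {
    roi_idx <- sample(rep(seq_len(nrow(rois)), length.out = n))
    pos <- vapply(roi_idx, function(i)
      sample(seq(rois$start[i] + 5L, rois$end[i] - 6L), 1L), 1L)
    keep <- !duplicated(pos)
    roi_idx <- roi_idx[keep]; pos <- pos[keep]
    chrom <- rois$chrom[roi_idx]
    ref <- vapply(seq_along(pos), function(i)
      as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i] + 1L, pos[i] + 1L)), "")
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               vaf = rep_len(vafs, length(pos)), kind = "SNV", origin = origin,
               stringsAsFactors = FALSE)
  })
}

# Eligible probe anchors for a set of fragments on one chromosome and one
# template strand, with geometric site choice. Plus-strand templates are
# captured by minus-strand probes extending toward the fragment start
# (ligated end); minus-strand templates by plus-strand probes extending
# toward the fragment end.
.pick_sites <- function(f_start, f_end, anchors, plens, template, p_geom) {
  n <- length(f_start)
  k <- rgeom(n, p_geom)
  # anchors within [f_start, f_end): lo..hi (anchors sorted ascending)
  lo <- findInterval(f_start - 0.5, anchors) + 1L
  hi <- findInterval(f_end - 0.5, anchors)
  idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (lo[i] > hi[i]) next
    cand <- lo[i]:hi[i]
    ok <- if (template == "+")
      anchors[cand] + plens[cand] <= f_end[i]   # footprint right of anchor
    else
      anchors[cand] - plens[cand] + 1L >= f_start[i] # footprint left of anchor
    cand <- cand[ok]
    if (!length(cand)) next
    # order by distance from the adapter-ligated end (f_start for "+"
    # templates, f_end for "-" templates)
    if (template == "-") cand <- rev(cand)
    idx[i] <- cand[min(k[i], length(cand) - 1L) + 1L]
  }
  idx
}

#' Simulate an OS-Seq sequencing library
#'
#' Implements the library architecture end to end: fragments are drawn from
#' the ROI space (depth scaled by copy ratio for genes under a CNA spec),
#' denatured to single-stranded templates, subjected to FFPE deamination,
#' adapter-ligated at their 5' end, and captured by panel probes under the
#' geometric site-choice model. Read 1 begins with the generating probe's
#' sequence at the probe's fixed genomic anchor; Read 2 initiates at the
#' adapter-ligated fragment end. Every pair carries a truth record.
#'
#' @param genome Reference genome (`DNAStringSet`, character, FASTA path).
#' @param panel Probe panel data.frame (see [design_panel()]).
#' @param rois ROI data.frame.
#' @param variants Optional variant data.frame (`chrom, pos, ref, alt, vaf,
#'   kind`); alleles are drawn per molecule (binomial in `vaf`).
#' @param cnas Optional data.frame `gene, copy_ratio`; fragment sampling
#'   weight for a gene's ROIs is scaled by its copy ratio.
#' @param fm,ffpe,cm [fragment_model()], [ffpe_model()], [capture_model()].
#' @param n_pairs Number of read pairs to emit (before duplicates).
#' @param read_length Read length, nt (paired 2 x 150 by default).
#' @param seq_error Uniform per-base substitution error rate.
#' @param seed Integer seed.
#' @return Object of class `osseq_sim`: list with `pairs` (truth table, one
#'   row per read pair), `variants`, `panel`, `rois`, and the models used.
#' @export
simulate_library <- function(genome, panel, rois, variants = NULL, cnas = NULL,
                             fm = fragment_model(), ffpe = ffpe_model(),
                             cm = capture_model(), n_pairs = 10000L,
                             read_length = 150L, seq_error = 1e-3, seed = 1L) {
  genome <- as_genome(genome)
  rois <- validate_rois(rois)
  if (!all(panel$chrom %in% names(genome)))
    stopf("probe %s lies off the reference", panel$id[!(panel$chrom %in% names(genome))][1L])
  glen <- setNames(Biostrings::width(genome), names(genome))
  if (any(panel$end > glen[panel$chrom]) || any(panel$start < 0L))
    stopf("probe %s lies off the reference",
          panel$id[which(panel$end > glen[panel$chrom] | panel$start < 0L)[1L]])
  if (!is.null(variants) && nrow(variants)) {
    vref <- vapply(seq_len(nrow(variants)), function(i)
      as.character(Biostrings::subseq(genome[[variants$chrom[i]]],
                                      variants$pos[i] + 1L,
                                      variants$pos[i] + nchar(variants$ref[i]))), "")
    if (any(vref != variants$ref))
      stopf("variant ref allele mismatch at %s:%d", variants$chrom[which(vref != variants$ref)[1L]],
            variants$pos[which(vref != variants$ref)[1L]])
    if (any(variants$vaf <= 0 | variants$vaf > 1)) stopf("vaf must lie in (0,1]")
  }

  with_seed(seed, {
    # --- fragment sampling: weight ROIs by length x copy ratio ------------
    w <- (rois$end - rois$start)
    if (!is.null(cnas) && nrow(cnas)) {
      m <- match(rois$gene, cnas$gene)
      ratio <- ifelse(is.na(m), 1, cnas$copy_ratio[m])
      if (any(ratio <= 0)) stopf("copy_ratio must be > 0")
      w <- w * ratio
    }
    # oversample fragments; not every fragment is captured
    n_frag <- ceiling(n_pairs * 1.6)

    draw_batch <- function(nf) {
      ri <- sample.int(nrow(rois), nf, replace = TRUE, prob = w)
      L <- pmax(fm$min_length, round(rnorm(nf, fm$mean_length, fm$sd)))
      # fragment must overlap its ROI
      fs <- floor(runif(nf, rois$start[ri] - L + 1, rois$end[ri] - 1))
      fe <- fs + L
      chrom <- rois$chrom[ri]
      fs <- pmax(fs, 0L); fe <- pmin(fe, glen[chrom])
      template <- sample(c("+", "-"), nf, replace = TRUE)
      out <- data.frame(chrom = chrom, f_start = as.integer(fs),
                        f_end = as.integer(fe), template = template,
                        stringsAsFactors = FALSE)
      out[out$f_end - out$f_start >= fm$min_length, , drop = FALSE]
    }

    frags <- draw_batch(n_frag)
    # --- capture: choose a probe site per fragment ------------------------
    pairs <- list()
    for (ch in unique(frags$chrom)) {
      for (tmpl in c("+", "-")) {
        sub <- frags[frags$chrom == ch & frags$template == tmpl, , drop = FALSE]
        if (!nrow(sub)) next
        pstrand <- if (tmpl == "+") "-" else "+"
        pr <- panel[panel$chrom == ch & panel$strand == pstrand, , drop = FALSE]
        if (!nrow(pr)) next
        pr <- pr[order(pr$anchor), , drop = FALSE]
        idx <- .pick_sites(sub$f_start, sub$f_end, pr$anchor,
                           pr$end - pr$start, tmpl, cm$capture_prob)
        ok <- !is.na(idx)
        if (!any(ok)) next
        sub <- sub[ok, , drop = FALSE]; idx <- idx[ok]
        sub$probe_id <- pr$id[idx]
        sub$anchor <- pr$anchor[idx]
        sub$plen <- pr$end[idx] - pr$start[idx]
        sub$roi_id <- pr$roi_id[idx]
        pairs[[length(pairs) + 1L]] <- sub
      }
    }
    if (!length(pairs)) stopf("no fragments captured; check panel/ROI overlap")
    pairs <- do.call(rbind, pairs)
    if (nrow(pairs) > n_pairs) pairs <- pairs[seq_len(n_pairs), , drop = FALSE]

    # molecule span in plus coordinates: probe footprint + extension insert
    plus_template <- pairs$template == "+"
    pairs$lig_end <- ifelse(plus_template, pairs$f_start, pairs$f_end - 1L)
    pairs$insert <- abs(pairs$anchor - pairs$lig_end)
    over <- pairs$insert > cm$max_insert
    if (any(over)) { # adapter end beyond max insert: clip the molecule
      pairs$lig_end[over] <- ifelse(plus_template[over],
                                    pairs$anchor[over] - cm$max_insert,
                                    pairs$anchor[over] + cm$max_insert)
      pairs$insert[over] <- cm$max_insert
    }
    pairs$m_start <- ifelse(plus_template, pairs$lig_end,
                            pairs$anchor - pairs$plen + 1L)
    pairs$m_end <- ifelse(plus_template, pairs$anchor + pairs$plen,
                          pairs$lig_end + 1L)

    # --- mispriming: a fraction of captures occur at random loci ----------
    pairs$on_target <- TRUE
    pairs$misprimed <- FALSE
    if (cm$mispriming_rate > 0) {
      mis <- which(runif(nrow(pairs)) < cm$mispriming_rate)
      if (length(mis)) {
        pairs$misprimed[mis] <- TRUE
        n_m <- length(mis)
        ch <- sample(names(genome), n_m, replace = TRUE)
        span <- pairs$m_end[mis] - pairs$m_start[mis]
        ms <- floor(runif(n_m, 0, glen[ch] - span))
        pairs$chrom[mis] <- ch
        pairs$m_start[mis] <- as.integer(ms)
        pairs$m_end[mis] <- as.integer(ms + span)
        # anchor / ligated end move with the misprimed locus
        plus_m <- plus_template[mis]
        pairs$anchor[mis] <- ifelse(plus_m, pairs$m_end[mis] - pairs$plen[mis],
                                    pairs$m_start[mis] + pairs$plen[mis] - 1L)
        pairs$lig_end[mis] <- ifelse(plus_m, pairs$m_start[mis],
                                     pairs$m_end[mis] - 1L)
        # a misprimed molecule is off-target unless it happens to land back
        # inside its probe's ROI (+/- flank), matching the QC definition
        ri <- match(pairs$roi_id[mis], rois$roi_id)
        lo <- rois$start[ri] - rois$flank[ri]
        hi <- rois$end[ri] + rois$flank[ri]
        pairs$on_target[mis] <- pairs$chrom[mis] == rois$chrom[ri] &
          pairs$m_start[mis] < hi & pairs$m_end[mis] > lo
      }
    }

    # --- molecule sequences (plus frame) ----------------------------------
    molseq <- character(nrow(pairs))
    for (ch in unique(pairs$chrom)) {
      i <- pairs$chrom == ch
      v <- Biostrings::Views(genome[[ch]], start = pairs$m_start[i] + 1L,
                             end = pairs$m_end[i])
      molseq[i] <- as.character(v)
    }

    # --- variants: per-molecule allele draws ------------------------------
    pairs$alleles <- ""
    if (!is.null(variants) && nrow(variants)) {
      for (vi in seq_len(nrow(variants))) {
        vv <- variants[vi, ]
        hit <- which(pairs$chrom == vv$chrom & pairs$on_target &
                       pairs$m_start <= vv$pos &
                       pairs$m_end >= vv$pos + nchar(vv$ref))
        if (!length(hit)) next
        carry <- hit[runif(length(hit)) < vv$vaf]
        if (!length(carry)) next
        off <- vv$pos - pairs$m_start[carry] + 1L
        molseq[carry] <- vapply(seq_along(carry), function(j) {
          s <- molseq[carry[j]]
          paste0(substr(s, 1L, off[j] - 1L), vv$alt,
                 substr(s, off[j] + nchar(vv$ref), nchar(s)))
        }, "")
        pairs$alleles[carry] <- paste0(pairs$alleles[carry],
                                       ifelse(nzchar(pairs$alleles[carry]), ";", ""),
                                       sprintf("%s:%d:%s>%s", vv$chrom, vv$pos,
                                               vv$ref, vv$alt))
      }
    }

    # --- FFPE deamination on the template strand --------------------------
    # The probe part of the molecule is a pristine synthetic oligo; only the
    # extension region copies (possibly damaged) template bases.
    pairs$damage <- ""
    if (ffpe$deamination_rate > 0) {
      tmpl_base <- ifelse(pairs$template == "+", "C", "G") # plus-frame base
      for (i in seq_len(nrow(pairs))) {
        s <- molseq[i]
        len_i <- nchar(s)
        cpos <- which(strsplit(s, "", fixed = TRUE)[[1L]] == tmpl_base[i])
        cpos <- if (pairs$template[i] == "+") cpos[cpos <= len_i - pairs$plen[i]]
        else cpos[cpos > pairs$plen[i]]
        if (!length(cpos)) next
        dmg <- cpos[runif(length(cpos)) < ffpe$deamination_rate]
        if (!length(dmg)) next
        if (ffpe$repair == "off") {
          # template C read as T: plus-frame C>T (+) or G>A (-)
          to <- if (pairs$template[i] == "+") "T" else "A"
          b <- strsplit(s, "", fixed = TRUE)[[1L]]
          b[dmg] <- to
          molseq[i] <- paste(b, collapse = "")
          pairs$damage[i] <- paste(dmg + pairs$m_start[i], collapse = ";")
        } else {
          # excision only: synthesis terminates at the damaged base nearest
          # the probe; the molecule is truncated on the adapter side
          if (pairs$template[i] == "+") {
            # probe at the right end of the molecule, adapter at the left
            cut <- max(dmg)
            molseq[i] <- substr(s, cut + 1L, nchar(s))
            pairs$m_start[i] <- pairs$m_start[i] + cut
            pairs$lig_end[i] <- pairs$m_start[i]
          } else {
            cut <- min(dmg)
            molseq[i] <- substr(s, 1L, cut - 1L)
            pairs$m_end[i] <- pairs$m_start[i] + cut - 1L
            pairs$lig_end[i] <- pairs$m_end[i] - 1L
          }
          pairs$insert[i] <- abs(pairs$anchor[i] - pairs$lig_end[i])
          pairs$damage[i] <- paste0("X", cut + pairs$m_start[i])
        }
      }
      # drop molecules truncated into the probe footprint
      keep <- nchar(molseq) > pairs$plen
      pairs <- pairs[keep, , drop = FALSE]; molseq <- molseq[keep]
    }

    # --- reads -------------------------------------------------------------
    plus_template <- pairs$template == "+" # rows may have been dropped above
    mol_len <- nchar(molseq)
    l1 <- pmin(read_length, mol_len)
    l2 <- pmin(read_length, mol_len)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(molseq)))
    # plus template: probe (minus strand) at right; R1 reads leftward (rc),
    # R2 from adapter at left reads plus strand
    r1 <- ifelse(plus_template, substr(rc, 1L, l1), substr(molseq, 1L, l1))
    r2 <- ifelse(plus_template, substr(molseq, 1L, l2), substr(rc, 1L, l2))
    # misprimed molecules still begin with the synthetic probe sequence
    if (any(pairs$misprimed)) {
      mi <- which(pairs$misprimed)
      pseq <- panel$sequence[match(pairs$probe_id[mi], panel$id)]
      substr(r1[mi], 1L, pairs$plen[mi]) <- pseq
    }
    pairs$r1_strand <- ifelse(plus_template, "-", "+")
    pairs$r2_strand <- ifelse(plus_template, "+", "-")
    pairs$r1_start <- ifelse(plus_template, pairs$m_end - l1, pairs$m_start)
    pairs$r1_end <- ifelse(plus_template, pairs$m_end, pairs$m_start + l1)
    pairs$r2_start <- ifelse(plus_template, pairs$m_start, pairs$m_end - l2)
    pairs$r2_end <- ifelse(plus_template, pairs$m_start + l2, pairs$m_end)

    # --- sequencing errors -------------------------------------------------
    if (seq_error > 0) {
      inject <- function(reads) {
        nb <- nchar(reads)
        ne <- rbinom(1L, sum(nb), seq_error)
        if (ne == 0L) return(reads)
        ri <- sample.int(length(reads), ne, replace = TRUE, prob = nb)
        po <- ceiling(runif(ne) * nb[ri])
        for (j in seq_len(ne)) {
          cur <- substr(reads[ri[j]], po[j], po[j])
          substr(reads[ri[j]], po[j], po[j]) <-
            sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
        reads
      }
      r1 <- inject(r1); r2 <- inject(r2)
    }
    pairs$r1_seq <- r1
    pairs$r2_seq <- r2
    pairs$r1_qual <- strrep("?", l1) # constant Q30
    pairs$r2_qual <- strrep("?", l2)
    pairs$pair_id <- sprintf("osseq:%d:%06d", seed, seq_len(nrow(pairs)))
    pairs$duplicate_of <- NA_character_

    # --- PCR duplicates ----------------------------------------------------
    if (cm$duplicate_rate > 0 && nrow(pairs)) {
      dup <- which(runif(nrow(pairs)) < cm$duplicate_rate)
      if (length(dup)) {
        d <- pairs[dup, , drop = FALSE]
        d$duplicate_of <- d$pair_id
        d$pair_id <- sprintf("osseq:%d:dup%06d", seed, seq_along(dup))
        pairs <- rbind(pairs, d)
      }
    }
    rownames(pairs) <- NULL
    structure(list(pairs = pairs, variants = variants, cnas = cnas,
                   panel = panel, rois = rois, genome = genome,
                   models = list(fragment = fm, ffpe = ffpe, capture = cm),
                   read_length = read_length, seq_error = seq_error,
                   seed = seed),
              class = "osseq_sim")
  })
}

#' Write all simulator outputs to a directory
#'
#' Emits R1/R2 FASTQ (gzipped), a truth SAM, a truth TSV and a truth VCF.
#'
#' @param sim An `osseq_sim` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named vector of paths, invisibly.
#' @export
write_sim_outputs <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, paste0(prefix, x))
  write_fastq_pair(sim$pairs, f("_R1.fastq.gz"), f("_R2.fastq.gz"))
  write_truth_sam(sim$pairs, sim$genome, f("_truth.sam"))
  tsv_cols <- c("pair_id", "probe_id", "chrom", "template", "anchor", "lig_end",
                "insert", "m_start", "m_end", "r1_start", "r1_end", "r1_strand",
                "r2_start", "r2_end", "r2_strand", "roi_id", "on_target",
                "alleles", "damage", "duplicate_of")
  write.table(sim$pairs[, tsv_cols], f("_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$variants) && nrow(sim$variants))
    write_variants_vcf(sim$variants, f("_truth.vcf"))
  invisible(c(r1 = f("_R1.fastq.gz"), r2 = f("_R2.fastq.gz"),
              sam = f("_truth.sam"), tsv = f("_truth.tsv"),
              vcf = f("_truth.vcf")))
}

#' Simulate a per-ROI coverage matrix
#'
#' Direct negative-binomial simulation of ROI read depths for copy-number
#' experiments: sample columns share a per-ROI capture-efficiency bias, and
#' depths of ROIs in genes under a CNA spec are scaled by the copy ratio in
#' the non-control samples.
#'
#' @param n_genes Number of genes.
#' @param rois_per_gene ROIs per gene.
#' @param mean_depth Baseline mean ROI depth.
#' @param dispersion Negative-binomial size parameter (`Inf` = Poisson).
#' @param cnas Optional data.frame `gene, copy_ratio` applied to test
#'   samples. Gene labels follow `sprintf("GENE%03d", i)`.
#' @param seed Integer seed.
#' @param n_samples Total sample columns.
#' @param control_cols Indices of control (diploid) columns the CNA spec
#'   does not touch.
#' @param roi_bias_sd SD of the log-normal per-ROI bias shared by all
#'   samples (region-specific capture efficiency).
#' @return List with `rois` (roi_id, gene) and `depth` matrix
#'   (ROI x sample).
#' @export
simulate_roi_coverage <- function(n_genes, rois_per_gene = 2L, mean_depth = 500,
                                  dispersion = 20, cnas = NULL, seed = 1L,
                                  n_samples = 2L, control_cols = 1L,
                                  roi_bias_sd = 0.3) {
  if (mean_depth <= 0) stopf("mean_depth must be > 0")
  with_seed(seed, {
    n_roi <- n_genes * rois_per_gene
    gene <- rep(sprintf("GENE%03d", seq_len(n_genes)), each = rois_per_gene)
    roi_id <- sprintf("%s_roi%d", gene, rep(seq_len(rois_per_gene), n_genes))
    bias <- exp(rnorm(n_roi, 0, roi_bias_sd))
    ratio <- rep(1, n_roi)
    if (!is.null(cnas) && nrow(cnas)) {
      m <- match(gene, cnas$gene)
      ratio <- ifelse(is.na(m), 1, cnas$copy_ratio[m])
      if (any(ratio <= 0)) stopf("copy_ratio must be > 0")
    }
    depth <- matrix(0, n_roi, n_samples,
                    dimnames = list(roi_id, sprintf("sample%d", seq_len(n_samples))))
    for (s in seq_len(n_samples)) {
      mu <- mean_depth * bias * if (s %in% control_cols) 1 else ratio
      depth[, s] <- if (is.infinite(dispersion)) rpois(n_roi, mu)
      else rnbinom(n_roi, mu = mu, size = dispersion)
    }
    list(rois = data.frame(roi_id = roi_id, gene = gene, stringsAsFactors = FALSE),
         depth = depth)
  })
}

#' Simulate gene-level log2 ratios with spiked copy-number events
#'
#' Gene-level log2 ratio noise is drawn from N(0, `noise_sd`) and the named
#' spike genes receive their log2 ratios on top — the reference scenario
#' being a 130-gene panel with three amplified genes at expected ratios
#' 4.90, 2.25 and 1.32 (log2 2.29, 1.17, 0.40) over N(0, 0.05) noise.
#'
#' @param n_genes Number of genes.
#' @param noise_sd SD of the null log2 ratios.
#' @param spikes Named numeric vector of log2 ratios, names = gene indices
#'   or labels (default three amplifications at log2 2.29, 1.17, 0.40).
#' @param seed Integer seed.
#' @return data.frame `gene, log2_ratio, spiked`.
#' @export
simulate_gene_ratios <- function(n_genes = 130L, noise_sd = 0.05,
                                 spikes = c(GENE001 = 2.29, GENE002 = 1.17,
                                            GENE003 = 0.40),
                                 seed = 1L) {
  with_seed(seed, {
    gene <- sprintf("GENE%03d", seq_len(n_genes))
    x <- rnorm(n_genes, 0, noise_sd)
    m <- match(names(spikes), gene)
    if (any(is.na(m))) stopf("spike gene label not present")
    x[m] <- x[m] + unname(spikes)
    data.frame(gene = gene, log2_ratio = x, spiked = seq_len(n_genes) %in% m,
               stringsAsFactors = FALSE)
  })
}
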