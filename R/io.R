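#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("reference FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a reference genome to FASTA
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(read_genome(genome))
  if (is.character(genome)) return(Biostrings::DNAStringSet(genome))
  genome
}

#' Read regions of interest from a BED file
#'
#' Expects 4+ columns: chrom, start, end, gene (BED: 0-based, half-open).
#' An optional 5th numeric column is interpreted as the per-ROI flank (bp)
#' used to enlarge intervals for variant calling; otherwise `flank` applies.
#'
#' @param path Path to a BED file.
#' @param flank Default flank in bp added on each side for variant-calling
#'   intervals (the ROI coordinates themselves are not modified).
#' @return A data.frame with columns `chrom, start, end, gene, roi_id, flank`.
#' @export
read_rois <- function(path, flank = 50L) {
  if (!file.exists(path)) stopf("ROI BED not found: %s", path)
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 4L) stopf("ROI BED needs >= 4 columns (chrom,start,end,gene): %s", path)
  rois <- data.frame(chrom = as.character(x[[1L]]), start = as.integer(x[[2L]]),
                     end = as.integer(x[[3L]]), gene = as.character(x[[4L]]),
                     stringsAsFactors = FALSE)
  rois$flank <- if (ncol(x) >= 5L && is.numeric(x[[5L]])) as.integer(x[[5L]]) else as.integer(flank)
  validate_rois(rois)
}

#' Write ROIs as BED
#' @param rois ROI data.frame (see [read_rois()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  write.table(rois[, c("chrom", "start", "end", "gene", "flank")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_rois <- function(rois) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(rois)))
  if (any(rois$end <= rois$start)) stopf("ROI with end <= start")
  if (is.null(rois$flank)) rois$flank <- 50L
  if (any(rois$flank < 0L)) stopf("negative ROI flank")
  rois <- rois[order(rois$chrom, rois$start), , drop = FALSE]
  # merge overlapping ROIs within a chromosome so the panel universe is
  # sorted and non-self-overlapping
  out <- do.call(rbind, lapply(split(rois, rois$chrom), function(d) {
    keep <- list(); cur <- d[1L, ]
    if (nrow(d) > 1L) for (i in 2L:nrow(d)) {
      if (d$start[i] < cur$end) {
        cur$end <- max(cur$end, d$end[i])
      } else { keep[[length(keep) + 1L]] <- cur; cur <- d[i, ] }
    }
    keep[[length(keep) + 1L]] <- cur
    do.call(rbind, keep)
  }))
  rownames(out) <- NULL
  if (is.null(out$roi_id)) out$roi_id <- sprintf("roi%04d", seq_len(nrow(out)))
  out
}

#' Read a probe panel metadata TSV
#'
#' The panel TSV is the probe metadata file consumed by the QC module:
#' columns `id, chrom, start, end, strand, anchor, sequence, roi_id, gene,
#' score, tm` (0-based half-open probe footprint; `anchor` is the 0-based
#' position of the probe 3' extension start).
#'
#' @param path Path to the TSV.
#' @return The panel data.frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("panel metadata file not found: %s", path)
  p <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "strand", "anchor", "sequence", "roi_id")
  miss <- setdiff(need, names(p))
  if (length(miss)) stopf("panel TSV missing columns: %s", paste(miss, collapse = ", "))
  p
}

#' Write a probe panel (TSV and optional FASTA)
#' @param panel Panel data.frame.
#' @param path Output TSV path.
#' @param fasta Optional output FASTA path for probe sequences.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, fasta = NULL) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    s <- Biostrings::DNAStringSet(setNames(panel$sequence, panel$id))
    Biostrings::writeXStringSet(s, fasta, width = 70L)
  }
  invisible(path)
}

#' Read variants from a VCF file or pass through a variant data.frame
#'
#' File input is parsed with \pkg{vcfR}. The in-package variant
#' representation is a data.frame with columns
#' `chrom, pos (0-based), ref, alt, vaf, origin`.
#'
#' @param x A VCF path or a variant data.frame.
#' @return Variant data.frame.
#' @export
read_variants <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
    if (is.null(x$vaf)) x$vaf <- NA_real_
    if (is.null(x$origin)) x$origin <- NA_character_
    return(x)
  }
  if (!file.exists(x)) stopf("VCF not found: %s", x)
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(x, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- vcfR::extract.info(v, "VAF")
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
               ref = fix$REF, alt = fix$ALT,
               vaf = suppressWarnings(as.numeric(info)),
               origin = NA_character_, stringsAsFactors = FALSE)
  } else {
    ln <- readLines(x)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    bad <- which(vapply(f, length, 1L) < 8L)
    if (length(bad)) stopf("malformed VCF line %d in %s", bad[1L], x)
    vaf <- vapply(f, function(z) {
      m <- regmatches(z[8L], regexec("VAF=([0-9.eE+-]+)", z[8L]))[[1L]]
      if (length(m) == 2L) as.numeric(m[2L]) else NA_real_
    }, 0)
    data.frame(chrom = vapply(f, `[`, "", 1L),
               pos = as.integer(vapply(f, `[`, "", 2L)) - 1L,
               ref = vapply(f, `[`, "", 4L), alt = vapply(f, `[`, "", 5L),
               vaf = vaf, origin = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Write variants as a minimal VCF
#' @param variants Variant data.frame (0-based `pos`).
#' @param path Output path.
#' @param sample_name Sample label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, sample_name = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=osseqtools"),
           sprintf("##sample=%s", sample_name),
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Simulated or estimated variant allelic fraction\">",
           "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"germline or somatic\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("VAF=%s%s",
                  ifelse(is.na(variants$vaf), ".", format(variants$vaf, trim = TRUE)),
                  ifelse(is.na(variants$origin %||% NA), "",
                         paste0(";ORIGIN=", variants$origin)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, variants$pos + 1L, variants$ref, variants$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write paired reads as FASTQ (R1/R2)
#' @param pairs Simulated pair table (see [simulate_library()]).
#' @param r1_path,r2_path Output FASTQ paths (".gz" suffix compresses).
#' @return `c(r1_path, r2_path)`, invisibly.
#' @export
write_fastq_pair <- function(pairs, r1_path, r2_path) {
  wr <- function(ids, seqs, quals, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    q <- Biostrings::BStringSet(quals)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = endsWith(path, ".gz"))
  }
  wr(paste0(pairs$pair_id, "/1"), pairs$r1_seq, pairs$r1_qual, r1_path)
  wr(paste0(pairs$pair_id, "/2"), pairs$r2_seq, pairs$r2_qual, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a FASTQ file into sequences and qualities
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with `id, seq, qual`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write simulator truth alignments as SAM
#'
#' Emits one SAM record per read with the simulator's alignment coordinates,
#' so downstream QC can run without an external aligner.
#'
#' @param pairs Simulated pair table.
#' @param genome Reference genome (for `@SQ` lines).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(pairs, genome, path) {
  genome <- as_genome(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)),
           "@PG\tID:osseqtools\tPN:osseqtools")
  flag1 <- 0x1 + 0x2 + 0x40 + ifelse(pairs$r1_strand == "-", 0x10, 0) +
    ifelse(pairs$r2_strand == "-", 0x20, 0)
  flag2 <- 0x1 + 0x2 + 0x80 + ifelse(pairs$r2_strand == "-", 0x10, 0) +
    ifelse(pairs$r1_strand == "-", 0x20, 0)
  rec <- function(id, flag, chrom, pos, seq, qual, mpos, probe) {
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t0\t%s\t%s\tXP:Z:%s",
            id, flag, chrom, pos + 1L, nchar(seq), mpos + 1L, seq, qual, probe)
  }
  l1 <- rec(pairs$pair_id, flag1, pairs$chrom, pairs$r1_start, pairs$r1_seq,
            pairs$r1_qual, pairs$r2_start, pairs$probe_id)
  l2 <- rec(pairs$pair_id, flag2, pairs$chrom, pairs$r2_start, pairs$r2_seq,
            pairs$r2_qual, pairs$r1_start, pairs$probe_id)
  writeLines(c(hdr, as.vector(rbind(l1, l2))), path)
  invisible(path)
}

#' Read a coverage matrix TSV (roi_id, gene, one column per sample)
#' @param path TSV path.
#' @return List with `rois` (roi_id, gene) and `depth` numeric matrix.
#' @export
read_coverage_tsv <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("roi_id", "gene") %in% names(x)))
  depth <- as.matrix(x[, setdiff(names(x), c("roi_id", "gene")), drop = FALSE])
  rownames(depth) <- x$roi_id
  list(rois = x[, c("roi_id", "gene")], depth = depth)
}

#' Write a coverage matrix TSV
#' @param rois data.frame with `roi_id, gene`.
#' @param depth Numeric matrix (ROI x sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(rois, depth, path) {
  out <- cbind(rois[, c("roi_id", "gene")], as.data.frame(depth))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
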