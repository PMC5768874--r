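# Read-depth copy-number calling: median normalization, ROI- then
# gene-level log2 ratios against a diploid control, and iterative
# Thompson-Tau outlier flagging.

#' Thompson-Tau test configuration
#'
#' @param alpha Two-tailed significance level of the t quantile.
#' @param df Degrees of freedom for the t quantile; `NULL` (default) uses
#'   n-1 recomputed with the current number of unflagged values at each
#'   iteration.
#' @param t_critical Optional explicit critical t value overriding the
#'   quantile (e.g. to reproduce a published value exactly).
#' @param max_iterations Cap on remove-and-recompute iterations.
#' @return List of class `tau_config`.
#' @export
tau_config <- function(alpha = 0.01, df = NULL, t_critical = NULL,
                       max_iterations = 100L) {
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0,1)")
  structure(list(alpha = alpha, df = df, t_critical = t_critical,
                 max_iterations = as.integer(max_iterations)),
            class = "tau_config")
}

#' Median-normalize ROI depths
#'
#' Divides each ROI depth by the sample's own median across all ROIs, so
#' the median of the normalized vector is 1 and overall sequencing depth
#' cancels between samples.
#'
#' @param depths Numeric vector (one sample) or matrix (ROI x sample).
#' @return Normalized vector/matrix.
#' @export
normalize_depths <- function(depths) {
  if (is.matrix(depths)) return(apply(depths, 2L, normalize_depths))
  m <- median(depths)
  if (!is.finite(m) || m <= 0)
    stopf("median depth is zero; cannot median-normalize")
  depths / m
}

#' Per-ROI log2 ratios of test versus control
#'
#' @param test_norm,control_norm Median-normalized depth vectors aligned on
#'   the same ROI set.
#' @return Numeric vector of log2(test/control); ROIs with a zero control
#'   (or test) depth are masked to `NA` with a warning.
#' @export
log2_ratios <- function(test_norm, control_norm) {
  stopifnot(length(test_norm) == length(control_norm))
  bad <- control_norm <= 0 | test_norm <= 0
  out <- rep(NA_real_, length(test_norm))
  out[!bad] <- log2(test_norm[!bad] / control_norm[!bad])
  if (any(bad))
    warning(sprintf("%d ROI(s) masked (zero depth in test or control)", sum(bad)))
  out
}

#' Aggregate ROI log2 ratios to the gene level
#'
#' Gene value = median of the gene's ROI log2 ratios (robust to single-ROI
#' artifacts), eliminating region-specific biases before outlier testing.
#'
#' @param roi_ratios Per-ROI log2 ratios.
#' @param gene Gene label per ROI.
#' @return data.frame `gene, log2_ratio, n_roi`.
#' @export
aggregate_gene <- function(roi_ratios, gene) {
  stopifnot(length(roi_ratios) == length(gene))
  sp <- split(roi_ratios, gene)
  data.frame(gene = names(sp),
             log2_ratio = vapply(sp, function(x) median(x, na.rm = TRUE), 0),
             n_roi = vapply(sp, function(x) sum(!is.na(x)), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Iterative Thompson-Tau outlier detection
#'
#' At each iteration the mean and SD of the currently unflagged values are
#' computed; the rejection threshold is
#' `tau = t (n-1) / (sqrt(n) sqrt(n-2+t^2))` with `t` the two-tailed
#' `alpha` quantile of the t distribution, and the single most deviant
#' value is flagged if `|x - mean| / SD > tau`. Flagging repeats until no
#' value exceeds tau (or SD collapses). Iteration is essential: a modest
#' event is masked by the SD inflation caused by larger events in a single
#' pass.
#'
#' @param x Numeric vector (e.g. gene-level log2 ratios), n >= 3.
#' @param config A [tau_config()].
#' @return List with `flagged` (logical), `iteration` (flagging iteration
#'   per value, NA if unflagged) and `trace` (per-iteration decisions).
#' @export
thompson_tau_outliers <- function(x, config = tau_config()) {
  n0 <- length(x)
  if (n0 < 3L) stopf("Thompson-Tau test needs n >= 3")
  flagged <- rep(FALSE, n0)
  iteration <- rep(NA_integer_, n0)
  trace <- list()
  for (it in seq_len(config$max_iterations)) {
    idx <- which(!flagged)
    n <- length(idx)
    if (n < 3L) break
    mu <- mean(x[idx]); s <- sd(x[idx])
    if (!is.finite(s) || s == 0) break
    tcrit <- if (!is.null(config$t_critical)) config$t_critical
    else qt(1 - config$alpha / 2, df = config$df %||% (n - 1L))
    tau <- tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2 + tcrit^2))
    dev <- abs(x[idx] - mu) / s
    j <- which.max(dev)
    hit <- dev[j] > tau
    trace[[it]] <- data.frame(iteration = it, n = n, mean = mu, sd = s,
                              t = tcrit, tau = tau, candidate = idx[j],
                              deviation = dev[j], flagged = hit)
    if (!hit) break
    flagged[idx[j]] <- TRUE
    iteration[idx[j]] <- it
  }
  list(flagged = flagged, iteration = iteration,
       trace = do.call(rbind, trace))
}

#' Call copy-number alterations from ROI coverage
#'
#' Full read-depth pipeline: median normalization of test and control,
#' per-ROI then per-gene log2 ratios, iterative Thompson-Tau flagging of
#' gene ratios, and back-transformed per-gene copy ratios with direction.
#'
#' @param test_depth,control_depth Raw ROI depth vectors on a shared ROI
#'   universe.
#' @param gene Gene label per ROI.
#' @param config A [tau_config()].
#' @param level `"gene"` (default) tests gene-aggregated ratios;
#'   `"roi"` tests ROI-level ratios directly.
#' @return List of class `cna_result`: `calls` data.frame (`gene,
#'   log2_ratio, ratio, direction, flagged, iteration`), `roi` table and
#'   the tau `trace`.
#' @export
call_cnas <- function(test_depth, control_depth, gene, config = tau_config(),
                      level = c("gene", "roi")) {
  level <- match.arg(level)
  stopifnot(length(test_depth) == length(control_depth),
            length(gene) == length(test_depth))
  tn <- normalize_depths(test_depth)
  cn <- normalize_depths(control_depth)
  rr <- suppressWarnings(log2_ratios(tn, cn))
  roi_tab <- data.frame(gene = gene, test_norm = tn, control_norm = cn,
                        log2_ratio = rr, stringsAsFactors = FALSE)
  if (level == "gene") {
    gtab <- aggregate_gene(rr, gene)
  } else {
    gtab <- data.frame(gene = gene, log2_ratio = rr, n_roi = 1L,
                       stringsAsFactors = FALSE)
  }
  usable <- is.finite(gtab$log2_ratio)
  tt <- thompson_tau_outliers(gtab$log2_ratio[usable], config)
  gtab$flagged <- FALSE; gtab$iteration <- NA_integer_
  gtab$flagged[usable] <- tt$flagged
  gtab$iteration[usable] <- tt$iteration
  gtab$ratio <- 2^gtab$log2_ratio
  gtab$direction <- ifelse(gtab$log2_ratio > 0, "amplification", "deletion")
  gtab$direction[!gtab$flagged] <- "neutral"
  calls <- gtab[, c("gene", "log2_ratio", "ratio", "direction", "flagged",
                    "iteration", "n_roi")]
  structure(list(calls = calls, roi = roi_tab, trace = tt$trace,
                 config = config, level = level),
            class = "cna_result")
}

#' Write CNA calls and trace as TSV
#' @param result A `cna_result`.
#' @param path Output TSV for calls.
#' @param trace_path Optional output TSV for the per-iteration trace.
#' @return `path`, invisibly.
#' @export
write_cna_calls <- function(result, path, trace_path = NULL) {
  write.table(result$calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trace_path) && !is.null(result$trace))
    write.table(result$trace, trace_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
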