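# Shared fixtures (built once per file) and independent oracle
# implementations used to cross-check the package's computations.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- builder()
  .fix_cache[[key]]
}

fix_small_ref <- function() cached("small_ref", function()
  make_reference(6, 2, 300, seed = 101, intergenic_len = 1500))

fix_small_panel <- function() cached("small_panel", function()
  design_panel(fix_small_ref()$rois, fix_small_ref()$genome)$panel)

fix_grid_world <- function() cached("grid_world", function() {
  ref <- make_reference(4, 1, 500, seed = 202)
  list(ref = ref, panel = panel_from_grid(ref$rois, ref$genome, 100, 25))
})

# ---- independent oracles -------------------------------------------------

# Nearest-neighbor duplex melting temperature, summed by explicit loop over
# an independently transcribed unified parameter table.
oracle_tm <- function(seq, na_molar = 0.05, conc = 2.5e-7) {
  tab <- list(AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), AC = c(-8.4, -22.4),
              AG = c(-7.8, -21.0), TA = c(-7.2, -21.3), TT = c(-7.9, -22.2),
              TC = c(-8.2, -22.2), TG = c(-8.5, -22.7), CA = c(-8.5, -22.7),
              CT = c(-7.8, -21.0), CC = c(-8.0, -19.9), CG = c(-10.6, -27.2),
              GA = c(-8.2, -22.2), GT = c(-8.4, -22.4), GC = c(-9.8, -24.4),
              GG = c(-8.0, -19.9))
  dh <- 0; ds <- 0
  for (i in seq_len(nchar(seq) - 1L)) {
    v <- tab[[substr(seq, i, i + 1L)]]
    dh <- dh + v[1L]; ds <- ds + v[2L]
  }
  for (end in c(substr(seq, 1L, 1L), substr(seq, nchar(seq), nchar(seq)))) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (nchar(seq) - 1L) * log(na_molar)
  1000 * dh / (ds + 1.9872 * log(conc / 4)) - 273.15
}

# fold 80 base penalty by explicit sort-and-index.
oracle_fold80 <- function(cov) {
  nz <- sort(cov[cov > 0])
  mean(nz) / nz[ceiling(0.2 * length(nz))]
}

# Iterative Thompson-Tau flagging, written independently (full rescan per
# iteration, two-tailed t quantile at df = n - 1).
oracle_tau <- function(x, alpha = 0.01) {
  flagged <- rep(FALSE, length(x))
  repeat {
    keep <- x[!flagged]
    n <- length(keep)
    if (n < 3L) break
    s <- sd(keep)
    if (!is.finite(s) || s == 0) break
    t <- qt(1 - alpha / 2, n - 1L)
    tau <- t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))
    dev <- abs(x - mean(keep)) / s
    dev[flagged] <- -Inf
    if (max(dev) <= tau) break
    flagged[which.max(dev)] <- TRUE
  }
  flagged
}

# Longest 3'-terminal complementarity run by exhaustive enumeration of
# annealing registers.
oracle_comp_run <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  na <- length(av); nb <- length(bv)
  best <- 0L
  for (off in seq_len(nb)) { # a's 3' base pairs with b[off]
    r <- 0L
    while (na - r >= 1L && off + r <= nb &&
           comp[[av[na - r]]] == bv[off + r]) r <- r + 1L
    best <- max(best, r)
  }
  best
}
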