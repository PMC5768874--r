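# ddPCR-derived quantification arithmetic: genome-equivalent mass
# conversion, adapter ligation efficiency, reference-normalized copy
# ratios, and library pooling volumes.

#' Quantification configuration
#' @param ng_per_10k_copies Mass of 10,000 genome-equivalent copies in ng
#'   (30 ng per 10,000 copies for human genomic DNA).
#' @param pooling_target Total library fragments targeted when pooling.
#' @param dilution Dilution factor applied to libraries before ddPCR
#'   quantification (bookkeeping only).
#' @return List of class `quant_config`.
#' @export
quant_config <- function(ng_per_10k_copies = 30, pooling_target = 1.2e9,
                         dilution = 1e-6) {
  if (ng_per_10k_copies <= 0 || pooling_target <= 0)
    stopf("quantification constants must be > 0")
  structure(list(ng_per_10k_copies = ng_per_10k_copies,
                 pooling_target = pooling_target, dilution = dilution),
            class = "quant_config")
}

#' Convert genome-equivalent copies to mass
#' @param copies Number of genome-equivalent copies (>= 0).
#' @param config A [quant_config()].
#' @return Mass in ng.
#' @export
copies_to_ng <- function(copies, config = quant_config()) {
  if (any(copies < 0)) stopf("copies must be >= 0")
  copies * config$ng_per_10k_copies / 1e4
}

#' Convert mass to genome-equivalent copies
#' @param ng Mass in ng (>= 0).
#' @param config A [quant_config()].
#' @return Number of copies.
#' @export
ng_to_copies <- function(ng, config = quant_config()) {
  if (any(ng < 0)) stopf("mass must be >= 0")
  ng * 1e4 / config$ng_per_10k_copies
}

#' Adapter ligation efficiency
#'
#' Efficiency = (2 x ligation assay copies) / control assay copies: the
#' adapter-specific assay only yields signal from one strand, while the
#' control locus assay yields product from both.
#'
#' @param ligated_copies Copies/uL from the adapter-junction assay.
#' @param control_copies Copies/uL from the control locus assay (> 0).
#' @return Fraction; values > 1 trigger a measurement-inconsistency
#'   warning (not an error).
#' @export
ligation_efficiency <- function(ligated_copies, control_copies) {
  if (any(control_copies <= 0)) stopf("control copies must be > 0")
  if (any(ligated_copies < 0)) stopf("ligated copies must be >= 0")
  eff <- 2 * ligated_copies / control_copies
  if (any(eff > 1))
    warning("ligation efficiency > 1: inconsistent ddPCR measurements")
  eff
}

#' Reference-normalized copy ratio between two samples
#'
#' The target assay is first normalized to the reference assay within each
#' sample, then the normalized target values are compared test versus
#' control: `(target/ref)_test / (target/ref)_control`. Invariant to
#' rescaling both channels of one sample by a common factor.
#'
#' @param target_test,ref_test Copies/uL in the test sample.
#' @param target_control,ref_control Copies/uL in the control sample.
#' @return Ratio (1 = no copy-number difference).
#' @export
normalized_copy_ratio <- function(target_test, ref_test,
                                  target_control, ref_control) {
  vals <- c(target_test, ref_test, target_control, ref_control)
  if (any(vals <= 0)) stopf("all four ddPCR measurements must be > 0")
  (target_test / ref_test) / (target_control / ref_control)
}

#' Library pooling volumes
#'
#' Computes per-library volumes delivering an equal share of the pooling
#' target given each library's fragment concentration.
#'
#' @param fragments_per_ul Named vector of library fragment concentrations
#'   (fragments/uL, from linkage-corrected ddPCR).
#' @param config A [quant_config()].
#' @return data.frame `library, fragments_per_ul, target_fragments,
#'   volume_ul`.
#' @export
pool_volumes <- function(fragments_per_ul, config = quant_config()) {
  if (any(fragments_per_ul <= 0)) stopf("fragment concentrations must be > 0")
  n <- length(fragments_per_ul)
  share <- config$pooling_target / n
  data.frame(library = names(fragments_per_ul) %||% paste0("lib", seq_len(n)),
             fragments_per_ul = as.numeric(fragments_per_ul),
             target_fragments = share,
             volume_ul = share / as.numeric(fragments_per_ul),
             row.names = NULL, stringsAsFactors = FALSE)
}
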