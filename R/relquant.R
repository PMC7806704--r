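#' Ct table for relative quantification
#'
#' Long-format quantification-cycle (Ct) records for the 2^-ddCt method.
#' Technical replicates (duplicate (sample, target) rows) are averaged on
#' the Ct scale at construction.
#'
#' @param data data frame with columns \code{sample_id}, \code{target_id},
#'   \code{ct} (numeric cycles).
#' @param normalizer_target id of the normalizer assay (e.g. the
#'   total-bacteria 27F/519R 16S assay).
#' @param reference_sample id of the control sample each target is
#'   expressed relative to.
#' @return a data frame of class \code{"ct_table"} with attributes
#'   \code{normalizer_target} and \code{reference_sample}.
#' @export
ct_table <- function(data, normalizer_target, reference_sample) {
  need <- c("sample_id", "target_id", "ct")
  if (!all(need %in% names(data)))
    stop("ct data must have columns ", paste(need, collapse = ", "))
  if (!is.numeric(data$ct) || any(!is.finite(data$ct)))
    stop("ct values must be finite numbers")
  agg <- stats::aggregate(ct ~ sample_id + target_id,
                          data = as.data.frame(data), FUN = mean)
  agg$sample_id <- as.character(agg$sample_id)
  agg$target_id <- as.character(agg$target_id)
  if (!normalizer_target %in% agg$target_id)
    stop("normalizer target '", normalizer_target, "' absent from table")
  if (!reference_sample %in% agg$sample_id)
    stop("reference sample '", reference_sample, "' absent from table")
  structure(agg,
            normalizer_target = normalizer_target,
            reference_sample = reference_sample,
            class = c("ct_table", "data.frame"))
}

#' Relative quantification by the 2^-ddCt method
#'
#' For each sample \eqn{s}: \eqn{\Delta Ct_s = Ct_{target,s} -
#' Ct_{normalizer,s}}, \eqn{\Delta\Delta Ct_s = \Delta Ct_s - \Delta
#' Ct_{reference}}, fold change \eqn{2^{-\Delta\Delta Ct_s}}. The reference
#' sample maps to exactly 1. Amplification efficiency is fixed at 2.
#'
#' Fold changes are relative to the chosen reference sample within one
#' target; no cross-target (absolute) comparison is implied.
#'
#' @param table a \code{\link{ct_table}}.
#' @param target target assay id to quantify.
#' @return named numeric vector of strictly positive fold changes, one per
#'   sample with a Ct for \code{target}.
#' @export
delta_delta_ct <- function(table, target) {
  if (!inherits(table, "ct_table")) stop("table must be a ct_table")
  normalizer <- attr(table, "normalizer_target")
  reference <- attr(table, "reference_sample")
  tt <- table[table$target_id == target, , drop = FALSE]
  if (!nrow(tt)) stop("no Ct records for target '", target, "'")
  samples <- tt$sample_id
  norm <- table[table$target_id == normalizer, , drop = FALSE]
  missing_norm <- setdiff(samples, norm$sample_id)
  if (length(missing_norm))
    stop("missing normalizer (", normalizer, ") Ct for sample(s): ",
         paste(missing_norm, collapse = ", "))
  if (!reference %in% samples)
    stop("missing reference sample '", reference, "' Ct for target '",
         target, "'")
  ct_t <- stats::setNames(tt$ct, samples)
  ct_n <- stats::setNames(norm$ct, norm$sample_id)[samples]
  d_ct <- ct_t - ct_n
  dd_ct <- d_ct - d_ct[reference]
  2^(-dd_ct)
}
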