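#' Fit MARS models across a metabolite panel
#'
#' Each metabolite is modeled separately against the same combination
#' design.
#'
#' @param design a \code{\link{combination_design}}.
#' @param panel a \code{\link{metabolite_panel}} aligned to \code{design}.
#' @param config a \code{\link{fit_config}}.
#' @return a list of \code{"mars"} models (class \code{"mars_panel"}), in
#'   panel column order, named by metabolite id.
#' @export
fit_panel <- function(design, panel, config = fit_config()) {
  check_alignment(design, panel)
  vals <- panel_matrix(panel)
  ids <- metabolite_ids(panel)
  models <- vector("list", length(ids))
  names(models) <- ids
  for (j in seq_along(ids)) {
    models[[j]] <- mars(design, vals[, j], config, response_id = ids[j])
  }
  structure(models, class = "mars_panel")
}

#' @export
print.mars_panel <- function(x, ...) {
  n_terms <- vapply(x, function(m) length(m$bases) - 1L, integer(1))
  cat(sprintf("MARS panel: %d metabolites, %d with non-intercept terms\n",
              length(x), sum(n_terms > 0)))
  invisible(x)
}

#' Probiotics entering a basis function
#'
#' Maps a basis function's variable indices to probiotic ids, in design
#' column order. The intercept maps to an empty set.
#'
#' @param basis a \code{\link{hinge_basis}}.
#' @param design the \code{\link{combination_design}} the model was fit on.
#' @return character vector of probiotic ids.
#' @export
term_probiotics <- function(basis, design) {
  ids <- probiotic_ids(design)
  ids[sort(basis$vars)]
}

# label used for report columns, e.g. "BL15707 × Ls126D10"
subset_label <- function(ids) paste(ids, collapse = " \u00d7 ")

#' Normalize model coefficients to percentages of the reference level
#'
#' Each retained non-intercept term is expressed as a signed percentage of
#' the prebiotic-alone reference level: positive percentages indicate the
#' term increased, negative that it decreased, metabolite production
#' relative to that reference. The reference level is the model intercept
#' \eqn{C_0}, i.e. the prediction at an all-zero dose vector. A term's
#' contribution is evaluated at its active dose vector \eqn{x_{active}}
#' (the term's probiotics at the maximum dose observed for each in the
#' design, all others at 0):
#' \deqn{pct_k = 100 \cdot C_k B_k(x_{active}) / C_0.}
#' Terms on the same probiotic subset (differing only in knots) are merged
#' by summing their contributions.
#'
#' @param model a fitted \code{"mars"} model.
#' @param design the \code{\link{combination_design}} it was fit on.
#' @return data frame with columns \code{metabolite}, \code{term_label},
#'   \code{degree}, \code{coefficient} (summed contribution
#'   \eqn{\sum C_k B_k(x_{active})} of the merged terms), and
#'   \code{percentage}; zero rows for an intercept-only model.
#'   If the reference level is not positive the fit is unusable for
#'   normalization: an error of class \code{"degenerate_reference"} is
#'   signalled.
#' @export
normalize_coefficients <- function(model, design) {
  c0 <- model$coefficients[1]
  if (basis_degree(model$bases[[1]]) != 0L)
    stop("model's first basis is not the intercept")
  # an intercept at (or numerically indistinguishable from) zero, or
  # negative, makes percentages of the reference level meaningless
  ref_tol <- 1e-8 * max(abs(model$coefficients))
  if (!is.finite(c0) || c0 <= ref_tol)
    stop(structure(class = c("degenerate_reference", "error", "condition"),
                   list(message = paste0(
                     "reference level (intercept) is ", format(c0),
                     " for ", model$response_id %||% "response",
                     "; percentages are undefined"),
                     call = NULL)))
  max_dose <- apply(dose_matrix(design), 2, max)
  ids <- probiotic_ids(design)

  rows <- list()
  for (k in seq_along(model$bases)[-1L]) {
    b <- model$bases[[k]]
    x_active <- numeric(length(ids))
    x_active[b$vars] <- max_dose[b$vars]
    bk <- evaluate_basis(b, matrix(x_active, nrow = 1L))
    contrib <- model$coefficients[k] * bk
    subset <- term_probiotics(b, design)
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = model$response_id %||% NA_character_,
      term_label = subset_label(subset),
      degree = length(subset),
      coefficient = contrib,
      percentage = 100 * contrib / c0,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(metabolite = character(), term_label = character(),
                      degree = integer(), coefficient = numeric(),
                      percentage = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # merge knot-split terms on the same probiotic subset
  agg <- stats::aggregate(out[c("coefficient", "percentage")],
                          by = out[c("metabolite", "term_label", "degree")],
                          FUN = sum)
  agg <- agg[order(agg$degree, agg$term_label), ]
  rownames(agg) <- NULL
  agg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the synergy report for a fitted panel
#'
#' The computational analogue of a metabolite-by-combination synergy
#' figure: every metabolite whose pruned model retains non-intercept terms
#' contributes one row per unique probiotic subset, with the term's signed
#' percentage of the reference level; metabolites with intercept-only
#' models are masked (their production is not affected by any tested
#' probiotic or combination). Metabolites with a non-positive reference
#' level are reported as masked with a warning rather than aborting the
#' panel.
#'
#' @param models a \code{"mars_panel"} (or list of \code{"mars"} models).
#' @param design the \code{\link{combination_design}} the panel was fit on.
#' @return an object of class \code{"synergy_report"}: a list with
#'   \code{terms} (long data frame: metabolite, term_label, degree,
#'   coefficient, percentage), \code{masked_metabolites},
#'   \code{degenerate_metabolites} (subset of the masked ones), and
#'   \code{reference_levels} (named vector of model intercepts).
#' @export
build_synergy_report <- function(models, design) {
  ids <- vapply(seq_along(models), function(j)
    models[[j]]$response_id %||% names(models)[j] %||% paste0("Y", j),
    character(1))
  terms <- list()
  masked <- character()
  degenerate <- character()
  refs <- stats::setNames(
    vapply(models, function(m) m$coefficients[1], numeric(1)), ids)

  for (j in seq_along(models)) {
    m <- models[[j]]
    if (is.null(m$response_id)) m$response_id <- ids[j]
    if (length(m$bases) == 1L) {
      masked <- c(masked, ids[j])
      next
    }
    tj <- tryCatch(normalize_coefficients(m, design),
                   degenerate_reference = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(tj)) {
      masked <- c(masked, ids[j])
      degenerate <- c(degenerate, ids[j])
    } else {
      terms[[length(terms) + 1L]] <- tj
    }
  }
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(metabolite = character(), term_label = character(),
               degree = integer(), coefficient = numeric(),
               percentage = numeric(), stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms,
                 metabolite_ids = ids,
                 masked_metabolites = masked,
                 degenerate_metabolites = degenerate,
                 reference_levels = refs),
            class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf(
    "Synergy report: %d metabolites (%d masked), %d term(s)\n",
    length(x$metabolite_ids), length(x$masked_metabolites), nrow(x$terms)))
  if (nrow(x$terms)) print(x$terms, ...)
  invisible(x)
}

#' Matrix view of a synergy report
#'
#' Rectangular metabolite-by-term percentage matrix. Cells with no
#' retained term are \code{NA} (distinct from an actual 0 percentage);
#' masked (grey) rows are flagged by the \code{"masked"} attribute.
#'
#' @param report a \code{\link{build_synergy_report}} result.
#' @param metabolite_ids row order; defaults to the report's panel order.
#' @param term_columns column order; defaults to the unique term labels
#'   sorted by degree then label.
#' @return numeric matrix with \code{NA} for absent cells and attributes
#'   \code{"masked"} (named logical, grey rows) and \code{"degree"} (named
#'   integer, per column).
#' @export
report_to_matrix <- function(report, metabolite_ids = NULL,
                             term_columns = NULL) {
  if (is.null(metabolite_ids)) metabolite_ids <- report$metabolite_ids
  tt <- report$terms
  if (is.null(term_columns)) {
    u <- unique(tt[c("term_label", "degree")])
    u <- u[order(u$degree, u$term_label), , drop = FALSE]
    term_columns <- u$term_label
    degrees <- stats::setNames(u$degree, u$term_label)
  } else {
    degrees <- stats::setNames(
      tt$degree[match(term_columns, tt$term_label)], term_columns)
  }
  mat <- matrix(NA_real_, length(metabolite_ids), length(term_columns),
                dimnames = list(metabolite_ids, term_columns))
  if (nrow(tt)) {
    ri <- match(tt$metabolite, metabolite_ids)
    ci <- match(tt$term_label, term_columns)
    keep <- !is.na(ri) & !is.na(ci)
    mat[cbind(ri[keep], ci[keep])] <- tt$percentage[keep]
  }
  attr(mat, "masked") <- stats::setNames(
    metabolite_ids %in% report$masked_metabolites, metabolite_ids)
  attr(mat, "degree") <- degrees
  mat
}

#' Long table view of a synergy matrix
#'
#' Inverse of \code{\link{report_to_matrix}} for the populated cells:
#' returns one row per non-\code{NA} matrix entry.
#'
#' @param mat a matrix from \code{\link{report_to_matrix}}.
#' @return data frame with columns \code{metabolite}, \code{term_label},
#'   \code{degree}, \code{percentage}.
#' @export
matrix_to_terms <- function(mat) {
  idx <- which(!is.na(mat), arr.ind = TRUE)
  degrees <- attr(mat, "degree")
  out <- data.frame(
    metabolite = rownames(mat)[idx[, 1]],
    term_label = colnames(mat)[idx[, 2]],
    degree = as.integer(degrees[colnames(mat)[idx[, 2]]]),
    percentage = mat[idx],
    stringsAsFactors = FALSE)
  out <- out[order(match(out$metabolite, rownames(mat)),
                   out$degree, out$term_label), ]
  rownames(out) <- NULL
  out
}

#' Heatmap of a synergy matrix
#'
#' Base-graphics rendering of the synergy matrix: signed percentages on a
#' blue-white-red scale, grey rows for masked metabolites, empty cells for
#' absent terms.
#'
#' @param x a \code{"synergy_report"}.
#' @param ... passed to \code{image}.
#' @return invisibly, the plotted matrix.
#' @export
plot.synergy_report <- function(x, ...) {
  mat <- report_to_matrix(x)
  if (!ncol(mat)) {
    graphics::plot.new()
    graphics::title("Synergy report: all metabolites masked")
    return(invisible(mat))
  }
  masked <- attr(mat, "masked")
  z <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  lim <- max(abs(z), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  op <- graphics::par(mar = c(8, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)),
                  z = t(z), zlim = c(-lim, lim), col = pal,
                  axes = FALSE, xlab = "", ylab = "", ...)
  grey_rows <- which(rev(masked))
  if (length(grey_rows))
    graphics::rect(0.5, grey_rows - 0.5, ncol(z) + 0.5, grey_rows + 0.5,
                   col = "grey85", border = NA)
  graphics::axis(1, at = seq_len(ncol(z)), labels = colnames(z), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(z)), labels = rownames(z), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(mat)
}
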