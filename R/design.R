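#' Combination design table
#'
#' A combination design records, for every fermentation run, which probiotic
#' strains were added and at what dose. Rows are (combination, replicate)
#' pairs; there is one dose column per probiotic, with 0 meaning the strain
#' was not added. An all-zero row is the prebiotic-alone reference
#' condition.
#'
#' @param combination_id character vector of combination labels.
#' @param replicate integer vector of replicate numbers (>= 1).
#' @param doses numeric matrix (rows aligned with \code{combination_id}),
#'   columns named by probiotic id; all entries finite and >= 0.
#' @return a data frame of class \code{"combination_design"} with columns
#'   \code{combination_id}, \code{replicate} and one dose column per
#'   probiotic; attribute \code{"probiotic_ids"} holds the column order.
#' @export
combination_design <- function(combination_id, replicate, doses) {
  doses <- as.matrix(doses)
  if (is.null(colnames(doses)) || anyDuplicated(colnames(doses)))
    stop("dose matrix must have unique probiotic column names")
  if (length(combination_id) != nrow(doses) ||
      length(replicate) != nrow(doses))
    stop("combination_id, replicate and doses must have matching lengths")
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate numbers must be integers >= 1")
  if (!all(is.finite(doses)) || any(doses < 0))
    stop("doses must be finite and non-negative")
  df <- data.frame(combination_id = as.character(combination_id),
                   replicate = replicate,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (p in colnames(doses)) df[[p]] <- as.numeric(doses[, p])
  structure(df,
            probiotic_ids = colnames(doses),
            class = c("combination_design", "data.frame"))
}

#' Probiotic ids of a design
#' @param design a \code{\link{combination_design}}.
#' @return character vector of probiotic column names, in design order.
#' @export
probiotic_ids <- function(design) attr(design, "probiotic_ids")

#' Dose matrix of a design
#'
#' @param design a \code{\link{combination_design}} or a bare numeric
#'   matrix/vector (passed through).
#' @return numeric matrix of doses (rows = runs, columns = probiotics).
#' @export
dose_matrix <- function(design) {
  if (inherits(design, "combination_design")) {
    m <- as.matrix(as.data.frame(design)[, probiotic_ids(design), drop = FALSE])
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.data.frame(design)) design <- as.matrix(design)
  if (is.null(dim(design))) design <- matrix(design, ncol = 1L)
  storage.mode(design) <- "double"
  design
}

#' @export
print.combination_design <- function(x, ...) {
  cat(sprintf("Combination design: %d rows, %d probiotics (%s)\n",
              nrow(x), length(probiotic_ids(x)),
              paste(probiotic_ids(x), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Metabolite panel table
#'
#' Measured (or simulated) metabolite concentrations aligned row-by-row to a
#' combination design.
#'
#' @param design the \code{\link{combination_design}} the rows belong to.
#' @param values numeric matrix (design rows x metabolites), column names =
#'   metabolite ids; entries finite and >= 0 (concentrations, ug/mL).
#' @return a data frame of class \code{"metabolite_panel"} with
#'   \code{combination_id}, \code{replicate} and one column per metabolite;
#'   attribute \code{"metabolite_ids"}.
#' @export
metabolite_panel <- function(design, values) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("panel matrix must have unique metabolite column names")
  if (nrow(values) != nrow(design))
    stop("panel has ", nrow(values), " rows but design has ", nrow(design))
  if (!all(is.finite(values)) || any(values < 0))
    stop("metabolite concentrations must be finite and non-negative")
  df <- data.frame(combination_id = design$combination_id,
                   replicate = design$replicate,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (m in colnames(values)) df[[m]] <- as.numeric(values[, m])
  structure(df,
            metabolite_ids = colnames(values),
            class = c("metabolite_panel", "data.frame"))
}

#' Metabolite ids of a panel
#' @param panel a \code{\link{metabolite_panel}}.
#' @return character vector of metabolite column names.
#' @export
metabolite_ids <- function(panel) attr(panel, "metabolite_ids")

#' Concentration matrix of a panel
#' @param panel a \code{\link{metabolite_panel}}.
#' @return numeric matrix (rows = runs, columns = metabolites).
#' @export
panel_matrix <- function(panel) {
  m <- as.matrix(as.data.frame(panel)[, metabolite_ids(panel), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("Metabolite panel: %d rows, %d metabolites\n",
              nrow(x), length(metabolite_ids(x))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# check that panel rows align one-to-one, in order, with design rows;
# error names the first offending (combination, replicate)
check_alignment <- function(design, panel) {
  dk <- paste(design$combination_id, design$replicate, sep = "/")
  pk <- paste(panel$combination_id, panel$replicate, sep = "/")
  if (length(dk) != length(pk)) {
    missing <- setdiff(dk, pk)
    extra <- setdiff(pk, dk)
    stop("panel rows do not align with design: ",
         if (length(missing)) paste0("missing (combination, replicate) ",
                                     paste(missing, collapse = ", ")) else "",
         if (length(extra)) paste0(" unexpected ",
                                   paste(extra, collapse = ", ")) else "")
  }
  bad <- which(dk != pk)
  if (length(bad))
    stop("panel row ", bad[1], " is (", pk[bad[1]],
         ") but design row is (", dk[bad[1]], ")")
  invisible(TRUE)
}
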