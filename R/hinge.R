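#' Hinge function
#'
#' The piecewise-linear atom of MARS bases, \eqn{h(x) = max(0, x)}.
#' Mirrored pairs \eqn{h(x - t)} and \eqn{h(t - x)} split a predictor at
#' knot \eqn{t}.
#'
#' @param x numeric vector.
#' @return \code{pmax(0, x)}.
#' @export
hinge <- function(x) pmax(0, x)

#' Construct a hinge basis function
#'
#' A basis function is a product of hinge factors, each acting on one
#' predictor (probiotic dose) column. The empty product is the intercept,
#' which evaluates to 1 everywhere. Within one basis no two factors may
#' share a variable: on dose designs repeated hinges on the same variable
#' only produce redundant powers of indicators.
#'
#' @param vars integer vector of 1-based design column indices.
#' @param knots numeric vector of knot locations \eqn{t_k}, same length.
#' @param dirs integer vector of directions in \code{c(1, -1)}: \code{+1}
#'   gives the factor \eqn{h(x_v - t)}, \code{-1} gives \eqn{h(t - x_v)}.
#' @return an object of class \code{"hinge_basis"}.
#' @examples
#' b <- hinge_basis(vars = c(1, 2), knots = c(0, 0), dirs = c(1, 1))
#' evaluate_basis(b, c(3, 2))  # h(3 - 0) * h(2 - 0) = 6
#' @export
hinge_basis <- function(vars = integer(), knots = numeric(), dirs = integer()) {
  vars <- as.integer(vars)
  dirs <- as.integer(dirs)
  knots <- as.numeric(knots)
  if (length(vars) != length(knots) || length(vars) != length(dirs))
    stop("vars, knots and dirs must have equal length")
  if (anyDuplicated(vars))
    stop("a hinge basis may not use the same variable twice")
  if (length(knots) && any(!is.finite(knots)))
    stop("knots must be finite")
  if (length(dirs) && !all(dirs %in% c(1L, -1L)))
    stop("dirs must be +1 or -1")
  structure(list(vars = vars, knots = knots, dirs = dirs),
            class = "hinge_basis")
}

#' @export
print.hinge_basis <- function(x, ...) {
  cat(format_basis(x), "\n")
  invisible(x)
}

# human-readable basis label, e.g. "h(x1 - 0) * h(x3 - 0)"
format_basis <- function(basis, var_names = NULL) {
  if (basis_degree(basis) == 0L) return("(intercept)")
  lab <- vapply(seq_along(basis$vars), function(i) {
    v <- if (is.null(var_names)) paste0("x", basis$vars[i]) else
      var_names[basis$vars[i]]
    t <- format(basis$knots[i])
    if (basis$dirs[i] > 0) sprintf("h(%s - %s)", v, t)
    else sprintf("h(%s - %s)", t, v)
  }, character(1))
  paste(lab, collapse = " * ")
}

#' Degree of a hinge basis
#'
#' Number of hinge factors in the product; the intercept has degree 0.
#'
#' @param basis a \code{\link{hinge_basis}}.
#' @return integer degree.
#' @export
basis_degree <- function(basis) length(basis$vars)

#' Evaluate a hinge basis at dose vectors
#'
#' Computes \eqn{\prod_k h(d_k (x_{v_k} - t_k))} for each row of \code{x}.
#' The intercept (degree 0) evaluates to 1; every basis value is
#' non-negative.
#'
#' @param basis a \code{\link{hinge_basis}}.
#' @param x numeric vector (one dose vector) or matrix (rows = samples,
#'   columns = probiotics).
#' @return numeric vector of basis values, one per row of \code{x}.
#' @export
evaluate_basis <- function(basis, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!all(is.finite(x))) stop("dose values must be finite")
  if (length(basis$vars) && max(basis$vars) > ncol(x))
    stop("variable index ", max(basis$vars), " exceeds design width ", ncol(x))
  out <- rep(1, nrow(x))
  for (i in seq_along(basis$vars)) {
    out <- out * pmax(0, basis$dirs[i] * (x[, basis$vars[i]] - basis$knots[i]))
  }
  out
}

#' Build the basis matrix for a set of basis functions
#'
#' @param bases list of \code{\link{hinge_basis}} objects; by convention the
#'   first is the intercept.
#' @param design a \code{\link{combination_design}} or a numeric dose matrix.
#' @return numeric matrix, rows = design rows, columns = bases; the
#'   intercept column is all ones.
#' @export
build_basis_matrix <- function(bases, design) {
  x <- dose_matrix(design)
  if (nrow(x) == 0L) stop("design has no rows")
  out <- matrix(0, nrow(x), length(bases))
  for (k in seq_along(bases)) out[, k] <- evaluate_basis(bases[[k]], x)
  out
}
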