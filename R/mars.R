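#' Fitting configuration for MARS
#'
#' @param max_terms maximum number of basis functions (intercept included)
#'   the forward pass may accumulate. Default 21.
#' @param max_degree maximum number of hinge factors per basis (interaction
#'   order). Default 3, enough for tertiary probiotic synergies.
#' @param gcv_penalty per-knot complexity charge \eqn{d} in the GCV cost
#'   \eqn{C = n_{terms} + d \cdot n_{knots}}. Default 3 for interaction
#'   models, 2 when \code{max_degree == 1} (additive model).
#' @param forward_improvement_tol minimum relative RSS decrease for the
#'   forward pass to accept a new term pair. Default 1e-4.
#' @param ridge_eps ridge stabilization added to the normal equations
#'   (intercept included); duplicated indicator columns arise routinely on
#'   small combination designs. Default 1e-8.
#' @param forward_criterion \code{"rss"} (classical) or \code{"gcv"}:
#'   score by which forward candidates are ranked.
#' @param seed reserved; the fit itself is deterministic.
#' @return a list of class \code{"fit_config"}.
#' @export
fit_config <- function(max_terms = 21L, max_degree = 3L,
                       gcv_penalty = NULL,
                       forward_improvement_tol = 1e-4,
                       ridge_eps = 1e-8,
                       forward_criterion = c("rss", "gcv"),
                       seed = NULL) {
  max_terms <- as.integer(max_terms)
  max_degree <- as.integer(max_degree)
  if (max_terms < 1L) stop("max_terms must be >= 1")
  if (max_degree < 1L) stop("max_degree must be >= 1")
  if (is.null(gcv_penalty)) gcv_penalty <- if (max_degree == 1L) 2 else 3
  if (!is.finite(gcv_penalty) || gcv_penalty < 0)
    stop("gcv_penalty must be a finite non-negative number")
  if (!is.finite(forward_improvement_tol))
    stop("forward_improvement_tol must be finite")
  if (!is.finite(ridge_eps) || ridge_eps < 0)
    stop("ridge_eps must be >= 0")
  structure(list(max_terms = max_terms, max_degree = max_degree,
                 gcv_penalty = gcv_penalty,
                 forward_improvement_tol = forward_improvement_tol,
                 ridge_eps = ridge_eps,
                 forward_criterion = match.arg(forward_criterion),
                 seed = seed),
            class = "fit_config")
}

#' Ridge-stabilized least squares for a basis matrix
#'
#' Minimizes \eqn{\|y - B C\|^2 + \epsilon \|C\|^2} via the augmented
#' system \eqn{[B; \sqrt{\epsilon} I] C = [y; 0]} solved by QR. With
#' \code{ridge_eps = 0} this is ordinary least squares. The reported RSS is
#' the residual sum of squares of the returned coefficients on the data
#' (the penalty term is not included).
#'
#' @param basis_matrix numeric matrix (n x K).
#' @param y numeric response vector of length n.
#' @param ridge_eps non-negative stabilization constant.
#' @return list with \code{coefficients} (length K) and \code{rss}.
#' @export
fit_least_squares <- function(basis_matrix, y, ridge_eps = 1e-8) {
  basis_matrix <- as.matrix(basis_matrix)
  if (length(y) == 0L) stop("y must be non-empty")
  if (nrow(basis_matrix) != length(y))
    stop("basis matrix rows (", nrow(basis_matrix),
         ") do not match length of y (", length(y), ")")
  k <- ncol(basis_matrix)
  if (ridge_eps > 0) {
    aug <- rbind(basis_matrix, diag(sqrt(ridge_eps), k))
    rhs <- c(y, rep(0, k))
  } else {
    aug <- basis_matrix
    rhs <- y
  }
  qr_aug <- qr(aug)
  coefs <- qr.coef(qr_aug, rhs)
  coefs[is.na(coefs)] <- 0  # rank-deficient & eps = 0: pivoted-out columns
  resid <- y - drop(basis_matrix %*% coefs)
  list(coefficients = as.numeric(coefs), rss = sum(resid^2))
}

#' Generalized cross-validation score
#'
#' \eqn{GCV = (RSS/n) / (1 - C/n)^2} with complexity charge
#' \eqn{C = n_{terms} + penalty \cdot n_{knots}}; returns \code{Inf} when
#' \eqn{C \ge n}, so over-parameterized models are never selected.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n_obs number of observations (>= 1).
#' @param n_terms number of basis functions, intercept included (>= 1).
#' @param n_knots total number of hinge knots across the bases (>= 0).
#' @param penalty per-knot charge.
#' @return non-negative GCV score, possibly \code{Inf}.
#' @export
gcv_score <- function(rss, n_obs, n_terms, n_knots, penalty = 3) {
  if (!is.finite(rss) || rss < 0) stop("rss must be finite and >= 0")
  if (n_obs < 1L) stop("n_obs must be >= 1")
  if (n_terms < 1L) stop("n_terms must be >= 1 (intercept counts)")
  if (n_knots < 0L) stop("n_knots must be >= 0")
  cost <- n_terms + penalty * n_knots
  if (cost >= n_obs) return(Inf)
  (rss / n_obs) / (1 - cost / n_obs)^2
}

# knots charged to a model = total hinge factors across non-intercept bases
count_knots <- function(bases) {
  sum(vapply(bases, basis_degree, integer(1)))
}

# column is numerically indistinguishable from zero
is_zero_col <- function(col) max(abs(col)) < 1e-12

# TRUE if appending `col` to matrix B leaves it numerically rank-deficient
adds_rank <- function(B, col, tol = 1e-7) {
  qr(cbind(B, col))$rank > qr(B)$rank
}

#' MARS forward pass
#'
#' Greedy growth of the basis set. Starting from the intercept, every
#' admissible candidate -- a parent basis already in the model, a variable
#' not used in that parent, and a knot drawn from the values of that
#' variable observed where the parent is positive -- is evaluated as a
#' mirrored hinge pair. The pair giving the lowest residual sum of squares
#' is added; a pair member whose column is identically zero or adds no
#' numerical rank is dropped. Growth stops at \code{max_terms}, when no
#' admissible candidate remains, or when the relative RSS improvement falls
#' below \code{forward_improvement_tol}.
#'
#' Ties are broken deterministically by (score, variable index, knot,
#' parent position), so fits are reproducible.
#'
#' @param design a \code{\link{combination_design}} or dose matrix.
#' @param y numeric response vector.
#' @param config a \code{\link{fit_config}}.
#' @return an unpruned \code{"mars"} model object.
#' @export
forward_pass <- function(design, y, config = fit_config()) {
  x <- dose_matrix(design)
  if (nrow(x) == 0L) stop("design has no rows")
  if (nrow(x) != length(y))
    stop("length of y (", length(y), ") does not match design rows (",
         nrow(x), ")")
  if (!all(is.finite(y))) stop("y must be finite")

  n <- nrow(x)
  bases <- list(hinge_basis())
  B <- matrix(1, n, 1L)
  fit <- fit_least_squares(B, y, config$ridge_eps)
  rss_cur <- fit$rss
  rss_scale <- max(sum((y - mean(y))^2), .Machine$double.eps)

  repeat {
    if (length(bases) >= config$max_terms) break
    if (rss_cur <= 1e-12 * max(1, rss_scale)) break

    best <- NULL
    for (p in seq_along(bases)) {
      parent <- bases[[p]]
      if (basis_degree(parent) >= config$max_degree) next
      active <- B[, p] > 0
      if (!any(active)) next
      for (v in setdiff(seq_len(ncol(x)), parent$vars)) {
        for (t in sort(unique(x[active, v]))) {
          pos <- B[, p] * pmax(0, x[, v] - t)
          neg <- B[, p] * pmax(0, t - x[, v])
          cols <- list()
          dirs <- integer()
          if (!is_zero_col(pos)) { cols <- c(cols, list(pos)); dirs <- c(dirs, 1L) }
          if (!is_zero_col(neg)) { cols <- c(cols, list(neg)); dirs <- c(dirs, -1L) }
          if (!length(cols)) next
          Bc <- cbind(B, do.call(cbind, cols))
          cand_fit <- fit_least_squares(Bc, y, config$ridge_eps)
          score <- cand_fit$rss
          if (config$forward_criterion == "gcv") {
            score <- gcv_score(cand_fit$rss, n,
                               length(bases) + length(cols),
                               count_knots(bases) +
                                 length(cols) * (basis_degree(parent) + 1L),
                               config$gcv_penalty)
          }
          if (is.null(best) ||
              score < best$score - 1e-10 * max(1, best$score) ||
              (abs(score - best$score) <= 1e-10 * max(1, best$score) &&
               (v < best$v || (v == best$v && (t < best$t ||
                (t == best$t && p < best$p)))))) {
            best <- list(score = score, rss = cand_fit$rss,
                         p = p, v = v, t = t, dirs = dirs)
          }
        }
      }
    }
    if (is.null(best)) break
    improvement <- (rss_cur - best$rss) / max(rss_cur, .Machine$double.eps)
    if (improvement < config$forward_improvement_tol) break

    parent <- bases[[best$p]]
    added <- FALSE
    for (d in best$dirs) {
      if (length(bases) >= config$max_terms) break
      nb <- hinge_basis(vars = c(parent$vars, best$v),
                        knots = c(parent$knots, best$t),
                        dirs = c(parent$dirs, d))
      col <- evaluate_basis(nb, x)
      if (is_zero_col(col) || !adds_rank(B, col)) next
      bases <- c(bases, list(nb))
      B <- cbind(B, col)
      added <- TRUE
    }
    if (!added) break
    fit <- fit_least_squares(B, y, config$ridge_eps)
    rss_cur <- fit$rss
  }

  new_mars(bases = bases, coefficients = fit$coefficients, rss = rss_cur,
           n_obs = n, config = config, design = design, y = y,
           pruned = FALSE)
}

#' MARS backward pass (GCV pruning)
#'
#' Greedy backward elimination: at each step the non-intercept basis whose
#' removal increases the residual sum of squares least is deleted and the
#' remaining coefficients are refit; over the whole deletion sequence (down
#' to the intercept-only model) the model with minimum GCV is returned,
#' preferring fewer terms on ties. Ranking deletions by RSS rather than by
#' GCV keeps the step well defined when the unpruned model is
#' over-parameterized (complexity charge >= n, GCV infinite) and prevents
#' the pruner from discarding a high-order term merely because that term
#' carries the largest complexity charge. The intercept is never removed.
#' Probiotics or combinations that do not predict the metabolite are
#' thereby removed from the final model.
#'
#' @param model an (unpruned) \code{"mars"} model from
#'   \code{\link{forward_pass}}.
#' @param design the design the model was fit on.
#' @param y the response the model was fit on.
#' @param config a \code{\link{fit_config}}.
#' @return the pruned, refit \code{"mars"} model.
#' @export
backward_pass <- function(model, design, y, config = fit_config()) {
  x <- dose_matrix(design)
  n <- length(y)
  bases <- model$bases

  refit <- function(idx) {
    B <- build_basis_matrix(bases[idx], x)
    f <- fit_least_squares(B, y, config$ridge_eps)
    g <- gcv_score(f$rss, n, length(idx), count_knots(bases[idx]),
                   config$gcv_penalty)
    list(idx = idx, fit = f, gcv = g)
  }

  cur <- refit(seq_along(bases))
  best <- cur
  path <- list(cur)
  while (length(cur$idx) > 1L) {
    step_best <- NULL
    for (j in seq_along(cur$idx)[-1L]) {  # never remove the intercept
      cand <- refit(cur$idx[-j])
      if (is.null(step_best) || cand$fit$rss < step_best$fit$rss)
        step_best <- cand
    }
    cur <- step_best
    path[[length(path) + 1L]] <- cur
    if (cur$gcv <= best$gcv) best <- cur  # ties resolve to fewer terms
  }

  out <- new_mars(bases = bases[best$idx], coefficients = best$fit$coefficients,
                  rss = best$fit$rss, n_obs = n, config = config,
                  design = design, y = y, pruned = TRUE,
                  response_id = model$response_id)
  # deletion sequence (indices into the unpruned model's bases), for
  # inspection of the pruning trajectory
  out$prune_path <- lapply(path, function(s)
    list(idx = s$idx, rss = s$fit$rss, gcv = s$gcv))
  out
}

# internal constructor for the fitted-model object
new_mars <- function(bases, coefficients, rss, n_obs, config, design, y,
                     pruned, response_id = NULL, call = NULL) {
  gcv <- gcv_score(rss, n_obs, length(bases), count_knots(bases),
                   config$gcv_penalty)
  x <- dose_matrix(design)
  fitted <- drop(build_basis_matrix(bases, x) %*% coefficients)
  var_names <- if (inherits(design, "combination_design"))
    probiotic_ids(design) else colnames(x)
  structure(list(bases = bases,
                 coefficients = as.numeric(coefficients),
                 rss = rss, gcv = gcv, n_obs = n_obs,
                 n_vars = ncol(x), var_names = var_names,
                 response_id = response_id,
                 config = config, pruned = pruned,
                 fitted.values = fitted,
                 residuals = y - fitted,
                 y = y, call = call),
            class = "mars")
}

#' Fit a MARS model to one metabolite
#'
#' Fits \eqn{f(X) = \sum_k C_k B_k(X)}, where each \eqn{B_k} is a product
#' of hinge functions \eqn{h(\pm(x_v - t))} on probiotic doses, by a greedy
#' forward pass followed by GCV-scored backward pruning. The intercept
#' \eqn{C_0} is the predicted metabolite level with no probiotics added
#' (the prebiotic-alone reference).
#'
#' @param design a \code{\link{combination_design}} or numeric dose matrix.
#' @param y numeric vector of metabolite concentrations, one per design
#'   row; replicates enter as independent rows.
#' @param config a \code{\link{fit_config}}.
#' @param response_id optional metabolite identifier stored on the model.
#' @return an object of class \code{"mars"} with components \code{bases},
#'   \code{coefficients}, \code{rss}, \code{gcv}, \code{n_obs},
#'   \code{fitted.values} and \code{residuals}. Supports \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals} and
#'   \code{fitted}.
#' @examples
#' X <- expand.grid(A = c(0, 1), B = c(0, 1))
#' y <- 1 + 2 * X$A + 3 * X$B
#' fit <- mars(as.matrix(X), y)
#' predict(fit, as.matrix(X))
#' @export
mars <- function(design, y, config = fit_config(), response_id = NULL) {
  fwd <- forward_pass(design, y, config)
  fwd$response_id <- response_id
  out <- backward_pass(fwd, design, y, config)
  out$call <- match.call()
  out
}

#' @export
print.mars <- function(x, ...) {
  cat(sprintf("MARS model%s: %d basis function(s), n = %d\n",
              if (!is.null(x$response_id)) paste0(" for ", x$response_id)
              else "",
              length(x$bases), x$n_obs))
  cat(sprintf("  RSS = %.6g, GCV = %.6g\n", x$rss, x$gcv))
  labels <- vapply(x$bases, format_basis, character(1),
                   var_names = x$var_names)
  for (k in seq_along(x$bases))
    cat(sprintf("  %12.6g  %s\n", x$coefficients[k], labels[k]))
  invisible(x)
}

#' @export
summary.mars <- function(object, ...) {
  labels <- vapply(object$bases, format_basis, character(1),
                   var_names = object$var_names)
  tss <- sum((object$y - mean(object$y))^2)
  structure(list(model = object,
                 terms = data.frame(label = labels,
                                    degree = vapply(object$bases,
                                                    basis_degree, integer(1)),
                                    coefficient = object$coefficients,
                                    stringsAsFactors = FALSE),
                 r_squared = if (tss > 0) 1 - object$rss / tss else NA_real_),
            class = "summary.mars")
}

#' @export
print.summary.mars <- function(x, ...) {
  print(x$model)
  if (!is.na(x$r_squared))
    cat(sprintf("  R-squared (training): %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.mars <- function(object, ...) {
  labels <- vapply(object$bases, format_basis, character(1),
                   var_names = object$var_names)
  stats::setNames(object$coefficients, labels)
}

#' Predict metabolite levels from a fitted MARS model
#'
#' @param object a \code{"mars"} model.
#' @param newdata a \code{\link{combination_design}} or dose matrix with the
#'   same number of probiotic columns the model was fit on; defaults to the
#'   training fitted values.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mars <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- dose_matrix(newdata)
  if (ncol(x) != object$n_vars)
    stop("newdata has ", ncol(x), " probiotic columns but the model was fit",
         " on ", object$n_vars)
  drop(build_basis_matrix(object$bases, x) %*% object$coefficients)
}

#' @export
residuals.mars <- function(object, ...) object$residuals

#' @export
fitted.mars <- function(object, ...) object$fitted.values
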