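# Independent oracles. These deliberately take different numerical routes
# from the package internals: explicit normal equations instead of the
# augmented-QR solver, and exhaustive enumeration instead of greedy search.

# explicit normal-equations ridge solution (B'B + eps I)^{-1} B'y
oracle_ridge <- function(B, y, eps = 1e-8) {
  B <- as.matrix(B)
  coefs <- solve(crossprod(B) + diag(eps, ncol(B)), crossprod(B, y))
  rss <- sum((y - B %*% coefs)^2)
  list(coefficients = as.numeric(coefs), rss = rss)
}

# exhaustive enumeration of all first-split candidates (parent = intercept):
# every variable, every observed knot, mirrored pair with zero columns
# dropped; returns the (rss, v, t)-ordered optimum
oracle_first_split <- function(X, y, eps = 1e-8) {
  X <- as.matrix(X)
  best <- NULL
  for (v in seq_len(ncol(X))) {
    for (t in sort(unique(X[, v]))) {
      pos <- pmax(0, X[, v] - t)
      neg <- pmax(0, t - X[, v])
      cols <- matrix(1, nrow(X), 1)
      if (max(abs(pos)) > 1e-12) cols <- cbind(cols, pos)
      if (max(abs(neg)) > 1e-12) cols <- cbind(cols, neg)
      if (ncol(cols) == 1L) next
      rss <- oracle_ridge(cols, y, eps)$rss
      if (is.null(best) || rss < best$rss - 1e-10 * max(1, best$rss))
        best <- list(rss = rss, v = v, t = t)
    }
  }
  best
}

# exhaustive best-GCV subset (intercept always retained) of a fitted
# model's bases; complexity charged as n_terms + penalty * n_knots with
# n_knots = total hinge factors
oracle_best_subset <- function(model, design, y, penalty = 3, eps = 1e-8) {
  bases <- model$bases
  n <- length(y)
  others <- seq_along(bases)[-1L]
  best <- NULL
  for (size in 0:length(others)) {
    subsets <- if (size == 0L) list(integer()) else
      utils::combn(others, size, simplify = FALSE)
    for (s in subsets) {
      idx <- c(1L, s)
      B <- build_basis_matrix(bases[idx], design)
      rss <- oracle_ridge(B, y, eps)$rss
      nk <- sum(vapply(bases[idx], basis_degree, integer(1)))
      cost <- length(idx) + penalty * nk
      gcv <- if (cost >= n) Inf else (rss / n) / (1 - cost / n)^2
      if (is.null(best) || gcv < best$gcv) best <- list(idx = idx, gcv = gcv)
    }
  }
  best
}

# random small design with a handful of dose levels (knots non-trivial)
random_design <- function(n, m, levels = c(0, 0.5, 1, 2)) {
  matrix(sample(levels, n * m, replace = TRUE), n, m,
         dimnames = list(NULL, paste0("P", seq_len(m))))
}

# binary full-factorial design with replicates, as a combination_design
binary_design <- function(m, reps = 3L, ids = paste0("P", seq_len(m))) {
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  colnames(grid) <- ids
  grid <- grid[rep(seq_len(nrow(grid)), each = reps), , drop = FALSE]
  combination_design(
    combination_id = rep(sprintf("G%02d", seq_len(2^m)), each = reps),
    replicate = rep(seq_len(reps), times = 2^m),
    doses = grid)
}

planted_demo_labels <- function() {
  list(main = c("3-HPPA", "BL15707"),
       pair = c("DHVL", "BL15707 × Ls126D10"),
       triple = c("3-HPVA", "BL15707 × Lp126A7 × Ls126D10"))
}

# percentage of a given (metabolite, term_label) in a report, or NA
report_pct <- function(report, metabolite, label) {
  tt <- report$terms
  hit <- tt$metabolite == metabolite & tt$term_label == label
  if (any(hit)) tt$percentage[hit] else NA_real_
}
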