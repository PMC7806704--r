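#' Canonical probiotic strain ids
#'
#' The six candidate probiotic strains used throughout the package's
#' examples and default design: Lactiplantibacillus plantarum Lp793 and
#' Lp126A7, Bifidobacterium longum BL15707, Limosilactobacillus reuteri
#' Lr126C6, Ligilactobacillus salivarius Ls126D10, and Bifidobacterium
#' adolescentis Ba114B10.
#'
#' @return character vector of length 6.
#' @export
probiotic_strains <- function() {
  c("Lp793", "BL15707", "Lp126A7", "Lr126C6", "Ls126D10", "Ba114B10")
}

#' Metabolite panel vocabulary
#'
#' The 44-analyte phenolic panel: 39 standard abbreviations of
#' polyphenol-derived metabolites (gallic acid GA, pyrogallol PG,
#' phenyl-gamma-valerolactones such as DHVL, phenylvaleric acids such as
#' 3-HPVA, flavonols such as QUER and KAMF, ...) plus 5 placeholder ids for
#' the parent prebiotic polyphenols, labelled \code{PARENT-1} ..
#' \code{PARENT-5} (synthetic placeholders: the parent analytes are not
#' individually named in the abbreviation vocabulary).
#'
#' @return character vector of length 44.
#' @export
pam_metabolites <- function() {
  c("GA", "PG", "4-HHA", "3,4-HBA", "3-HHA", "D3Glc", "3,4-diHPPA",
    "C3Glc", "4-MeGA", "4-HBA", "HA", "Mvd", "4-HPAA", "3,4-diHPAA",
    "VA", "M3Glc", "CA", "3-HBA", "PAC-B2", "3-HPAA", "HVA", "PGA",
    "DHVL", "4-HPPA", "4-HCA", "3-HPPA", "DHFA", "FA", "3-HCA", "PA",
    "3,4-diHPVA", "MYR", "DHRSV", "4-HPVA", "3-HPVA", "QUER", "KAMF",
    "3'-MeQUER", "7'-MeQUER",
    paste0("PARENT-", 1:5))
}

#' Default combination layout
#'
#' Twelve combinations of the six strains: the six singletons, five pairs
#' and one triple. The layout is chosen so the triple's sub-pairs each
#' co-occur in at least one other combination, making a planted tertiary
#' synergy identifiable from a planted pairwise one (see
#' \code{\link{check_identifiability}}). It is illustrative of a screening
#' design at this scale, not a record of any particular study's layout.
#'
#' @return named list of 12 character vectors of strain ids.
#' @export
default_combinations <- function() {
  s <- probiotic_strains()
  combos <- c(
    as.list(s),
    list(c("BL15707", "Ls126D10"),
         c("BL15707", "Lp126A7"),
         c("Lp126A7", "Ls126D10"),
         c("Lp793", "Ls126D10"),
         c("Lp793", "Lr126C6"),
         c("BL15707", "Lp126A7", "Ls126D10")))
  stats::setNames(combos, sprintf("C%02d", seq_along(combos)))
}

#' Generate a combination design
#'
#' One row per (combination, replicate); member probiotics get the tested
#' dose, all others 0. Deterministic given its inputs. Dose 1.0 is the
#' package's abstract dose unit (one unit corresponds to the inoculation
#' dose, e.g. 1e10 CFU per meal).
#'
#' @param probiotic_ids character vector of strain ids (design columns).
#' @param combinations named list of strain-id subsets; an empty subset is
#'   the prebiotic-alone reference combination.
#' @param replicates number of independent replicate rows per combination.
#' @param dose dose placed at member strains.
#' @param include_reference if \code{TRUE}, append an all-zero
#'   prebiotic-alone combination (\code{"BDPP"}).
#' @return a \code{\link{combination_design}}; with the defaults, 6
#'   probiotics x 12 combinations x 3 replicates = 36 rows.
#' @export
generate_design <- function(probiotic_ids = probiotic_strains(),
                            combinations = default_combinations(),
                            replicates = 3L, dose = 1.0,
                            include_reference = FALSE) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!is.finite(dose) || dose <= 0) stop("dose must be a positive number")
  if (is.null(names(combinations)))
    names(combinations) <- sprintf("C%02d", seq_along(combinations))
  if (include_reference) combinations <- c(combinations,
                                           list(BDPP = character()))
  for (nm in names(combinations)) {
    unknown <- setdiff(combinations[[nm]], probiotic_ids)
    if (length(unknown))
      stop("combination ", nm, " uses unknown probiotic(s): ",
           paste(unknown, collapse = ", "))
  }
  n <- length(combinations) * replicates
  doses <- matrix(0, n, length(probiotic_ids),
                  dimnames = list(NULL, probiotic_ids))
  cid <- character(n)
  rep_no <- integer(n)
  i <- 0L
  for (nm in names(combinations)) {
    for (r in seq_len(replicates)) {
      i <- i + 1L
      cid[i] <- nm
      rep_no[i] <- r
      doses[i, combinations[[nm]]] <- dose
    }
  }
  combination_design(cid, rep_no, doses)
}

#' Planted effect specification
#'
#' Ground truth for the synthetic generator. Each effect is a
#' (metabolite, probiotic subset, effect size) triple: when all members of
#' the subset are dosed in a run, the metabolite's expected concentration
#' gains the fraction \code{effect} of its baseline. Effects combine
#' additively on the fraction scale (matching the percentage semantics of
#' the synergy report); a fully multiplicative combination is available via
#' \code{combine = "multiplicative"}.
#'
#' @param baselines named positive numeric vector: per-metabolite reference
#'   concentration (ug/mL) with no probiotics.
#' @param effects data frame with columns \code{metabolite} (character),
#'   \code{probiotics} (list column of character vectors, subset size 1-3),
#'   \code{effect} (numeric > -1). Use \code{planted_effect} to build rows.
#' @param noise_sigma lognormal noise scale on the log scale (>= 0).
#' @param dose tested dose (dose units); must match the design's.
#' @param combine \code{"additive"} (default) or \code{"multiplicative"}.
#' @return an object of class \code{"effect_spec"}.
#' @export
effect_spec <- function(baselines, effects = NULL, noise_sigma = 0.1,
                        dose = 1.0, combine = c("additive",
                                                "multiplicative")) {
  if (is.null(names(baselines)) || anyDuplicated(names(baselines)))
    stop("baselines must be uniquely named by metabolite id")
  if (any(!is.finite(baselines)) || any(baselines <= 0))
    stop("baselines must be positive and finite")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be >= 0")
  if (is.null(effects))
    effects <- data.frame(metabolite = character(), effect = numeric())
  if (!"probiotics" %in% names(effects))
    effects$probiotics <- vector("list", nrow(effects))
  if (nrow(effects)) {
    if (!all(effects$metabolite %in% names(baselines)))
      stop("effects name metabolites absent from baselines: ",
           paste(setdiff(effects$metabolite, names(baselines)),
                 collapse = ", "))
    sizes <- lengths(effects$probiotics)
    if (any(sizes < 1L) || any(sizes > 3L))
      stop("probiotic subsets must have size 1-3")
    if (any(vapply(effects$probiotics, anyDuplicated, integer(1)) > 0))
      stop("probiotic subsets must be duplicate-free")
    keys <- paste(effects$metabolite,
                  vapply(effects$probiotics,
                         function(p) paste(sort(p), collapse = "+"),
                         character(1)))
    if (anyDuplicated(keys))
      stop("duplicate (metabolite, subset) effects")
    if (any(!is.finite(effects$effect)) || any(effects$effect <= -1))
      stop("effect sizes must be finite and > -1")
  }
  structure(list(baselines = baselines, effects = effects,
                 noise_sigma = noise_sigma, dose = dose,
                 combine = match.arg(combine)),
            class = "effect_spec")
}

#' One planted effect row
#'
#' @param metabolite metabolite id.
#' @param probiotics character vector of 1-3 strain ids.
#' @param effect effect size as a fraction of the baseline (> -1);
#'   \code{2.0} means +200\% of the reference level.
#' @return one-row data frame suitable for \code{rbind} into the
#'   \code{effects} argument of \code{\link{effect_spec}}.
#' @export
planted_effect <- function(metabolite, probiotics, effect) {
  data.frame(metabolite = metabolite,
             probiotics = I(list(probiotics)),
             effect = effect, stringsAsFactors = FALSE)
}

#' Demonstration effect specification at study scale
#'
#' A 44-metabolite panel with three planted effects chosen to exercise all
#' interaction orders: a +50\% main effect of BL15707 on 3-HPPA, a +200\%
#' pairwise synergy of BL15707 x Ls126D10 on DHVL, and a +500\% tertiary
#' synergy of BL15707 x Lp126A7 x Ls126D10 on 3-HPVA. All other
#' metabolites are null. Baselines default to 10 ug/mL.
#'
#' @param noise_sigma lognormal noise scale (default 0.05).
#' @param baseline common baseline concentration (ug/mL).
#' @return an \code{\link{effect_spec}}.
#' @export
demo_effect_spec <- function(noise_sigma = 0.05, baseline = 10) {
  baselines <- stats::setNames(rep(baseline, length(pam_metabolites())),
                               pam_metabolites())
  effects <- rbind(
    planted_effect("3-HPPA", "BL15707", 0.5),
    planted_effect("DHVL", c("BL15707", "Ls126D10"), 2.0),
    planted_effect("3-HPVA", c("BL15707", "Lp126A7", "Ls126D10"), 5.0))
  effect_spec(baselines, effects, noise_sigma = noise_sigma)
}

# 0/1 activity of each planted subset across design rows
effect_activity <- function(design, spec) {
  x <- dose_matrix(design)
  vapply(seq_len(nrow(spec$effects)), function(i) {
    members <- spec$effects$probiotics[[i]]
    as.numeric(rowSums(x[, members, drop = FALSE] > 0) == length(members))
  }, numeric(nrow(x)))
}

#' Generate a synthetic metabolite panel
#'
#' Expected concentration for row \eqn{i}, metabolite \eqn{j}:
#' \deqn{\mu_{ij} = r_j (1 + \sum_{T active in i} e_T)}
#' (or \eqn{r_j \prod (1 + e_T)} under multiplicative combination), where a
#' planted subset \eqn{T} is active iff every member strain has dose > 0 in
#' the row. Observed values are \eqn{\mu_{ij} \epsilon_{ij}} with
#' \eqn{\epsilon = \exp N(-\sigma^2/2, \sigma^2)}, so \eqn{E[\epsilon] = 1};
#' values are clipped at 0. Reproducible for a fixed seed.
#'
#' @param design a \code{\link{combination_design}}.
#' @param spec an \code{\link{effect_spec}}; its metabolites and strains
#'   are validated against the design.
#' @param seed integer seed for the noise draws.
#' @return a \code{\link{metabolite_panel}}.
#' @export
generate_panel <- function(design, spec, seed = 1L) {
  if (!inherits(spec, "effect_spec")) stop("spec must be an effect_spec")
  x <- dose_matrix(design)
  if (nrow(spec$effects)) {
    unknown <- setdiff(unique(unlist(spec$effects$probiotics)),
                       probiotic_ids(design))
    if (length(unknown))
      stop("effect spec names probiotics absent from the design: ",
           paste(unknown, collapse = ", "))
  }
  ids <- names(spec$baselines)
  n <- nrow(x)
  mu <- matrix(rep(spec$baselines, each = n), n, length(ids),
               dimnames = list(NULL, ids))
  if (nrow(spec$effects)) {
    act <- effect_activity(design, spec)
    for (i in seq_len(nrow(spec$effects))) {
      j <- spec$effects$metabolite[i]
      f <- if (spec$combine == "additive")
        act[, i] * spec$effects$effect[i]
      else (1 + spec$effects$effect[i])^act[, i] - 1
      if (spec$combine == "additive") {
        mu[, j] <- mu[, j] + spec$baselines[j] * f
      } else {
        mu[, j] <- mu[, j] * (1 + f)
      }
    }
    bad <- which(mu <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("planted effects drive expected concentration <= 0 in ",
           "combination ", design$combination_id[bad[1, 1]],
           " for metabolite ", ids[bad[1, 2]])
  }
  sigma <- spec$noise_sigma
  if (sigma > 0) {
    set.seed(as.integer(seed))
    eps <- matrix(exp(stats::rnorm(n * length(ids), -sigma^2 / 2, sigma)),
                  n, length(ids))
    mu <- mu * eps
  }
  metabolite_panel(design, pmax(mu, 0))
}

#' Ground-truth synergy report for a planted effect specification
#'
#' Converts planted effects to the report the pipeline should recover: each
#' (metabolite, subset, e) becomes a term with percentage \eqn{100 e};
#' metabolites without effects are masked; reference levels equal the
#' baselines. Comparable field-by-field with pipeline output.
#'
#' @param spec an \code{\link{effect_spec}}.
#' @return a \code{"synergy_report"}.
#' @export
ground_truth_report <- function(spec) {
  ids <- names(spec$baselines)
  if (nrow(spec$effects)) {
    terms <- data.frame(
      metabolite = spec$effects$metabolite,
      term_label = vapply(spec$effects$probiotics, subset_label,
                          character(1)),
      degree = lengths(spec$effects$probiotics),
      coefficient = spec$baselines[spec$effects$metabolite] *
        spec$effects$effect,
      percentage = 100 * spec$effects$effect,
      stringsAsFactors = FALSE)
    terms <- terms[order(terms$degree, terms$term_label), ]
    rownames(terms) <- NULL
  } else {
    terms <- data.frame(metabolite = character(), term_label = character(),
                        degree = integer(), coefficient = numeric(),
                        percentage = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(terms = terms,
                 metabolite_ids = ids,
                 masked_metabolites = setdiff(ids, terms$metabolite),
                 degenerate_metabolites = character(),
                 reference_levels = spec$baselines),
            class = "synergy_report")
}

#' Check identifiability of planted effects under a design
#'
#' A planted subset is recoverable only if its activity pattern across the
#' design's rows (a) varies, and (b) is not reproduced by any other
#' probiotic subset of the same or smaller size -- otherwise the model
#' selection step, which prefers simpler terms, can legitimately return a
#' different subset. Confounded effects should be excluded from
#' exact-recovery assertions.
#'
#' @param design a \code{\link{combination_design}}.
#' @param spec an \code{\link{effect_spec}}.
#' @param max_size largest alternative subset size considered (default 3).
#' @return logical vector, one entry per effect row: \code{TRUE} if
#'   identifiable.
#' @export
check_identifiability <- function(design, spec, max_size = 3L) {
  if (!nrow(spec$effects)) return(logical())
  x <- dose_matrix(design) > 0
  ids <- probiotic_ids(design)
  patterns <- list()  # label -> activity pattern for all subsets size<=max
  sizes <- integer()
  for (s in seq_len(max_size)) {
    for (cols in utils::combn(length(ids), s, simplify = FALSE)) {
      key <- paste(ids[cols], collapse = "+")
      patterns[[key]] <- rowSums(x[, cols, drop = FALSE]) == s
      sizes[key] <- s
    }
  }
  vapply(seq_len(nrow(spec$effects)), function(i) {
    members <- sort(spec$effects$probiotics[[i]])
    key <- paste(members, collapse = "+")
    p <- patterns[[key]]
    if (is.null(p) || !any(p) || all(p)) return(FALSE)
    for (other in names(patterns)) {
      if (other == key) next
      if (sizes[other] <= sizes[key] && identical(patterns[[other]], p))
        return(FALSE)
    }
    TRUE
  }, logical(1))
}
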