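test_that("default design is 6 probiotics x 12 combinations x 3 replicates", {
  d <- generate_design()
  expect_identical(nrow(d), 36L)
  expect_identical(length(probiotic_ids(d)), 6L)
  expect_identical(length(unique(d$combination_id)), 12L)
  expect_true(all(table(d$combination_id) == 3L))
  # member strains at dose 1, all others 0
  X <- dose_matrix(d)
  combos <- default_combinations()
  for (nm in names(combos)) {
    row <- X[match(nm, d$combination_id), ]
    expect_setequal(names(row)[row > 0], combos[[nm]])
    expect_true(all(row %in% c(0, 1)))
  }
})

test_that("design generation is deterministic and validates subsets", {
  d1 <- generate_design()
  d2 <- generate_design()
  expect_identical(d1, d2)

  ref <- generate_design(combinations = list(NONE = character()),
                         replicates = 1)
  expect_identical(nrow(ref), 1L)
  expect_true(all(dose_matrix(ref) == 0))

  withref <- generate_design(include_reference = TRUE)
  expect_identical(nrow(withref), 39L)
  expect_true("BDPP" %in% withref$combination_id)

  expect_error(generate_design(combinations = list(BAD = "NotAStrain")),
               "unknown probiotic")
})

test_that("noiseless panels equal baseline times planted factors", {
  d <- generate_design()
  baselines <- stats::setNames(c(10, 4), c("M1", "M2"))
  spec <- effect_spec(baselines,
                      planted_effect("M2", "Lp793", 0.5),
                      noise_sigma = 0)
  panel <- generate_panel(d, spec)
  vals <- panel_matrix(panel)
  expect_true(all(vals[, "M1"] == 10))
  has_a <- dose_matrix(d)[, "Lp793"] > 0
  expect_true(all(vals[has_a, "M2"] == 6))
  expect_true(all(vals[!has_a, "M2"] == 4))
})

test_that("lognormal noise has unit mean (Monte-Carlo)", {
  d <- generate_design(combinations = list(C1 = c("Lp793", "BL15707")),
                       replicates = 1000)
  baselines <- c(M1 = 20)
  spec <- effect_spec(baselines,
                      planted_effect("M1", "Lp793", 0.5),
                      noise_sigma = 0.1)
  panel <- generate_panel(d, spec, seed = 123)
  y <- panel_matrix(panel)[, 1]
  mu <- 20 * 1.5
  se <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - mu), 3 * se)
})

test_that("panel generation is reproducible for a fixed seed", {
  d <- generate_design()
  spec <- demo_effect_spec()
  p1 <- generate_panel(d, spec, seed = 42)
  p2 <- generate_panel(d, spec, seed = 42)
  p3 <- generate_panel(d, spec, seed = 43)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("effects that drive concentrations non-positive are rejected", {
  d <- generate_design()
  baselines <- c(M1 = 10)
  spec <- effect_spec(baselines, rbind(
    planted_effect("M1", "BL15707", -0.6),
    planted_effect("M1", "Ls126D10", -0.6)))
  # both active in combination C07 (BL15707 + Ls126D10): 1 - 1.2 < 0
  expect_error(generate_panel(d, spec), "<= 0")
  expect_error(effect_spec(baselines,
                           planted_effect("M1", "Lp793", -1.5)),
               "> -1")
})

test_that("ground-truth report mirrors the planted effects", {
  spec <- demo_effect_spec()
  truth <- ground_truth_report(spec)
  expect_identical(nrow(truth$terms), 3L)
  expect_equal(report_pct(truth, "3-HPPA", "BL15707"), 50)
  expect_equal(report_pct(truth, "DHVL", "BL15707 × Ls126D10"), 200)
  expect_equal(report_pct(truth, "3-HPVA",
                          "BL15707 × Lp126A7 × Ls126D10"), 500)
  expect_identical(length(truth$masked_metabolites), 41L)

  empty <- ground_truth_report(effect_spec(c(M1 = 5)))
  expect_identical(nrow(empty$terms), 0L)
  expect_identical(empty$masked_metabolites, "M1")

  neg <- ground_truth_report(
    effect_spec(c(M1 = 5), planted_effect("M1", "A", -0.3)))
  expect_equal(neg$terms$percentage, -30)
})

test_that("identifiability checker flags confounded planted subsets", {
  d <- generate_design()
  spec <- demo_effect_spec()
  expect_true(all(check_identifiability(d, spec)))

  # drop the Lp126A7+Ls126D10 pair: that sub-pair of the triple now occurs
  # only inside the triple, so the planted triple is confounded with it
  combos <- default_combinations()
  combos[["C09"]] <- NULL
  d_conf <- generate_design(combinations = combos)
  flags <- check_identifiability(d_conf, spec)
  names(flags) <- spec$effects$metabolite
  expect_true(flags[["3-HPPA"]])
  expect_true(flags[["DHVL"]])
  expect_false(flags[["3-HPVA"]])

  # an effect on a never-dosed strain has a constant activity pattern
  d_small <- generate_design(combinations = list(C1 = "Lp793"),
                             replicates = 2)
  spec_dead <- effect_spec(c(M1 = 10),
                           planted_effect("M1", "BL15707", 1.0))
  expect_false(any(check_identifiability(d_small, spec_dead)))
})

test_that("multiplicative effect combination compounds planted fractions", {
  d <- generate_design()
  baselines <- c(M1 = 10)
  spec <- effect_spec(baselines, rbind(
    planted_effect("M1", "BL15707", 0.5),
    planted_effect("M1", "Ls126D10", 1.0)),
    noise_sigma = 0, combine = "multiplicative")
  vals <- panel_matrix(generate_panel(d, spec))[, 1]
  both <- dose_matrix(d)[, "BL15707"] > 0 & dose_matrix(d)[, "Ls126D10"] > 0
  expect_true(all(vals[both] == 10 * 1.5 * 2.0))
})
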