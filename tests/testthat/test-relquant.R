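make_ct <- function() {
  data.frame(
    sample_id = rep(c("S1", "S2", "S3"), each = 2),
    target_id = rep(c("16S", "Firmicutes"), times = 3),
    ct = c(15.0, 22.0,   # S1: dCt = 7
           15.5, 21.5,   # S2: dCt = 6
           14.0, 23.5))  # S3: dCt = 9.5
}

test_that("the reference sample maps to exactly 1", {
  tab <- ct_table(make_ct(), normalizer_target = "16S",
                  reference_sample = "S1")
  fc <- delta_delta_ct(tab, "Firmicutes")
  expect_identical(unname(fc["S1"]), 1)
})

test_that("a one-cycle Ct drop with fixed normalizer doubles the fold", {
  tab <- ct_table(make_ct(), normalizer_target = "16S",
                  reference_sample = "S1")
  fc <- delta_delta_ct(tab, "Firmicutes")
  # S2: ddCt = 6 - 7 = -1 -> 2
  expect_identical(unname(fc["S2"]), 2)
})

test_that("a hand-computed three-sample table matches to 1e-12", {
  tab <- ct_table(make_ct(), normalizer_target = "16S",
                  reference_sample = "S1")
  fc <- delta_delta_ct(tab, "Firmicutes")
  # by hand: dCt = (7, 6, 9.5); ddCt = (0, -1, 2.5)
  want <- c(S1 = 2^0, S2 = 2^1, S3 = 2^-2.5)
  expect_equal(fc[names(want)], want, tolerance = 1e-12)
  expect_true(all(fc > 0))
})

test_that("shifting all Ct values of a sample cancels in the fold change", {
  d <- make_ct()
  d$ct[d$sample_id == "S3"] <- d$ct[d$sample_id == "S3"] + 4.2
  tab <- ct_table(d, "16S", "S1")
  fc <- delta_delta_ct(tab, "Firmicutes")
  ref <- delta_delta_ct(ct_table(make_ct(), "16S", "S1"), "Firmicutes")
  expect_equal(fc, ref, tolerance = 1e-12)
})

test_that("technical replicates are averaged on the Ct scale", {
  d <- rbind(make_ct(),
             data.frame(sample_id = "S2", target_id = "Firmicutes",
                        ct = 23.5))  # S2 target becomes mean(21.5, 23.5)=22.5
  tab <- ct_table(d, "16S", "S1")
  fc <- delta_delta_ct(tab, "Firmicutes")
  expect_identical(unname(fc["S2"]), 2^-(22.5 - 15.5 - 7))
})

test_that("missing normalizer or reference entries are reported by key", {
  d <- make_ct()
  d <- d[!(d$sample_id == "S2" & d$target_id == "16S"), ]
  tab <- ct_table(d, "16S", "S1")
  expect_error(delta_delta_ct(tab, "Firmicutes"), "S2")

  d2 <- make_ct()
  d2 <- d2[!(d2$sample_id == "S1" & d2$target_id == "Firmicutes"), ]
  tab2 <- ct_table(d2, "16S", "S1")
  expect_error(delta_delta_ct(tab2, "Firmicutes"), "reference sample")

  expect_error(ct_table(make_ct(), "NoSuchAssay", "S1"), "normalizer")
  expect_error(ct_table(make_ct(), "16S", "S9"), "reference")
  expect_error(delta_delta_ct(ct_table(make_ct(), "16S", "S1"), "NoTarget"),
               "no Ct records")
})
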