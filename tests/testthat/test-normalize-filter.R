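test_that("3-SD control-outlier rule is single-pass and conserves wells", {
  tight <- c(A23 = 1000, B23 = 1010, C23 = 990, D23 = 1005)
  r <- remove_control_outliers(tight)
  expect_length(r$removed, 0L)
  expect_identical(r$retained, tight)
  # zero variance: nothing can exceed 0
  flat <- c(A23 = 100, B23 = 100, C23 = 100, D23 = 100)
  expect_length(remove_control_outliers(flat)$removed, 0L)
  # a lone gross outlier cannot exceed 3 sd in small groups: the max
  # standardized deviation among n values is (n-1)/sqrt(n), below 3 for
  # n <= 10, so 12 clean wells + one at 10 are needed for a removal
  set.seed(1)
  x9 <- c(round(rnorm(8, 1000, 10)), 10)
  names(x9) <- paste0(LETTERS[1:9], 23)
  expect_length(remove_control_outliers(x9)$removed, 0L)
  x <- c(round(rnorm(12, 1000, 10)), 10)
  names(x) <- paste0(LETTERS[1:13], 23)
  m <- mean(x); s <- sd(x)            # independent single-pass oracle
  expect_identical(names(x)[abs(x - m) > 3 * s], "M23")
  r2 <- remove_control_outliers(x)
  expect_identical(r2$removed, x["M23"])
  expect_length(r2$retained, 12L)
  expect_identical(sort(c(names(r2$retained), names(r2$removed))),
                   sort(names(x)))
  expect_error(remove_control_outliers(c(1, 2)), "at least 3")
})

test_that("plates normalize to the retained DMSO mean", {
  p <- mini_plate(c(A1 = 250, A2 = 1000, B1 = 500, B2 = 2000,
                    A23 = 1000, B23 = 1000, C23 = 1000, D23 = 1000))
  np <- normalize_plate(p, mini_layout())
  expect_equal(unname(np$normalized["A1"]), 0.25)
  expect_equal(unname(np$normalized["B2"]), 2)
  expect_equal(np$control_summary$mean, 1000)
  # retained DMSO wells average exactly 1
  ctrl <- np$normalized[c("A23", "B23", "C23", "D23")]
  expect_equal(mean(ctrl), 1)
})

test_that("flagged wells leave the analysis before anything else", {
  p <- mini_plate(c(A1 = 250, A2 = 500, B1 = 500, B2 = 500,
                    A23 = 10, B23 = 1000, C23 = 1000, D23 = 1000),
                  flags = list(A23 = "low_control", A2 = "artefact"))
  np <- normalize_plate(p, mini_layout())
  # flagged control never enters the mean; flagged compound well absent
  expect_equal(np$control_summary$mean, 1000)
  expect_equal(np$control_summary$n_retained, 3L)
  expect_false("A2" %in% names(np$normalized))
  expect_false("A23" %in% names(np$normalized))
  # all controls flagged -> normalization error
  p2 <- mini_plate(c(A1 = 250, A23 = 1000, B23 = 1000, C23 = 1000,
                     D23 = 1000),
                   flags = stats::setNames(rep(list("artefact"), 4),
                                           paste0(LETTERS[1:4], 23)))
  expect_error(normalize_plate(p2, mini_layout()), "DMSO")
})

test_that("normalizing an already-normalized plate is the identity", {
  p <- mini_plate(c(A1 = 250, A2 = 1000, B1 = 500, B2 = 2000,
                    A23 = 1000, B23 = 1000, C23 = 1000, D23 = 1000))
  np1 <- normalize_plate(p, mini_layout())
  p2 <- mini_plate(np1$normalized)
  np2 <- normalize_plate(p2, mini_layout())
  expect_equal(np2$normalized, np1$normalized)
})

test_that("layout mismatches are refused", {
  p <- mini_plate(c(A1 = 1), layout_id = "other")
  expect_error(normalize_plate(p, mini_layout()), "other")
})

test_that("vehicle-toxicity triage is strict at 0.5 and conserves compounds", {
  df <- data.frame(
    compound_id = c("a", "b", "c", "d"),
    cell_line = "1455",
    viability = c(0.49, 0.5, 1.1, NA))
  r <- vehicle_toxicity_filter(df)
  expect_identical(r$excluded$compound_id, "a")
  expect_identical(sort(r$retained$compound_id), c("b", "c"))
  expect_identical(r$unevaluable$compound_id, "d")
  expect_equal(nrow(r$retained) + nrow(r$excluded) + nrow(r$unevaluable),
               nrow(df))
  # per-line decisions: same compound can pass in one line only
  df2 <- data.frame(compound_id = "a", cell_line = c("1455", "1458"),
                    viability = c(0.4, 0.9))
  r2 <- vehicle_toxicity_filter(df2)
  expect_equal(r2$excluded$cell_line, "1455")
  expect_equal(r2$retained$cell_line, "1458")
  # replicate vehicle wells use their mean
  df3 <- data.frame(compound_id = "a", cell_line = "1455",
                    viability = c(0.4, 0.8))
  expect_equal(nrow(vehicle_toxicity_filter(df3)$retained), 1L)
})

test_that("noise-free screen excludes exactly the programmed toxic set", {
  cfg <- generator_config(n_library_plates = 2L, compounds_per_plate = 100L,
                          well_noise_cv = 0, toxic_fraction = 0.1,
                          hit_fraction = 0, seed = 21)
  ds <- simulate_primary_screen(cfg)
  res <- run_primary_screen(ds, threshold = 70)
  truth_toxic <- unique(ds$truth$compound_id[ds$truth$is_toxic])
  expect_identical(sort(unique(res$toxicity$excluded$compound_id)),
                   sort(truth_toxic))
})
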