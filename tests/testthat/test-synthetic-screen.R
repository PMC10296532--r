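test_that("identical configs give identical datasets", {
  a <- simulate_primary_screen(tiny_config(seed = 11))
  b <- simulate_primary_screen(tiny_config(seed = 11))
  expect_identical(lapply(a$plates, `[[`, "counts"),
                   lapply(b$plates, `[[`, "counts"))
  expect_identical(a$truth, b$truth)
  c <- simulate_primary_screen(tiny_config(seed = 12))
  expect_false(identical(a$plates[[1]]$counts, c$plates[[1]]$counts))
})

test_that("generator config rejects impossible parameters", {
  expect_error(generator_config(compounds_per_plate = 400), "352")
  expect_error(generator_config(toxic_fraction = 1.2))
  expect_error(generator_config(well_noise_cv = -1))
})

test_that("noise-free null screen normalizes to exactly 1 in both conditions", {
  ds <- simulate_primary_screen(null_config())
  for (p in ds$plates) {
    np <- normalize_plate(p, ds$layouts[[p$layout_id]])
    lay <- ds$layouts[[p$layout_id]]
    lib <- lay$well[lay$role == "library_compound"]
    expect_identical(unname(np$normalized[lib]), rep(1, length(lib)))
  }
})

test_that("programmed effects are recovered through normalization", {
  # noise-free, with toxicity and hits: normalized values match the
  # truth ledger up to integer count rounding
  cfg <- generator_config(n_library_plates = 1L, compounds_per_plate = 100L,
                          well_noise_cv = 0, toxic_fraction = 0.2,
                          hit_fraction = 0.1, seed = 3)
  ds <- simulate_primary_screen(cfg)
  tr <- ds$truth
  for (i in seq_len(nrow(ds$pairing))) {
    pr <- ds$pairing[i, ]
    lay <- ds$layouts[[pr$layout_id]]
    lib <- lay[lay$role == "library_compound", ]
    v <- normalize_plate(ds$plates[[pr$vehicle_plate]], lay)$normalized
    e <- normalize_plate(ds$plates[[pr$estrogen_plate]], lay)$normalized
    t_i <- tr[tr$cell_line == pr$cell_line, ]
    j <- match(lib$compound_id, t_i$compound_id)
    expect_equal(unname(v[lib$well]), t_i$vehicle_effect[j],
                 tolerance = 2e-3)
    expect_equal(unname(e[lib$well]), t_i$estrogen_effect[j],
                 tolerance = 2e-3)
  }
})

test_that("true hit counts follow the configured binomial rate", {
  cfg <- generator_config(n_library_plates = 9L, compounds_per_plate = 334L,
                          hit_fraction = 0.015, seed = 7)  # 3006 compounds
  ds <- simulate_primary_screen(cfg)
  per_compound <- ds$truth[!duplicated(ds$truth$compound_id), ]
  n <- nrow(per_compound)
  k <- sum(per_compound$is_hit)
  expect_true(abs(k - n * 0.015) <= 3 * sqrt(n * 0.015 * 0.985))
  # hit status is a compound-level trait, identical across lines
  byline <- split(ds$truth$is_hit, ds$truth$cell_line)
  expect_identical(byline[[1]], byline[[2]])
})

test_that("truth ledger flags agree with the programmed effects", {
  ds <- simulate_primary_screen(tiny_config(seed = 5))
  tr <- ds$truth
  expect_identical(tr$vehicle_effect < 0.5, tr$is_toxic)
  expect_true(all(tr$true_edi[tr$is_hit] >= 75 & tr$true_edi[tr$is_hit] <= 98))
  expect_equal(tr$estrogen_effect,
               tr$vehicle_effect * (1 - tr$true_edi / 100))
})

test_that("confirmation doses are the exact 1:5 series from 10 uM", {
  expect_equal(confirmation_doses(), c(10, 2, 0.4, 0.08, 0.016))
})

test_that("confirmation screens have singlet + duplicate structure and are seeded", {
  tr <- data.frame(compound_id = "X", cell_line = "1455", top = 100,
                   bottom = 0, hill = 1, log10_ic50 = log10(0.4))
  cfg <- tiny_config(seed = 2)
  r1 <- simulate_confirmation_screen(tr, cfg)
  r2 <- simulate_confirmation_screen(tr, cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 15L)  # 5 doses x (1 + 2 replicates)
  expect_equal(as.integer(table(r1$screen)), c(5L, 10L))
  # zero noise: responses equal the 4PL exactly; response at the IC50 is 50
  cfg0 <- tiny_config(); cfg0$well_noise_cv <- 0
  r0 <- simulate_confirmation_screen(tr, cfg0)
  expect_equal(r0$response_pct,
               four_pl(r0$dose_uM, 0, 100, 1, log10(0.4)))
  expect_equal(unique(r0$response_pct[r0$dose_uM == 0.4]), 50)
})

test_that("QC titrations run the 10-point 1:2 series from 50 uM", {
  prof <- list(panobinostat = list(
    vehicle = list(top = 100, bottom = 5, hill = 1, log10_ic50 = log10(0.5)),
    estrogen = list(top = 100, bottom = 5, hill = 1, log10_ic50 = log10(0.5))))
  cfg <- tiny_config(); cfg$well_noise_cv <- 0
  tt <- simulate_qc_titration(cfg, prof)
  expect_equal(sort(unique(tt$dose_uM)), sort(50 * 2^-(0:9)))
  expect_equal(max(unique(tt$dose_uM)), 50)
  expect_equal(min(unique(tt$dose_uM)), 50 / 2^9, tolerance = 1e-12)
  expect_equal(nrow(tt), 10L * 3L * 2L)
  # an inhibitor with IC50 well below 10 uM is far below 30% of top at 10 uM
  at10 <- tt$response_pct[tt$dose_uM == 10 & tt$condition == "estrogen"]
  expect_true(all(at10 < 30))
  # zero noise reproduces the 4PL exactly
  expect_equal(tt$response_pct,
               four_pl(tt$dose_uM, 5, 100, 1, log10(0.5)))
})
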