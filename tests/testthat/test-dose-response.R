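test_that("4PL evaluates midpoint, asymptotes and plain arithmetic", {
  expect_equal(four_pl(0.4, 0, 100, 1, log10(0.4)), 50)
  expect_equal(four_pl(0.4, 20, 80, 2.3, log10(0.4)), 50)
  expect_equal(four_pl(1e-9, 0, 100, 1, 0), 100, tolerance = 1e-6)
  expect_equal(four_pl(1e9, 0, 100, 1, 0), 0, tolerance = 1e-6)
  expect_equal(four_pl(2, 0, 100, 1, log10(0.4)), 100 / 6)
  expect_error(four_pl(0, 0, 100, 1, 0), "> 0")
  # strictly decreasing in dose for h > 0, T > B
  y <- four_pl(10^seq(-3, 2, by = 0.25), 5, 95, 1.4, log10(0.3))
  expect_true(all(diff(y) < 0))
})

test_that("screens average duplicates first, then screens equally", {
  r <- data.frame(screen = c(1, 2, 2), replicate = c(1, 1, 2),
                  dose_uM = 1, response_pct = c(80, 60, 70))
  expect_equal(average_screens(r)$response_pct, 72.5)
  # identical screens -> identity
  r2 <- data.frame(screen = rep(1:2, each = 3), replicate = 1,
                   dose_uM = rep(c(10, 1, 0.1), 2),
                   response_pct = rep(c(90, 50, 10), 2))
  avg <- average_screens(r2)
  expect_equal(avg$response_pct, c(90, 50, 10))
  expect_equal(avg$dose_uM, c(10, 1, 0.1))
  # mismatched dose grids are an error
  r3 <- r2[-1, ]
  expect_error(average_screens(r3), "dose grids")
})

test_that("noise-free curves are recovered to machine precision", {
  doses <- confirmation_doses()
  for (ic in c(0.02, 0.4)) for (h in c(0.7, 2)) {
    y <- four_pl(doses, 0, 100, h, log10(ic))
    f <- fit_4pl(doses, y)
    expect_equal(f$ic50, ic, tolerance = 1e-6)
    expect_equal(f$h, h, tolerance = 1e-6)
    expect_equal(f$T, 100, tolerance = 1e-6)
    expect_lt(abs(f$B), 1e-4)
  }
})

test_that("fit is invariant to dose order and scales with the responses", {
  doses <- confirmation_doses()
  y <- four_pl(doses, 0, 100, 1.3, log10(0.3))
  f1 <- fit_4pl(doses, y)
  o <- c(3, 1, 5, 2, 4)
  f2 <- fit_4pl(doses[o], y[o])
  expect_equal(f2$ic50, f1$ic50, tolerance = 1e-8)
  # uniform response scaling moves T and B, not ic50 or h
  f3 <- fit_4pl(doses, 0.6 * y)
  expect_equal(f3$ic50, f1$ic50, tolerance = 1e-6)
  expect_equal(f3$h, f1$h, tolerance = 1e-6)
  expect_equal(f3$T, 60, tolerance = 1e-4)
})

test_that("flat series and insufficient inhibition are adjudicated, not fitted", {
  doses <- confirmation_doses()
  flat <- fit_4pl(doses, rep(100, 5))
  expect_equal(flat$status, "nd")
  expect_equal(flat$ic50_display, "ND")
  expect_match(flat$reason, "no dose dependence")
  # inhibited only to 80% of control at the top dose -> ">10"
  shallow <- four_pl(doses, 80, 100, 1, log10(1))
  f <- fit_4pl(doses, shallow)
  expect_equal(f$status, "above_range")
  expect_equal(f$ic50_display, ">10")
  expect_error(fit_4pl(c(1, 2, 3), c(1, 2, 3)), "at least 4")
})

test_that("IC50 below the dose range is reported but flagged extrapolated", {
  doses <- confirmation_doses()
  y <- four_pl(doses, 0, 100, 1, log10(0.002))
  f <- fit_4pl(doses, y)
  expect_equal(f$status, "extrapolated_low")
  expect_equal(f$ic50, 0.002, tolerance = 1e-4)
})

test_that("uncertain or narrow fits fall back to ND", {
  mk <- function(...) {
    structure(list(B = 0, T = 100, h = 1, log10_ic50 = log10(0.4),
                   ic50 = 0.4, rss = 1, se_log10_ic50 = 0.1,
                   converged = TRUE, status = "nd", reason = NULL,
                   ic50_display = "ND",
                   doses_uM = confirmation_doses(),
                   response_pct = c(5, 20, 50, 80, 95), ...),
              class = "dose_response_fit")
  }
  f <- mk(); f$se_log10_ic50 <- 1.5
  expect_equal(adjudicate_ic50(f)$status, "nd")
  f <- mk(); f$T <- 20            # span below 25 points
  expect_equal(adjudicate_ic50(f)$status, "nd")
  f <- mk(); f$converged <- FALSE
  expect_equal(adjudicate_ic50(f)$status, "nd")
  f <- mk()
  expect_equal(adjudicate_ic50(f)$status, "converged")
})

test_that("lead designation treats ND and > tokens as non-leads and partitions", {
  tab <- data.frame(
    compound_id = rep(c("a", "b", "c", "d"), each = 2),
    cell_line = rep(c("1455", "1458"), 4),
    ic50 = c("1.88", "0.96",   # second line only
             "0.02", "0.08",   # both
             "ND", "ND",       # neither
             ">20", "0.5"))    # ">" never leads, whatever the number
  lt <- designate_leads(tab)
  expect_equal(lt$category[lt$compound_id == "a"], "1458_only")
  expect_equal(lt$category[lt$compound_id == "b"], "both")
  expect_equal(lt$category[lt$compound_id == "c"], "neither")
  expect_equal(lt$category[lt$compound_id == "d"], "1458_only")
  cats <- categorize_leads(lt)
  expect_equal(cats$n_leads, 3)
  expect_equal(cats[["1455_only"]] + cats[["1458_only"]] + cats$both +
                 cats$neither, nrow(lt))
  # boundary: exactly 1 uM is a lead (<= cutoff)
  one <- designate_leads(data.frame(compound_id = "x", cell_line = "1455",
                                    ic50 = "1"))
  expect_true(one$lead)
})

test_that("the bundled confirmation outcomes give 17 leads split 4/6/7", {
  lt <- designate_leads(bundled_ic50())
  cats <- categorize_leads(lt)
  expect_equal(cats$n_leads, 17)
  expect_equal(cats[["1455_only"]], 4)
  expect_equal(cats[["1458_only"]], 6)
  expect_equal(cats$both, 7)
})
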