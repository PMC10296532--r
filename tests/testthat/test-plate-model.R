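test_that("well addresses parse, canonicalize and round-trip", {
  a <- parse_well_address(c("A1", "P24", "h12", " B3 "))
  expect_equal(a$well, c("A1", "P24", "H12", "B3"))
  expect_equal(a$row, c("A", "P", "H", "B"))
  expect_equal(a$column, c(1L, 24L, 12L, 3L))
  expect_equal(format_well_address(a$row, a$column), a$well)
  # every generated address satisfies the bounds
  w <- all_wells()
  expect_length(w, 384L)
  p <- parse_well_address(w)
  expect_true(all(p$row %in% LETTERS[1:16]))
  expect_true(all(p$column >= 1L & p$column <= 24L))
  expect_equal(p$well, w)
})

test_that("out-of-range and malformed addresses name the offender", {
  expect_error(parse_well_address("Q5"), "Q5")
  expect_error(parse_well_address("A25"), "A25")
  expect_error(parse_well_address("A0"), "A0")
  expect_error(parse_well_address("12A"), "malformed")
  expect_error(parse_well_address(""), "non-empty")
})

test_that("layouts validate roles, uniqueness and control placement", {
  lay <- make_library_layout("P1", sprintf("c%03d", 1:352))
  expect_s3_class(lay, "plate_layout")
  expect_equal(nrow(lay), 384L)
  expect_equal(sum(table(lay$role)), 384L)
  expect_equal(sum(lay$role == "library_compound"), 352L)
  expect_true(all(lay$concentration_uM[lay$role == "library_compound"] == 10))
  # control roles only in columns 23-24
  expect_true(all(lay$column[lay$role %in% c("vehicle_control",
    "media_control", "qc_positive", "qc_negative")] >= 23L))
  expect_error(make_library_layout("P1", sprintf("c%03d", 1:353)), "352")
  bad <- data.frame(well = "A5", role = "qc_positive",
                    compound_id = "x", concentration_uM = 10)
  expect_error(plate_layout("P1", bad), "columns 23-24")
  dup <- data.frame(well = c("A1", "A1"), role = "library_compound",
                    compound_id = c("x", "y"), concentration_uM = 10)
  expect_error(plate_layout("P1", dup), "duplicate")
  unk <- data.frame(well = "A1", role = "mystery",
                    compound_id = NA, concentration_uM = NA)
  expect_error(plate_layout("P1", unk), "unknown role")
})

test_that("layout CSV round-trips field-for-field and empty file works", {
  lay <- make_library_layout("P1", sprintf("c%03d", 1:100))
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_layout(lay, f)
  back <- read_plate_layout(f, plate_id = "P1")
  expect_equal(as.data.frame(back), as.data.frame(lay))
  # an empty layout file yields 384 empty wells
  writeLines("well,role,compound_id,concentration_uM", f)
  empty <- read_plate_layout(f)
  expect_equal(sum(empty$role == "empty"), 384L)
})

test_that("control-layout report passes the canonical block and itemizes deficits", {
  lay <- make_library_layout("P1", sprintf("c%03d", 1:10))
  rep <- validate_control_layout(lay)
  expect_true(rep$pass)
  expect_equal(rep$counts$dmso, 8L)
  expect_equal(rep$counts$media, 4L)
  expect_true(all(unlist(rep$counts$per_qc) == 4L))
  # remove one DMSO well -> deficit listed
  lay7 <- lay
  lay7$role[lay7$well == "A23"] <- "empty"
  rep7 <- validate_control_layout(lay7)
  expect_false(rep7$pass)
  expect_match(rep7$issues, "8 DMSO", all = FALSE)
  # no QC compounds at all -> fail
  none <- lay
  none$role[none$role %in% c("qc_positive", "qc_negative")] <- "empty"
  expect_false(validate_control_layout(none)$pass)
})

test_that("count tables group into plates, carry flags, and reject bad rows", {
  cfg <- tiny_config()
  ds <- simulate_primary_screen(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_table(ds$plates[1:2], f)
  back <- read_count_table(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$counts, ds$plates[[i]]$counts)
    expect_equal(back[[i]]$condition, ds$plates[[i]]$condition)
    expect_equal(back[[i]]$cell_line_id, ds$plates[[i]]$cell_line_id)
  }
  df <- utils::read.csv(f, colClasses = c(well = "character"))
  df$count[3] <- -5
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_count_table(f), "negative")
  df$count[3] <- 5; df$condition[4] <- "mock"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_count_table(f), "condition")
  df$condition[4] <- "vehicle"; df$well[5] <- df$well[4]
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_count_table(f), "repeated")
})

test_that("flag tokens are parsed as a set and flagged wells stay visible", {
  p <- mini_plate(c(A1 = 100, A23 = 1000, B23 = 990, C23 = 1010, D23 = 1000),
                  flags = list(A1 = c("acquisition_error", "artefact")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_count_table(list(p), f)
  back <- read_count_table(f)[[1]]
  expect_equal(sort(back$flags$A1), c("acquisition_error", "artefact"))
  expect_true("A1" %in% names(back$counts))
})

test_that("missing input files abort naming the path", {
  expect_error(read_count_table("no/such/counts.csv"), "no/such/counts.csv")
  expect_error(read_plate_layout("no/such/layout.csv"), "no/such/layout.csv")
})
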