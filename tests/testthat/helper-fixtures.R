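# Small fixtures built in code; nothing is read from disk except files
# the tests themselves write to tempdir().

# 2-plate, 50-compound noise-free-able config for fast end-to-end runs
tiny_config <- function(seed = 1L, n_library_plates = 2L,
                        compounds_per_plate = 50L, ...) {
  generator_config(n_library_plates = n_library_plates,
                   compounds_per_plate = compounds_per_plate,
                   seed = seed, ...)
}

# noise-free screen with no toxicity/hits/background spread: every
# compound well should normalize to exactly 1 in both conditions
null_config <- function(seed = 1L) {
  generator_config(n_library_plates = 1L, compounds_per_plate = 20L,
                   well_noise_cv = 0, toxic_fraction = 0, hit_fraction = 0,
                   background_inhibition_mean = 0,
                   background_inhibition_sd = 0, seed = seed)
}

# minimal hand-built plate: 4 DMSO controls and a few compound wells
mini_layout <- function(plate_id = "L1") {
  plate_layout(plate_id, data.frame(
    well = c("A1", "A2", "B1", "B2", "A23", "B23", "C23", "D23"),
    role = c(rep("library_compound", 4L), rep("vehicle_control", 4L)),
    compound_id = c("cmpA", "cmpB", "cmpC", "cmpD", rep(NA, 4L)),
    concentration_uM = c(rep(10, 4L), rep(NA, 4L)),
    stringsAsFactors = FALSE))
}

mini_plate <- function(counts, plate_id = "L1_x_vehicle", layout_id = "L1",
                       condition = "vehicle", flags = list()) {
  raw_plate(plate_id, layout_id, "1455", condition, counts, flags)
}

# a vector with exact mean m and exact sample sd s
with_moments <- function(x, m, s) {
  z <- (x - mean(x)) / stats::sd(x)
  m + s * z
}

bundled_ic50 <- function() {
  f <- system.file("extdata", "confirmation_ic50.csv",
                   package = "estroscreen")
  if (!nzchar(f)) f <- file.path("..", "..", "inst", "extdata",
                                 "confirmation_ic50.csv")
  read_ic50_table(f)
}
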