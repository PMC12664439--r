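test_that("chord length follows the circle-chord formula", {
  expect_equal(chord_length(c(-3.1, 0, 0), c(1, 0, 0), 3.1), 6.2)
  # tangent ray
  expect_equal(chord_length(c(3.1, 0, 0), c(0, 1, 0), 3.1), 0)
  # impact parameter 1 um on a 3.1 um sphere
  b <- 1
  entry <- c(-sqrt(3.1^2 - b^2), b, 0)
  expect_equal(chord_length(entry, c(1, 0, 0), 3.1), 2 * sqrt(3.1^2 - b^2))
  expect_equal(chord_length(entry, c(1, 0, 0), 3.1), 5.86856, tolerance = 1e-6)
  # outward ray warns and returns 0
  expect_warning(len <- chord_length(c(-3.1, 0, 0), c(-1, 0, 0), 3.1), "outward")
  expect_equal(len, 0)
  expect_error(chord_length(c(-1, 0, 0), c(1, 0, 0), 3.1), "surface")
})

test_that("alpha deposition counts follow the Poisson line process", {
  m <- fixed_model(density = 100)
  counts <- vapply(1:200, function(s) {
    nrow(generate_alpha_track(c(-3.1, 0, 0), c(1, 0, 0), 5, m, seed = s)$depositions)
  }, 0)
  expect_lt(abs(mean(counts) - 620), 3 * sqrt(620 / 200))
  # zero density: empty depositions but the chord is still reported
  m0 <- fixed_model(density = 0)
  g <- generate_alpha_track(c(-3.1, 0, 0), c(1, 0, 0), 5, m0, seed = 1)
  expect_equal(nrow(g$depositions), 0)
  expect_equal(g$chord_um, 6.2)
  # same-seed determinism
  g1 <- generate_alpha_track(c(-3.1, 0, 0), c(1, 0, 0), 5, m, seed = 7)
  g2 <- generate_alpha_track(c(-3.1, 0, 0), c(1, 0, 0), 5, m, seed = 7)
  expect_identical(g1, g2)
  expect_error(generate_alpha_track(c(-3.1, 0, 0), c(1, 0, 0), 99, m, seed = 1),
               "outside the model range")
})

test_that("electron tracks are sparse with the configured mean count", {
  m <- track_model("e-", 0.2, list(family = "fixed", value_eV = 60), c(0, 10))
  entry <- c(-2.5, sqrt(3.1^2 - 2.5^2), 0)  # chord 5 um along +x
  counts <- vapply(1:400, function(s) {
    nrow(generate_electron_track(entry, c(1, 0, 0), 1, m, seed = s))
  }, 0)
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 400))
  # tangent entry: zero-length chord, no depositions
  tang <- generate_electron_track(c(3.1, 0, 0), c(0, 0, 1), 1, m, seed = 2)
  expect_equal(nrow(tang), 0)
})

test_that("all depositions lie inside the nucleus and conserve track energy", {
  m <- alpha_track_model()
  ex <- generate_nucleus_exposure(50, list(m), seed = 21)
  r <- sqrt(ex$depositions$x_nm^2 + ex$depositions$y_nm^2 + ex$depositions$z_nm^2)
  expect_lte(max(r), 3.1 * 1000 * (1 + 1e-9))
  expect_gt(min(ex$depositions$edep_eV), 0)
  # per-track energy is the sum of its depositions (used by dosimetry)
  per_track <- tapply(ex$depositions$edep_eV, ex$depositions$track_id, sum)
  s <- score_exposure(ex, damage_parameters(), seed = 3)
  expect_equal(as.numeric(per_track[as.character(s$track_id[s$deposited_energy_eV > 0])]),
               s$deposited_energy_eV[s$deposited_energy_eV > 0])
})

test_that("exposures have one track per primary with chords bounded by the diameter", {
  m <- fixed_model(density = 1)
  ex <- generate_nucleus_exposure(1000, list(m), seed = 5)
  expect_equal(nrow(ex$tracks), 1000)
  expect_identical(sort(unique(ex$tracks$track_id)), 1:1000)
  expect_lte(max(ex$tracks$chord_um), 6.2)
  expect_gte(min(ex$tracks$chord_um), 0)
  expect_true(all(!is.na(ex$tracks$alpha_track_length_um)))
  # empty exposure
  ex0 <- generate_nucleus_exposure(0, list(m), seed = 5)
  expect_equal(nrow(ex0$tracks), 0)
  expect_equal(nrow(ex0$depositions), 0)
  # determinism of the whole exposure
  ex2 <- generate_nucleus_exposure(20, list(m), seed = 5)
  ex3 <- generate_nucleus_exposure(20, list(m), seed = 5)
  expect_identical(ex2$depositions, ex3$depositions)
  expect_identical(ex2$tracks, ex3$tracks)
})

test_that("mixture weights control the particle fractions", {
  ma <- track_model("alpha", 0, list(family = "fixed", value_eV = 60), c(0, 10))
  me <- track_model("e-", 0, list(family = "fixed", value_eV = 60), c(0, 10))
  ex <- generate_nucleus_exposure(10000, list(ma, me), weights = c(0.5, 0.5),
                                  seed = 8)
  frac <- mean(ex$tracks$particle == "alpha")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(generate_nucleus_exposure(10, list(), seed = 1), "Empty")
  expect_error(generate_nucleus_exposure(10, list(ma), weights = c(0.4),
                                         seed = 1), "sum to 1")
})

test_that("empirical deposition density converges to the model density", {
  m <- fixed_model(density = 50)
  total_len <- 0
  total_n <- 0
  for (s in 1:100) {
    g <- generate_alpha_track(c(-3.1, 0, 0), c(1, 0, 0), 5, m, seed = s)
    total_len <- total_len + g$chord_um
    total_n <- total_n + nrow(g$depositions)
  }
  lambda <- total_n / total_len
  expect_lt(abs(lambda - 50), 3 * sqrt(50 / total_len))
})

test_that("exposures round-trip through CSV", {
  m <- alpha_track_model()
  ex <- generate_nucleus_exposure(10, list(m), seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_exposure(ex, path)
  back <- read_exposure(path)
  expect_equal(as.data.frame(back$depositions), as.data.frame(ex$depositions))
  expect_equal(as.data.frame(back$tracks), as.data.frame(ex$tracks))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("x_nm,y_nm,z_nm,track_id,particle\n", bad)
  expect_error(read_exposure(bad), "edep_eV")
})
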