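placement <- place_cells(5, seed = 3)
ps <- toy_phase_space(placement, per_cell = 4)

test_that("phase-space construction validates records and metadata", {
  expect_s3_class(ps, "phase_space")
  expect_identical(ps_metadata(ps)$frame, "vial")
  bad <- as.data.frame(ps)
  bad$dx[1] <- 2  # not unit length
  expect_error(phase_space(bad, "Lu-177", 10), "unit length")
  bad2 <- as.data.frame(ps)
  bad2$weight[1] <- 0
  expect_error(phase_space(bad2, "Lu-177", 10), "Weights")
  expect_error(phase_space(as.data.frame(ps)[, -2], "Lu-177", 10), "ekin_MeV")
  expect_error(phase_space(as.data.frame(ps), "Lu-177", 0), "nt")
})

test_that("translation moves records to cell-local coordinates once, exactly", {
  local <- translate_to_cell_origin(ps, placement)
  expect_identical(ps_metadata(local)$frame, "cell-local")
  # records were generated on each cell surface: local radius is 3.75 um
  r <- sqrt(local$x_um^2 + local$y_um^2 + local$z_um^2)
  expect_equal(r, rep(3.75, nrow(local)))
  # a record exactly at its cell centre maps to the origin
  centre_rec <- as.data.frame(ps)[1, ]
  centre_rec$x_um <- placement$x_um[placement$cell_id == centre_rec$cell_id]
  centre_rec$y_um <- placement$y_um[placement$cell_id == centre_rec$cell_id]
  centre_rec$z_um <- placement$z_um[placement$cell_id == centre_rec$cell_id]
  one <- translate_to_cell_origin(
    phase_space(centre_rec, "Lu-177", 100), placement)
  expect_equal(c(one$x_um, one$y_um, one$z_um), c(0, 0, 0))
  # directions unchanged, frame guard, unknown cell
  expect_identical(local$dx, ps$dx)
  expect_error(translate_to_cell_origin(local, placement), "already cell-local")
  orphan <- as.data.frame(ps)
  orphan$cell_id <- 999L
  expect_error(
    translate_to_cell_origin(phase_space(orphan, "Lu-177", 100), placement),
    "999"
  )
})

test_that("translation preserves pairwise distances within a cell", {
  local <- translate_to_cell_origin(ps, placement)
  one_cell <- ps$cell_id == placement$cell_id[1]
  d_before <- dist(as.data.frame(ps)[one_cell, c("x_um", "y_um", "z_um")])
  d_after <- dist(as.data.frame(local)[one_cell, c("x_um", "y_um", "z_um")])
  expect_equal(as.numeric(d_before), as.numeric(d_after))
})

test_that("merging concatenates cell-local phase spaces with stable order", {
  local <- translate_to_cell_origin(ps, placement)
  a <- phase_space(as.data.frame(local)[1:8, ], "Lu-177", 100, "cell-local")
  b <- phase_space(as.data.frame(local)[9:20, ], "Lu-177", 100, "cell-local")
  m <- merge_phase_spaces(list(a, b))
  expect_equal(nrow(m), 20)
  expect_identical(m$event_id, c(a$event_id, b$event_id))
  expect_equal(as.data.frame(merge_phase_spaces(list(a))), as.data.frame(a))
  expect_error(merge_phase_spaces(list()), "non-empty")
  expect_error(merge_phase_spaces(list(a, ps)), "cell-local")
  c_other <- phase_space(as.data.frame(b), "Y-90", 100, "cell-local")
  expect_error(merge_phase_spaces(list(a, c_other)), "radionuclides")
})

test_that("anti-neutrino stripping removes exactly the anti-neutrinos", {
  local <- translate_to_cell_origin(ps, placement)
  df <- as.data.frame(local)
  df$name[1:5] <- c("anti_nu_e", "ANTI_NU_E", "nu_e-bar", "e-", "gamma")
  mixed <- phase_space(df, "Lu-177", 100, "cell-local")
  stripped <- strip_antineutrinos(mixed)
  expect_equal(nrow(stripped), nrow(mixed) - 3)
  expect_false(any(tolower(stripped$name) == "anti_nu_e"))
  # untouched when none present; empty output is valid
  expect_equal(nrow(strip_antineutrinos(stripped)), nrow(stripped))
  only_nu <- phase_space(
    transform(as.data.frame(local), name = "anti_nu_e"),
    "Lu-177", 100, "cell-local")
  expect_equal(nrow(strip_antineutrinos(only_nu)), 0)
})

test_that("merge and filter commute on record multisets", {
  local <- translate_to_cell_origin(ps, placement)
  df <- as.data.frame(local)
  df$name[seq(1, nrow(df), by = 3)] <- "anti_nu_e"
  a <- phase_space(df[1:10, ], "Lu-177", 100, "cell-local")
  b <- phase_space(df[11:20, ], "Lu-177", 100, "cell-local")
  merged_then <- strip_antineutrinos(merge_phase_spaces(list(a, b)))
  then_merged <- merge_phase_spaces(lapply(list(a, b), strip_antineutrinos))
  expect_equal(as.data.frame(merged_then), as.data.frame(then_merged))
})

test_that("phase-space CSV round-trip is lossless including metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_phase_space(ps, path)
  back <- read_phase_space(path)
  expect_equal(as.data.frame(back), as.data.frame(ps))
  expect_identical(ps_metadata(back), ps_metadata(ps))
  # read-then-translate composes with the translation op
  local <- translate_to_cell_origin(back, placement)
  expect_equal(sqrt(local$x_um^2 + local$y_um^2 + local$z_um^2),
               rep(3.75, nrow(local)))
})

test_that("schema violations are reported with the missing names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# radionuclide=X", "# nt=5", "# frame=vial",
               "name,ekin_MeV,x_um,y_um,z_um,dx,dy,weight,event_id,cell_id",
               "e-,1,0,0,0,1,0,1,1,1"), path)
  expect_error(read_phase_space(path), "dz")
  expect_error(write_phase_space(ps, tempfile(), format = "hdf5"), "csv")
})
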