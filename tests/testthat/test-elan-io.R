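test_that("a comma-delimited line file parses to an ordered raw line", {
  f <- write_line_file(file.path(tempdir(), "line 3.xl"),
                       "Time,P31,C12", c("0.0,10,5", "0.27,20,5"))
  rl <- parse_line_file(f)
  expect_s3_class(rl, "raw_line")
  expect_equal(rl$order_index, 3L)
  expect_equal(rl$times, c(0, 0.27))
  expect_setequal(names(rl$intensities), c("P31", "C12"))
  expect_equal(rl$intensities$P31, c(10, 20))
})

test_that("a single-point single-isotope file is the minimal valid case", {
  f <- write_line_file(file.path(tempdir(), "line 1.xl"),
                       "Time,Cu63", "0.0,7")
  rl <- parse_line_file(f)
  expect_equal(length(rl$times), 1L)
  expect_equal(rl$intensities, list(Cu63 = 7))
})

test_that("tab and semicolon delimiters and banner lines are handled", {
  f_tab <- write_line_file(file.path(tempdir(), "line 2.xl"),
                           "Time\t63Cu\t31P", c("0\t1\t2", "0.27\t3\t4"))
  rl <- parse_line_file(f_tab)
  expect_setequal(names(rl$intensities), c("Cu63", "P31"))

  f_semi <- write_line_file(
    file.path(tempdir(), "line 4.xl"),
    c("Instrument export banner", "acquired 2016-05-01",
      "Time;Cu63", "0;1", "0.27;2"), character(0))
  rl2 <- parse_line_file(f_semi)
  expect_equal(rl2$intensities$Cu63, c(1, 2))
})

test_that("format defects are reported with their location", {
  f <- write_line_file(file.path(tempdir(), "line 5.xl"),
                       "Time,Cu63", c("0,1", "0.27,2,9"))
  expect_error(parse_line_file(f), "row 2")
  f2 <- write_line_file(file.path(tempdir(), "line 6.xl"),
                        "Time,NotAnIsotope", "0,1")
  expect_error(parse_line_file(f2), "NotAnIsotope")
  expect_error(parse_line_file(file.path(tempdir(), "absent.xl")),
               "cannot read")
  f3 <- write_line_file(file.path(tempdir(), "line 7.xl"),
                        "Time,Cu63", c("0,1", "0.27,-5"))
  expect_warning(rl3 <- parse_line_file(f3), "clamped")
  expect_equal(rl3$intensities$Cu63, c(1, 0))
})

test_that("order is taken from the last digit run of the base name", {
  expect_equal(extract_order("line 10.xl"), 10L)
  expect_equal(extract_order("line 2.xl"), 2L)
  expect_equal(extract_order("sample7_line 3.xl"), 3L)
  expect_equal(extract_order("/some/dir/line 8.xl"), 8L)
  expect_error(extract_order("line.xl"), "no digits")
})

test_that("line files sort naturally by order, not lexically", {
  dir <- file.path(tempdir(), "natorder")
  dir.create(dir, showWarnings = FALSE)
  for (i in c(10L, 2L, 1L)) {
    write_line_file(file.path(dir, paste0("line ", i, ".xl")),
                    "Time,Cu63", sprintf("0,%d", i))
  }
  lines <- read_line_files(dir)
  expect_equal(vapply(lines, `[[`, integer(1L), "order_index"),
               c(1L, 2L, 10L))
})

test_that("mixed isotope sets across line files are rejected", {
  dir <- file.path(tempdir(), "mixiso")
  dir.create(dir, showWarnings = FALSE)
  write_line_file(file.path(dir, "line 1.xl"), "Time,Cu63", "0,1")
  write_line_file(file.path(dir, "line 2.xl"), "Time,P31", "0,1")
  expect_error(read_line_files(dir), "isotope sets")
})

test_that("parameters.conf parses with key variants and validates", {
  f <- file.path(tempdir(), "parameters.conf")
  writeLines(c("standard = C12", "Ablation.Speed: 10",
               "acquisition_time=0.270", "SPACE INTERVAL = 15"), f)
  p <- parse_parameters(f)
  expect_equal(p$standard, "C12")
  expect_equal(p$ablation_speed, 10)
  expect_equal(p$acquisition_time, 0.270)
  expect_equal(p$space_interval, 15)

  writeLines(c("standard=C12", "ablation.speed=10",
               "acquisition.time=1.5", "space.interval=15"), f)
  expect_warning(p2 <- parse_parameters(f), "1\\.0 s")
  expect_equal(p2$acquisition_time, 1.5)

  writeLines(c("standard=C12", "ablation.speed=10",
               "acquisition.time=0.27", "space.interval=0"), f)
  expect_error(parse_parameters(f), "positive")

  writeLines(c("standard=C12", "ablation.speed=10",
               "acquisition.time=0.27"), f)
  expect_error(parse_parameters(f), "space.interval")
})

test_that("positions records parse in file order, header optional", {
  f <- file.path(tempdir(), "positions.txt")
  writeLines(c("name\tx_start\ty_start\tx_end\ty_end",
               "line 1\t0\t0\t0\t500", "line 2\t0\t15\t0\t515"), f)
  pos <- parse_positions(f)
  expect_equal(nrow(pos), 2L)
  expect_equal(pos$line_index, c(1L, 2L))
  expect_true(all(pos$x_start == pos$x_end))

  writeLines(character(0), f)
  expect_equal(nrow(parse_positions(f)), 0L)

  writeLines(c("line 1 0 0 100 0", "line 2 0 fifteen 100 15"), f)
  expect_error(parse_positions(f), "record 2")
})

test_that("CSV round-trips are value-identical in every dialect", {
  m <- matrix(c(1.5, pi, 1/3, 1e-7, 123456.789, NA), nrow = 2)
  for (d in list(csv_dialect("excel"), csv_dialect("libreoffice"),
                 csv_dialect("custom", field_sep = ";",
                             decimal_sep = ","))) {
    f <- tempfile(fileext = ".csv")
    write_map_csv(m, f, d)
    back <- read_map_csv(f, d)
    expect_identical(unname(back), unname(m))
  }
})

test_that("dialects render the documented separators", {
  f <- tempfile(fileext = ".csv")
  write_map_csv(matrix(1.5), f, csv_dialect("excel"))
  expect_identical(readChar(f, file.size(f)), "1.5\r\n")
  write_map_csv(matrix(c(1.5, 2.5), nrow = 1), f,
                csv_dialect("custom", field_sep = ";", decimal_sep = ","))
  expect_identical(readChar(f, file.size(f)), "1,5;2,5\n")
  expect_error(csv_dialect("custom", field_sep = ",", decimal_sep = ","),
               "must differ")
})

test_that("sessions round-trip matrices bit-identically with settings", {
  sim <- simulate_dataset(phantom_spec(n_lines = 4, n_points = 6,
                                       noise_sd = 2, seed = 7),
                          out_dir = file.path(tempdir(), "sess_ds"))
  ds <- normalize_dataset(read_dataset(sim$dir))
  f <- tempfile(fileext = ".lai")
  settings <- list(interpolation = "high", range_mode = "custom",
                   v_min = 0.007, v_max = 0.025)
  save_session(ds, settings, f)
  sess <- load_session(f)
  for (iso in names(ds$maps)) {
    expect_identical(sess$dataset$maps[[iso]]$values,
                     unname(ds$maps[[iso]]$values))
    expect_true(sess$dataset$maps[[iso]]$normalized)
    expect_equal(sess$dataset$maps[[iso]]$standard, "C12")
  }
  expect_equal(sess$settings$interpolation, "high")
  expect_equal(sess$settings$v_min, 0.007)
  expect_equal(sess$settings$v_max, 0.025)
  expect_equal(sess$dataset$parameters$acquisition_time, 0.270)
})

test_that("corrupt or future-versioned session archives are refused", {
  f <- tempfile(fileext = ".lai")
  writeLines("not a tar archive", f)
  expect_error(load_session(f), "session archive")
  expect_error(load_session(tempfile()), "does not exist")

  # a well-formed archive with an unsupported version tag
  tmp <- file.path(tempdir(), "futuresess")
  dir.create(tmp, showWarnings = FALSE)
  jsonlite::write_json(list(format_version = "99.0"),
                       file.path(tmp, "session.json"), auto_unbox = TRUE)
  f2 <- file.path(tempdir(), "future.lai")
  old <- setwd(tmp); on.exit(setwd(old))
  utils::tar(f2, files = "session.json", tar = "internal")
  setwd(old)
  expect_error(load_session(f2), "supported versions: 1\\.0")
})
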