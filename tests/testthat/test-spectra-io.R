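test_that("spectrum construction canonicalizes and validates", {
  s <- ir_spectrum(c(1200, 1000, 1100), c(3, 1, 2), id = "x")
  expect_equal(s$wavenumbers, c(1000, 1100, 1200))
  expect_equal(s$absorbance, c(1, 2, 3))

  expect_error(ir_spectrum(c(1000, 1000), c(1, 2)), class = "ir_axis_error")
  expect_error(ir_spectrum(c(-5, 10), c(1, 2)), class = "ir_axis_error")
  expect_error(ir_spectrum(c(10, 20), c(1, NaN)), class = "ir_parse_error")
  expect_error(ir_spectrum(c(10, 20), c(1, Inf)), class = "ir_parse_error")
  expect_error(ir_spectrum(c(10, 20), c(1, 2, 3)), class = "ir_shape_error")
})

test_that("dataset invariants: shared axis, unique ids, finite values", {
  expect_error(ir_dataset(toy_axis(), matrix(1, 2, 5), ids = c("a", "a")),
               class = "ir_contract_error")
  m <- matrix(1, 2, 5); m[2, 3] <- NA
  expect_error(ir_dataset(toy_axis(), m, ids = c("a", "b")),
               class = "ir_parse_error")
  expect_error(ir_dataset(toy_axis(4), matrix(1, 2, 5)),
               class = "ir_shape_error")
})

test_that("CSV round trip preserves values in both orientations", {
  d <- toy_dataset(3L, toy_axis(5L))
  expect_equal(dim(d$matrix), c(3L, 5L))
  for (orient in c("columns", "rows")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_spectra_csv(d, path, orientation = orient)
    back <- read_spectra_csv(path, orientation = orient)
    expect_equal(back$axis, d$axis, tolerance = 1e-12)
    expect_equal(back$matrix, d$matrix, tolerance = 1e-12)
    expect_identical(back$ids, d$ids)
  }
})

test_that("descending-axis file reads as its ascending rewrite", {
  d <- toy_dataset(2L, toy_axis(6L))
  asc <- withr::local_tempfile(fileext = ".csv")
  desc <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(d, asc)
  # hand-build the descending-axis file by reversing data lines
  lines <- readLines(asc)
  writeLines(c(lines[1L], rev(lines[-1L])), desc)
  expect_equal(read_spectra_csv(desc), read_spectra_csv(asc))
})

test_that("CSV reader names the offending cell on parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,s1", "1000,0.5", "1010,oops"), path)
  expect_error(read_spectra_csv(path), "oops", class = "ir_parse_error")
  writeLines(c("wavenumber,s1", "1000,0.5", "1000,0.7"), path)
  expect_error(read_spectra_csv(path), class = "ir_axis_error")
})

test_that("JCAMP fixture with YFACTOR scales absorbances", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=toy", "##JCAMP-DX=4.24",
               "##FIRSTX=1000", "##LASTX=1004", "##NPOINTS=5",
               "##YFACTOR=0.001", "##XYDATA=(X++(Y..Y))",
               "1000 100 200 300", "1003 400 500", "##END="), path)
  s <- read_jcamp(path)
  expect_equal(s$wavenumbers, 1000:1004)
  expect_equal(s$absorbance, c(0.1, 0.2, 0.3, 0.4, 0.5))
})

test_that("JCAMP arithmetic axis from FIRSTX/LASTX/NPOINTS is uniform", {
  path <- withr::local_tempfile(fileext = ".jdx")
  n <- 3601L
  y <- paste(rep("1", n), collapse = " ")
  writeLines(c("##TITLE=axis", "##FIRSTX=400", "##LASTX=4000",
               sprintf("##NPOINTS=%d", n), "##XYDATA=(X++(Y..Y))",
               paste("400", y), "##END="), path)
  s <- read_jcamp(path)
  expect_equal(length(s$wavenumbers), n)
  expect_equal(unique(round(diff(s$wavenumbers), 9)), 1)
})

test_that("JCAMP write/read round trip on a synthetic spectrum", {
  axis <- seq(650, 1950, by = 1.0292)
  s <- water_reference(axis)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(s, path)
  back <- read_jcamp(path)
  expect_lt(max(abs(back$wavenumbers - s$wavenumbers)), 1e-9)
  expect_lt(max(abs(back$absorbance - s$absorbance)), 1e-9)
  expect_identical(back$id, s$id)
})

test_that("JCAMP rejects compressed dialects and NPOINTS mismatches", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=sqz", "##FIRSTX=1000", "##LASTX=1004",
               "##NPOINTS=5", "##XYDATA=(X++(Y..Y))",
               "1000 A00 B00 C00", "##END="), path)
  expect_error(read_jcamp(path), "SQZ", class = "ir_parse_error")
  writeLines(c("##TITLE=bad", "##FIRSTX=1000", "##LASTX=1004",
               "##NPOINTS=5", "##XYDATA=(X++(Y..Y))",
               "1000 1 2 3", "##END="), path)
  expect_error(read_jcamp(path), class = "ir_integrity_error")
})

test_that("resampling: identity, linear invariance, brute-force oracle", {
  axis <- toy_axis(20L)
  s <- ir_spectrum(axis, 2 * axis + 5)
  # identity axis -> exact passthrough
  expect_identical(resample_spectrum(s, axis)$absorbance, s$absorbance)
  # linear law preserved at arbitrary interior targets
  tgt <- c(1003.7, 1051.2, 1188.9)
  r <- resample_spectrum(s, tgt)
  expect_equal(r$absorbance, 2 * tgt + 5, tolerance = 1e-12)

  # random piecewise-linear spectrum vs an independent two-point oracle
  set.seed(3)
  y <- runif(20)
  sp <- ir_spectrum(axis, y)
  tgt <- sort(runif(15, min(axis), max(axis)))
  got <- resample_spectrum(sp, tgt)$absorbance
  oracle <- vapply(tgt, function(t) {
    i <- max(which(axis <= t))
    if (axis[i] == t) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (t - axis[i]) / (axis[i + 1] - axis[i])
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)

  # idempotence and refusal to extrapolate
  once <- resample_spectrum(sp, tgt)
  expect_identical(resample_spectrum(once, tgt)$absorbance, once$absorbance)
  expect_error(resample_spectrum(sp, c(999, 1500)), class = "ir_range_error")
})

test_that("results table round trip and formatting", {
  empty <- preclassify(toy_dataset(1L), get_spectrum(toy_dataset(1L), 1L),
                       threshold = 0.1)[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_preclass_tsv(empty, path)
  expect_identical(readLines(path), "id\ta\tb\trmse\tthreshold\tlabel")

  sim <- simulate_spectra(n_water = 2L, n_cartilage = 2L, seed = 5L)
  res <- preclassify(sim$dataset, water_reference(sim$dataset$axis),
                     threshold = 0.05, region = c(800, 1900))
  write_preclass_tsv(res, path)
  lines <- readLines(path)
  expect_length(lines, 5L)
  # numeric fields carry >= 10 significant digits
  expect_true(all(nchar(gsub("[^0-9]", "", strsplit(lines[2L], "\t")[[1L]][4L])) >= 10))
  back <- read_preclass_tsv(path)
  expect_equal(back$rmse, res$rmse, tolerance = 1e-9)
  expect_identical(back$label, res$label)
})
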