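small_session <- function(seed = 3L) {
  withr::with_seed(seed, {
    recording_session(array(rnorm(400 * 4 * 3), c(400, 4, 3)),
                      sampling_rate = 200, contraction_time = 1,
                      n_repetitions = 2L,
                      movement_names = c("open", "close", "rest"),
                      subject_id = "s01")
  })
}

test_that("session constructor derives dimensions and validates timing", {
  s <- small_session()
  expect_equal(s$channel_count, 4L)
  expect_equal(dim(s$samples)[1L], 2 * 1 * 200)  # reps x seconds x Hz
  expect_equal(s$rep_boundaries, c(1L, 201L))
  ## too few samples for the declared protocol
  expect_error(
    recording_session(array(0, c(100, 2, 1)), sampling_rate = 200,
                      contraction_time = 1, n_repetitions = 2L,
                      movement_names = "m"),
    class = "emgpr_data_error")
  ## non-finite samples
  bad <- array(0, c(40, 2, 1)); bad[5, 1, 1] <- NA
  expect_error(
    recording_session(bad, 10, 1, 2L, "m"),
    class = "emgpr_data_error")
  ## dimension mismatch against movement names
  expect_error(
    recording_session(array(0, c(40, 2, 2)), 10, 1, 2L, "only_one"),
    class = "emgpr_data_error")
})

test_that("fixture dialect round-trips a session bit-for-bit", {
  s <- small_session()
  dir <- withr::local_tempdir()
  write_session(s, dir, "fixture")
  s2 <- read_session(dir, "fixture")
  expect_identical(s2$samples, s$samples)
  expect_identical(s2$sampling_rate, s$sampling_rate)
  expect_identical(s2$contraction_time, s$contraction_time)
  expect_identical(s2$n_repetitions, s$n_repetitions)
  expect_identical(s2$movement_names, s$movement_names)
  expect_identical(s2$subject_id, s$subject_id)
  expect_identical(s2$rep_boundaries, s$rep_boundaries)
})

test_that("mat dialect round-trips a session", {
  s <- small_session(9L)
  f <- withr::local_tempfile(fileext = ".mat")
  write_session(s, f, "mat")
  s2 <- read_session(f, "mat")
  expect_equal(s2$samples, s$samples, tolerance = 1e-12)
  expect_identical(dim(s2$samples), dim(s$samples))
  expect_equal(s2$sampling_rate, s$sampling_rate)
  expect_identical(s2$movement_names, s$movement_names)
  expect_identical(s2$n_repetitions, s$n_repetitions)
})

test_that("a custom field map renames the MAT struct fields", {
  s <- small_session()
  fmap <- mat_field_map()
  fmap[["samples"]] <- "cdata"
  fmap[["sampling_rate"]] <- "fsamp"
  f <- withr::local_tempfile(fileext = ".mat")
  write_session(s, f, "mat", field_map = fmap)
  expect_error(read_session(f, "mat"), class = "emgpr_structural_error")
  s2 <- read_session(f, "mat", field_map = fmap)
  expect_equal(s2$samples, s$samples, tolerance = 1e-12)
})

test_that("structural problems are reported by field name", {
  s <- small_session()
  dir <- withr::local_tempdir()
  write_session(s, dir, "fixture")
  meta <- jsonlite::read_json(file.path(dir, "session.json"))
  meta$sampling_rate <- NULL
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE)
  expect_error(read_session(dir, "fixture"), "sampling_rate",
               class = "emgpr_structural_error")
})

test_that("writing an invalid session is refused", {
  s <- small_session()
  s$movement_names <- character(0)
  dir <- withr::local_tempdir()
  expect_error(write_session(s, file.path(dir, "x"), "fixture"),
               class = "emgpr_structural_error")
})

test_that("mat files interoperate with an independent MAT-file v5 reader", {
  s <- small_session(21L)
  f <- withr::local_tempfile(fileext = ".mat")
  write_session(s, f, "mat")
  py <- withr::local_tempfile(fileext = ".py")
  out <- withr::local_tempfile(fileext = ".mat")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from scipy.io import loadmat, savemat",
    "m = loadmat(sys.argv[1], squeeze_me=True, struct_as_record=False)",
    "m = m['recSession']",
    "assert float(m.sF) == 200.0",
    "td = m.tdata",
    "assert td.shape == (400, 4, 3)",
    sprintf("assert abs(td[0, 0, 0] - (%.17g)) < 1e-12", s$samples[1, 1, 1]),
    "names = [str(x) for x in m.mvnts]",
    "assert names == ['open', 'close', 'rest']",
    "savemat(sys.argv[2], {'recSession': {",
    "  'sF': 200.0, 'cT': 1.0, 'nR': 2.0, 'nCh': 4.0,",
    "  'mvnts': np.array(['open', 'close', 'rest'], dtype=object),",
    "  'tdata': td, 'sbj': 's01'}})",
    "print('OK')"), py)
  res <- system2("python", c(py, f, out), stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0L,
              info = paste(res, collapse = "\n"))
  expect_true(any(grepl("^OK$", res)))
  ## and a scipy-written container loads back through our reader
  s3 <- read_session(out, "mat")
  expect_equal(s3$samples, s$samples, tolerance = 1e-12)
  expect_identical(s3$movement_names, s$movement_names)
})
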