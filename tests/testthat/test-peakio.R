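test_that("peak series constructor enforces its invariants", {
  r <- residue_id(8, "PHE")
  expect_error(peak_series(r, "time_hr", c(1, 1, 2, 3), 1:4),
               "strictly increasing")
  expect_error(peak_series(r, "time_hr", c(3, 2, 1), 1:3),
               "strictly increasing")
  expect_error(peak_series(r, "time_hr", c(-1, 0, 1), 1:3), "non-negative")
  expect_error(peak_series(r, "time_hr", 1:4, 1:3), "same length")
  expect_error(peak_series(r, "banana", 1:3, 1:3))
  s <- peak_series(r, "urea_M", 0:5, rep(1, 6))
  expect_s3_class(s, "peak_series")
  expect_identical(s$residue$residue_code, "PHE")
})

test_that("tsv and sparky dialects round-trip on all fields", {
  tp <- c(0.5, 1, 2, 4, 8, 16, 24, 48)
  mk <- function(seq_no, code, k)
    peak_series(residue_id(seq_no, code), "time_hr", tp, 100 * exp(-k * tp))
  series <- list(mk(8, "PHE", 0.114), mk(12, "HIS", 0.038),
                 mk(124, "VAL", 0.36))
  for (dialect in c("tsv", "sparky_list")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_peak_series(series, path, dialect)
    back <- read_peak_series(path, dialect)
    expect_length(back, 3L)
    for (i in 1:3) {
      expect_identical(back[[i]]$residue$seq_number,
                       series[[i]]$residue$seq_number)
      expect_identical(back[[i]]$residue$residue_code,
                       series[[i]]$residue$residue_code)
      expect_equal(back[[i]]$axis_values, tp, tolerance = 1e-9)
      expect_equal(back[[i]]$values, series[[i]]$values, tolerance = 1e-9)
    }
    # second round trip is the identity on the file too
    path2 <- withr::local_tempfile(fileext = ".tsv")
    write_peak_series(back, path2, dialect)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("malformed rows are dropped with a warning, duplicates error", {
  path <- withr::local_tempfile()
  writeLines(c("# axis: time_hr 1 2 3 4",
               "8\tPHE\t10\t9\t8\t7",
               "9\tGLU\t10\tnot_a_number\t8\t7",
               "10\tARG\t5\t4\t3\t2"), path)
  expect_warning(out <- read_peak_series(path), "non-numeric")
  expect_length(out, 2L)
  expect_identical(vapply(out, function(s) s$residue$seq_number, integer(1)),
                   c(8L, 10L))
  writeLines(c("# axis: time_hr 1 2 3 4",
               "8\tPHE\t10\t9\t8\t7",
               "8\tPHE\t10\t9\t8\t7"), path)
  expect_error(read_peak_series(path), "duplicated")
  writeLines(c("no header here", "8\tPHE\t1\t2"), path)
  expect_error(read_peak_series(path), "malformed header")
})

test_that("hand-written PDB is parsed exactly and written back", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   PHE A   8      11.104  -2.334   5.000  1.00  0.00           N",
    "ATOM      2  CA  PHE A   8      12.560  -2.100   5.100  1.00  0.00           C",
    "ATOM      3  C   PHE A   8      13.000   0.000   0.250  1.00  0.00           C",
    "ATOM      4  O   PHE A   8      -1.500   3.125  99.999  1.00  0.00           O",
    "ATOM      5  H   PHE A   8       0.000   0.000   0.001  1.00  0.00           H"),
    path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 5L)
  expect_identical(m$atoms$atom_name, c("N", "CA", "C", "O", "H"))
  expect_identical(m$atoms$res_seq, rep(8L, 5))
  expect_equal(m$atoms$x, c(11.104, 12.560, 13.000, -1.500, 0.000))
  expect_equal(m$atoms$z[4], 99.999)
  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, out)
  m2 <- read_structure(out)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-9)
  expect_identical(m2$atoms$element, m$atoms$element)
})

test_that("multi-model files report model count and select models", {
  helix <- make_synthetic_helix(4)
  # build a real 3-model file through the writer; PDB stores 3 decimals,
  # so compare with an absolute 5e-4 bound
  path <- withr::local_tempfile(fileext = ".pdb")
  fr <- array(NA_real_, c(3, nrow(helix$atoms), 3))
  for (f in 1:3) fr[f, , ] <- ribodyn:::coords(helix) + (f - 1)
  write_trajectory_pdb(trajectory(helix, fr), path)
  m1 <- read_structure(path)
  expect_identical(attr(m1, "n_models"), 3L)
  expect_lt(max(abs(ribodyn:::coords(m1) - ribodyn:::coords(helix))), 6e-4)
  m3 <- read_structure(path, model = 3)
  expect_lt(max(abs(m3$atoms$x - (helix$atoms$x + 2))), 6e-4)
  back <- read_trajectory_pdb(path)
  expect_lt(max(abs(back$frames - fr)), 6e-4)
})

test_that("synthetic helix survives a structure round trip", {
  helix <- make_synthetic_helix(6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(helix, path)
  back <- read_structure(path)
  expect_identical(back$atoms$atom_name, helix$atoms$atom_name)
  expect_identical(back$atoms$res_seq, helix$atoms$res_seq)
  expect_lt(max(abs(ribodyn:::coords(back) - ribodyn:::coords(helix))), 6e-4)
  expect_setequal(unique(back$atoms$atom_name), c("N", "H", "CA", "C", "O"))
})

test_that("insertion codes and empty structures are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", path)
  expect_error(read_structure(path), "no ATOM records")
  writeLines(
    "ATOM      1  N   PHE A   8A     11.104  -2.334   5.000  1.00  0.00           N",
    path)
  expect_error(read_structure(path), "insertion codes")
})

test_that("relaxation tables round-trip and default errors to 2%", {
  rec <- relaxation_records(1:6, R1 = rep(2.1, 6), R2 = rep(11.1, 6),
                            NOE = rep(0.79, 6), field_MHz = 500.13)
  expect_equal(rec$R1_err, rep(0.042, 6))
  expect_match(paste(attr(rec, "error_policy"), collapse = " "), "R1_err=2%")
  path <- withr::local_tempfile()
  write_relaxation_table(rec, path)
  back <- read_relaxation_table(path, 500.13)
  expect_equal(back$R1, rec$R1)
  expect_equal(back$NOE_err, rec$NOE_err, tolerance = 1e-9)
  expect_error(relaxation_records(1:3, c(2, 2, 2), c(1, 11, 11),
                                  c(0.8, 0.8, 0.8), 500.13),
               "R2 < R1")
})
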