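test_that("CSV round trip preserves values and types", {
  rec <- make_records(6,
    species = c("AAAA", "BBBB"), count = c(3L, 5L),
    size_tl_cm = c(12.25, 7.123456), obs_type = c("I", "N"),
    replicateid = c(1L, 1L, 2L, 2L, 3L, 3L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spc_csv(rec, f)
  back <- read_spc_csv(f)
  expect_identical(back$species, rec$species)
  expect_identical(back$count, rec$count)
  expect_identical(back$sitevisitid, rec$sitevisitid)
  expect_identical(back$obs_type, rec$obs_type)
  expect_equal(back$size_tl_cm, rec$size_tl_cm, tolerance = 1e-6)
  expect_equal(back$lw_a, rec$lw_a, tolerance = 1e-6)
  # empty cells become NA
  rec$visibility_m <- NA_real_
  write_spc_csv(rec, f)
  expect_true(all(is.na(read_spc_csv(f)$visibility_m)))
})

test_that("header-only file reads as empty; missing mandatory column errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_spc_csv(make_records(0), f)
  expect_equal(nrow(read_spc_csv(f)), 0)

  rec <- make_records(2)
  rec$obs_type <- NULL
  write_spc_csv(rec, f)
  expect_error(read_spc_csv(f), "OBS_TYPE")

  # unknown columns are kept with a warning, not dropped
  rec <- make_records(2)
  rec$mystery <- "x"
  write_spc_csv(rec, f)
  expect_warning(back <- read_spc_csv(f), "MYSTERY")
  expect_true("mystery" %in% names(back))
})

test_that("an invalid observation-type code parses but fails validation", {
  rec <- make_records(2, obs_type = c("Q", "I"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spc_csv(rec, f)
  back <- read_spc_csv(f)
  expect_equal(back$obs_type[1], "Q")
  expect_false("Q" %in% obs_type_codes())
  rep <- validate_spc(back)
  expect_true(any(rep$issues$rule == "obs_type_code" & rep$issues$row == 1))
  expect_equal(rep$error_rows, 1L)
})

test_that("depth-bin classifier matches the published zones and is monotone", {
  expect_equal(classify_depth_bin(3), "shallow")
  expect_equal(classify_depth_bin(18), "deep")
  expect_equal(classify_depth_bin(30), "deep")
  expect_equal(classify_depth_bin(c(5.9, 6, 17.9)),
               c("shallow", "mid", "mid"))
  expect_error(classify_depth_bin(0), "domain")
  expect_error(classify_depth_bin(30.1), "domain")
  d <- seq(0.1, 30, by = 0.1)
  idx <- match(classify_depth_bin(d), c("shallow", "mid", "deep"))
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) >= 0))
})

test_that("DACOR bands match the published scales and cover all counts", {
  expect_equal(classify_dacor(35, "free"), "C")
  expect_equal(classify_dacor(0, "free"), "R")
  expect_equal(classify_dacor(500, "boring"), "A")
  for (cat in c("free", "boring")) {
    cls <- classify_dacor(0:600, cat)
    expect_false(anyNA(cls))
    idx <- match(cls, c("R", "O", "C", "A", "D"))
    expect_true(all(diff(idx) >= 0))
  }
  # gap closure toward the rarer class
  expect_equal(classify_dacor(5, "free"), "R")
  expect_equal(classify_dacor(25, "boring"), "R")
  expect_error(classify_dacor(-1, "free"))
})

test_that("pooled reporting units expand to their member islands", {
  expect_equal(expand_reporting_units("Guam"), "Guam")
  expect_equal(expand_reporting_units("AGS"),
               c("Alamagan", "Guguan", "Sarigan"))
  units <- unique(pacific_area_table()$reporting_unit)
  expect_length(units, 37)
  expect_length(expand_reporting_units(units), 39)
})

test_that("validation boundaries: visibility floor and depth rules", {
  rec <- make_records(4, visibility_m = c(5, 7.4, 7.5, 20))
  rep <- validate_spc(rec)
  vf <- rep$issues[rep$issues$rule == "visibility_floor", ]
  expect_equal(vf$row, c(1L, 2L))
  expect_match(vf$message[1], "below visibility floor")

  rec <- make_records(3, depth_m = c(1.2, 1.5, 12),
                      depth_bin = c("shallow", "shallow", "mid"))
  rep <- validate_spc(rec)
  expect_equal(rep$issues$row[rep$issues$rule == "depth_floor"], 1L)
  # depth 12 in "mid" raises no label warning
  expect_false(any(rep$issues$rule == "depth_bin_label" &
                     rep$issues$row == 3))
})

test_that("validator agrees with a brute-force row-by-row oracle", {
  set.seed(11)
  n <- 200
  rec <- make_records(n,
    obs_type = sample(c("I", "N", "F", "T", "P", "Q"), n, TRUE,
                      prob = c(.5, .2, .1, .05, .05, .1)),
    count = sample(c(-1L, 0L, 1L, 3L), n, TRUE, prob = c(.05, .05, .6, .3)),
    size_tl_cm = sample(c(-2, 0, 8, 25), n, TRUE,
                        prob = c(.05, .05, .5, .4)),
    depth_m = round(runif(n, 0.5, 33), 1),
    visibility_m = round(runif(n, 4, 32), 1),
    obs_year = sample(c(2010L, 2015L), n, TRUE))
  rec$depth_bin <- sample(c("shallow", "mid", "deep"), n, TRUE)
  got <- validate_spc(rec)$error_rows

  oracle <- vapply(seq_len(n), function(i) {
    r <- rec[i, ]
    any(!r$obs_type %in% c("I", "N", "F", "T", "P"),
        r$count < 1,
        r$size_tl_cm <= 0,
        r$depth_m > 30, r$depth_m < 1.5,
        r$visibility_m < 7.5, r$visibility_m > 30,
        r$obs_type %in% c("F", "T") && r$obs_year < 2012)
  }, logical(1))
  expect_equal(got, which(oracle))
})
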