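# Window statistics, begin/end/coef aggregations, the candidate grammar and
# featurize().

test_that("window_stat matches hand-computed values", {
  s <- make_series(0:3, c(10, 12, 11, 15))
  expect_equal(window_stat(s, 0, 10, "diff"), 5 / 3)  # (2 - 1 + 4) / 3
  expect_equal(window_stat(s, 0, 10, "avg"), 12)
  expect_equal(window_stat(s, 0, 10, "var"), mean((c(10, 12, 11, 15) - 12)^2))

  icp <- make_series(0:3, c(18, 22, 25, 19))
  expect_equal(window_stat(icp, 0, 10, "ht20", signal = "icp"), 0.5)

  one <- make_series(5, 42)
  expect_equal(window_stat(one, 0, 10, "avg"), 42)
  expect_true(is.na(window_stat(one, 0, 10, "var")))
  expect_true(is.na(window_stat(one, 0, 10, "diff")))
  expect_true(is.na(window_stat(one, 20, 30, "avg")))  # empty window

  expect_error(window_stat(s, 0, 10, "ht20", signal = "map"), "not defined")
  expect_error(window_stat(s, 0, 10, "ht120", signal = "icp"), "not defined")
})

test_that("windows are half-open [a, b)", {
  s <- make_series(c(0, 239, 240), c(1, 1, 100))
  expect_equal(window_stat(s, 0, 240, "avg"), 1)
  expect_equal(window_stat(s, 240, 480, "avg"), 100)
})

test_that("diff equals the telescoping identity and direct summation", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:60, 1)
    v <- rnorm(n, 15, 6)
    s <- make_series(sort(sample(0:239, n)), v)
    d <- window_stat(s, 0, 240, "diff")
    expect_equal(d, mean(v[-1] - v[-n]), tolerance = 1e-12)
    expect_equal(d, (v[n] - v[1]) / (n - 1), tolerance = 1e-12)
  }
})

test_that("quantile and fraction statistics obey their bounds", {
  set.seed(8)
  for (rep in 1:10) {
    v <- rnorm(sample(2:100, 1), 15, 10)
    s <- make_series(seq_along(v) - 1, v)
    q10 <- window_stat(s, 0, 1e5, "q10")
    q90 <- window_stat(s, 0, 1e5, "q90")
    expect_lte(q10, median(v))
    expect_gte(q90, median(v))
    for (k in c("ht20", "lt10")) {
      f <- window_stat(s, 0, 1e5, k)
      expect_gte(f, 0); expect_lte(f, 1)
    }
  }
})

test_that("begin_feature uses the first 24 h window", {
  const <- make_series(seq(0, 1439, 5), 15)
  expect_equal(begin_feature(const, "avg"), 15)
  late <- make_series(seq(1500, 2000, 5), 15)
  expect_true(is.na(begin_feature(late, "avg")))
  lin <- make_series(0:1439, 10 + 10 * (0:1439) / 1439)
  expect_equal(begin_feature(lin, "diff"), 10 / 1439, tolerance = 1e-12)
})

test_that("end_feature uses the trailing 8 h window", {
  cpp <- make_series(seq(0, 24 * 60 - 1, 2), 70)
  expect_equal(end_feature(cpp, "avg", 24), 70)
  expect_true(is.na(end_feature(make_series(0:100, 70), "avg", 24)))
  two <- make_series(c(16 * 60, 16 * 60 + 1), c(20, 30))
  expect_equal(end_feature(two, "var", 24), 25)  # population variance
})

test_that("coef_feature equals the closed-form OLS slope of rolling-window stats", {
  flat <- make_series(seq(0, 24 * 60 - 1, 2), 12)
  expect_equal(coef_feature(flat, "avg", 24), 0)

  # value = 0.5 * hours: each 4-h window mean is 0.5*(k - 2) -> slope 0.5
  t <- seq(0, 24 * 60 - 1, 1)
  lin <- make_series(t, 0.5 * t / 60)
  expect_equal(coef_feature(lin, "avg", 24), 0.5, tolerance = 1e-9)

  set.seed(9)
  noisy <- make_series(seq(0, 24 * 60 - 1, 3), rnorm(480, 15, 5))
  for (kind in c("avg", "var", "q90", "diff")) {
    ends <- 4:24
    y <- vapply(ends, function(k)
      window_stat(noisy, (k - 4) * 60, k * 60, kind), numeric(1))
    expect_equal(coef_feature(noisy, kind, 24), slope_oracle(ends, y),
                 tolerance = 1e-9)
  }

  # fewer than two non-missing windows -> missing
  sparse <- make_series(c(0, 1), c(10, 11))
  expect_true(is.na(coef_feature(sparse, "avg", 24)))
})

test_that("location shift moves level statistics and leaves shape statistics alone", {
  set.seed(10)
  t <- sort(sample(0:1439, 400))
  v <- rnorm(400, 15, 5)
  s0 <- make_series(t, v); s1 <- make_series(t, v + 7)
  for (k in c("avg", "min", "max", "q90", "q10")) {
    expect_equal(window_stat(s1, 0, 1440, k),
                 window_stat(s0, 0, 1440, k) + 7, tolerance = 1e-9)
  }
  for (k in c("diff", "var")) {
    expect_equal(window_stat(s1, 0, 1440, k), window_stat(s0, 0, 1440, k),
                 tolerance = 1e-9)
  }
  expect_equal(coef_feature(s1, "avg", 24), coef_feature(s0, "avg", 24),
               tolerance = 1e-9)
})

test_that("age deciles clip to [1, 9]", {
  expect_equal(age_decile(46), 4L)
  expect_equal(age_decile(16), 1L)
  expect_equal(age_decile(101), 9L)
  expect_equal(age_decile(95), 9L)
  expect_error(age_decile(-3), "non-negative")
})

test_that("the default grammar enumerates the 54 + 1 candidate features", {
  feats <- enumerate_candidate_features()
  expect_equal(nrow(feats), 55L)
  expect_true(all(c("icp_end", "cpp_diff_coef", "map_var_coef", "agec") %in%
                    feats$name))
  retrained <- c("cpp_diff_coef", "map_diff_coef", "map_diff_begin",
                 "icp_diff_coef", "cpp_diff_begin", "icp_q90_coef",
                 "icp_end", "agec", "cpp_end", "cpp_var_coef",
                 "icp_diff_end", "icp_coef", "map_var_coef", "icp_var_coef")
  expect_true(all(retrained %in% feats$name))
  expect_identical(feats, enumerate_candidate_features())  # deterministic

  with_minmax <- enumerate_candidate_features(
    feature_grammar(include_minmax = TRUE))
  expect_equal(nrow(with_minmax), 73L)  # 3*7*3 + 9 + 1
})

test_that("grammar hashes distinguish grammars and are stable", {
  expect_identical(grammar_hash(feature_grammar()),
                   grammar_hash(feature_grammar()))
  expect_false(identical(grammar_hash(feature_grammar()),
                         grammar_hash(feature_grammar(include_minmax = TRUE))))
})

test_that("featurize fills every feature for a fully sampled patient", {
  cohort <- make_cohort(dense_vitals(48), age_years = 47)
  fv <- featurize(cohort, times = c(24, 32), quiet = TRUE)
  expect_equal(nrow(fv), 2L)
  expect_equal(fv$t_h, c(24, 32))
  expect_equal(sum(is.na(fv)), 0L)
  expect_equal(unique(fv$agec), 4)
  expect_equal(fv$icp_end, c(15, 15))
  expect_equal(fv$cpp_begin, c(70, 70))
  expect_identical(tibble::as_tibble(fv),
                   tibble::as_tibble(featurize(cohort, times = c(24, 32),
                                               quiet = TRUE)))
})

test_that("a completely missing trailing window leaves cpp_*_end features missing", {
  v <- dense_vitals(48)
  v <- v[!(v$signal == "cpp" & v$time_min >= 16 * 60 & v$time_min < 24 * 60), ]
  fv <- featurize(make_cohort(v), times = c(24, 32), quiet = TRUE)
  at24 <- fv[fv$t_h == 24, ]
  end_cols <- grep("^cpp(_[a-z0-9]+)?_end$|^cpp_end$", names(fv), value = TRUE)
  expect_true(length(end_cols) >= 5)
  expect_true(all(is.na(at24[, end_cols])))
  expect_false(anyNA(fv[fv$t_h == 32, end_cols]))
})

test_that("begin features are identical across prediction times", {
  fv <- small_features()
  begin_cols <- grep("_begin$", names(fv), value = TRUE)
  per_patient <- fv |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(begin_cols), dplyr::n_distinct))
  expect_true(all(per_patient[, begin_cols] == 1))
})

test_that("featurize rejects off-schedule prediction times", {
  cohort <- make_cohort(dense_vitals(48))
  expect_error(featurize(cohort, times = 25, quiet = TRUE), "multiples of 8")
  expect_error(featurize(cohort, times = 16, quiet = TRUE), "multiples of 8")
})

test_that("feature tables round-trip through CSV with the grammar hash", {
  dir <- withr::local_tempdir()
  fv <- small_features()
  write_features(fv, file.path(dir, "f.csv"))
  back <- read_features(file.path(dir, "f.csv"))
  expect_equal(attr(back, "grammar_hash"), attr(fv, "grammar_hash"))
  expect_equal(as.data.frame(back), as.data.frame(fv), tolerance = 1e-12)
})
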