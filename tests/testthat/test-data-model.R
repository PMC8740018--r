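test_that("LOQ follows from the plating scheme", {
  expect_equal(compute_loq(plating_scheme(25, 225)), 10)
  expect_equal(compute_loq(plating_scheme(10, 90, 1, 10)), 100)
  expect_equal(compute_loq(plating_scheme(1, 9)), 10)
  # homogeneity: scaling mass and diluent together leaves the LOQ alone
  for (f in c(0.5, 2, 7.3)) {
    expect_equal(compute_loq(plating_scheme(25 * f, 225 * f)),
                 compute_loq(plating_scheme(25, 225)))
  }
  expect_error(plating_scheme(-1, 225), "positive")
  expect_error(plating_scheme(25, 225, 0), "positive")
  expect_error(plating_scheme(25, 225, 1, 0.5), ">= 1")
})

test_that("quantitative results parse to exact and censored observations", {
  d <- enum_quantitative(c("20", "ND", "300"), loq = 10)
  o <- d$observations
  expect_equal(sort(o$value[o$kind == "exact"]), log10(c(20, 300)))
  expect_equal(o$upper[o$kind == "left_censored"], 1)
  expect_equal(d$mode, "QN_3")
  expect_equal(n_detected(d), 2)
  expect_equal(m_censored(d), 1)

  # numeric input with NA as the ND marker
  d2 <- enum_quantitative(c(20, NA, 300), loq = 10)
  expect_equal(d2$observations$weight, d$observations$weight)

  # 15 records with 5 ND: the censored share is exactly one third
  d3 <- enum_quantitative(c(rep(50, 10), rep(NA, 5)), loq = 10)
  expect_equal(n_detected(d3), 10)
  expect_equal(m_censored(d3), 5)
  expect_equal(d3$mode, "QN_3")
  expect_identical(censored_fraction(d3), 5 / 15)

  expect_equal(enum_quantitative(c(20, 300), loq = 10)$mode, "QN_1")
  expect_error(enum_quantitative(c("ND", "ND"), loq = 10), "censored")
  expect_error(enum_quantitative(c(5, 20), loq = 10), "below the LOQ")
  expect_error(enum_quantitative(c("20", "abc"), loq = 10), "unparseable")
})

test_that("interval tables parse with ND as the censored class", {
  d <- enum_intervals(10^(1:5), 10^(2:6), c(258, 368, 234, 44, 2),
                      nd = 214, loq = 10)
  expect_equal(n_detected(d) + m_censored(d), 1120)
  expect_equal(m_censored(d), 214)
  expect_equal(d$mode, "QN_4")

  # zero-count classes are dropped (blank table cells read as zero)
  d4 <- enum_intervals(10^(1:5), 10^(2:6), c(16, 2, 1, 0, 0),
                       nd = 81, loq = 10)
  expect_equal(n_detected(d4) + m_censored(d4), 100)
  expect_equal(sum(d4$observations$kind == "interval"), 3)

  d5 <- enum_intervals(10, 100, 5, nd = 0, loq = 10)
  expect_equal(d5$mode, "QN_2")
  expect_equal(m_censored(d5), 0)

  expect_error(enum_intervals(c(10, 50), c(100, 500), c(1, 1), loq = 10),
               "overlap")
  expect_error(enum_intervals(5, 100, 3, loq = 10), "below the LOQ")
  expect_error(enum_intervals(10, 100, 0, nd = 4, loq = 10), "zero")
})

test_that("censored fractions are exact ratios", {
  cs <- case_datasets()
  expect_identical(censored_fraction(cs$case2), 1008 / 1120)
  expect_identical(censored_fraction(cs$case4), 81 / 100)
  expect_identical(censored_fraction(enum_quantitative(c(20, 40), 10)), 0)
})

test_that("sub-tool mode dispatch matches censoring and data format", {
  combos <- list(
    list(d = enum_quantitative(c(20, 40), 10), mode = "QN_1"),
    list(d = enum_intervals(10, 100, 5, loq = 10), mode = "QN_2"),
    list(d = enum_quantitative(c(20, NA), 10), mode = "QN_3"),
    list(d = enum_intervals(10, 100, 5, nd = 2, loq = 10), mode = "QN_4"))
  for (cb in combos) {
    o <- cb$d$observations
    expect_equal(cb$d$mode, cb$mode)
    expect_equal(any(o$kind == "left_censored"),
                 cb$mode %in% c("QN_3", "QN_4"))
    expect_equal(any(o$kind == "interval"),
                 cb$mode %in% c("QN_2", "QN_4"))
  }
})

test_that("CSV round-trips preserve observations, weights and LOQ exactly", {
  # quantitative dialect, including awkward floating-point values
  dq <- simulate_enum(1.7, 0.9, 40, loq = 10, seed = 11)
  fq <- tempfile(fileext = ".csv")
  write_enum_csv(dq, fq)
  rq <- read_enum_csv(fq, loq = dq$loq)
  expect_identical(rq$observations$kind, dq$observations$kind)
  expect_identical(rq$observations$value, dq$observations$value)
  expect_identical(rq$observations$weight, dq$observations$weight)
  expect_identical(rq$loq, dq$loq)

  # interval dialect via a packaged fixture
  f1 <- system.file("extdata", "case1_total_coliforms.csv",
                    package = "cfufit")
  d1 <- read_enum_csv(f1, loq = 10)
  expect_equal(d1$mode, "QN_4")
  f2 <- tempfile(fileext = ".csv")
  write_enum_csv(d1, f2)
  r1 <- read_enum_csv(f2, loq = 10)
  expect_identical(r1$observations[order(r1$observations$kind), ],
                   d1$observations[order(d1$observations$kind), ])
  unlink(c(fq, f2))
})

test_that("dialect detection reads both packaged layouts", {
  q <- read_enum_csv(system.file("extdata", "example_quantitative.csv",
                                 package = "cfufit"), loq = 10)
  expect_equal(q$mode, "QN_3")
  expect_equal(n_detected(q) + m_censored(q), 15)
  expect_error(
    read_enum_csv(system.file("extdata", "all_nd.csv", package = "cfufit"),
                  loq = 10),
    "censored")
})
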