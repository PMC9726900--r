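test_that("gamma pause-time density matches its closed form and normalizes", {
  # boundary values at t = 0
  expect_equal(gamma_dwell_pdf(0, n_steps = 1, rate = 0.1), 0.1)
  expect_equal(gamma_dwell_pdf(0, n_steps = 2, rate = 0.5), 0)

  # N = 1 reduces to the exponential density pointwise
  tt <- seq(0, 50, by = 0.5)
  expect_equal(gamma_dwell_pdf(tt, 1, 0.2), 0.2 * exp(-0.2 * tt))

  # unit mass over a grid of (N, k), adaptive quadrature as the oracle
  for (N in c(1, 1.5, 3, 6, 12)) {
    for (k in c(0.05, 0.5, 2)) {
      mass <- stats::integrate(gamma_dwell_pdf, 0, Inf, n_steps = N,
                               rate = k, rel.tol = 1e-9)$value
      expect_equal(mass, 1, tolerance = 1e-6)
    }
  }

  expect_error(gamma_dwell_pdf(1, n_steps = 0.5, rate = 1),
               class = "remkin_domain_error")
  expect_error(gamma_dwell_pdf(1, n_steps = 2, rate = -1),
               class = "remkin_domain_error")
  expect_error(gamma_dwell_pdf(-1, n_steps = 2, rate = 1),
               class = "remkin_domain_error")
})

test_that("hypoexponential sampler matches analytic mean and variance", {
  # pure exponential: mean 1/k
  x <- sample_dwell_times(1, 2.0, n = 1e5, seed = 101)
  expect_equal(mean(x$values), 0.5, tolerance = 4 * 0.5 / sqrt(1e5))

  # N steps plus distinct step: mean N/k_N + 1/k_X, var N/k_N^2 + 1/k_X^2
  x <- sample_dwell_times(6, 0.1, extra_rate = 1.0, n = 1e5, seed = 102)
  mu <- 6 / 0.1 + 1 / 1.0
  v <- 6 / 0.1^2 + 1 / 1.0^2
  expect_equal(mean(x$values), mu, tolerance = 4 * sqrt(v / 1e5))
  expect_equal(var(x$values), v, tolerance = 0.05 * v)

  # reproducibility under a fixed seed, global RNG untouched
  y1 <- sample_dwell_times(3, 0.5, n = 50, seed = 9)
  y2 <- sample_dwell_times(3, 0.5, n = 50, seed = 9)
  expect_identical(y1$values, y2$values)

  expect_error(sample_dwell_times(3, -0.5, n = 10),
               class = "remkin_domain_error")
})

test_that("dwell container validates inputs", {
  expect_error(dwell_times(c(1, -2)), class = "remkin_domain_error")
  expect_error(dwell_times(c(1, 2), censored = c(TRUE, FALSE, TRUE)),
               class = "remkin_domain_error")
  x <- dwell_times(c(5, 10), censored = c(FALSE, TRUE), condition = "wt")
  expect_equal(length(x), 2L)
})

test_that("maximum-likelihood fit recovers simulation ground truth", {
  x <- sample_dwell_times(6, 0.1, n = 2000, seed = 7)
  f <- fit_dwell(x, model = "gamma")
  expect_gte(f$n_app, 5)
  expect_lte(f$n_app, 7)
  expect_lt(abs(f$k_app - 0.1) / 0.1, 0.15)
  expect_identical(f$n_app_rounded, 6)

  # exponential closed form: k = 1/mean, N fixed at 1
  e <- sample_dwell_times(1, 0.8, n = 2000, seed = 8)
  fe <- fit_dwell(e, model = "exponential")
  expect_equal(fe$k_app, 1 / mean(e$values))
  expect_identical(fe$n_app, 1)

  # k_overall consistency holds exactly for every fit
  expect_identical(f$k_overall, f$k_app / f$n_app)
  expect_identical(fe$k_overall, fe$k_app / fe$n_app)
})

test_that("fitted shape agrees with an independent gamma MLE", {
  skip_if_not_installed("fitdistrplus")
  x <- sample_dwell_times(4, 0.2, n = 1500, seed = 21)
  f <- fit_dwell(x, model = "gamma")
  ref <- fitdistrplus::fitdist(x$values, "gamma",
                               start = list(shape = 2, rate = 0.1))
  expect_equal(f$n_app, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$k_app, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("reporting convention rounds to 0.5 below 2 and integers above", {
  expect_identical(remkin:::round_n_app(6.2), 6)
  expect_identical(remkin:::round_n_app(1.6), 1.5)
  expect_identical(remkin:::round_n_app(1.2), 1)
  expect_identical(remkin:::round_n_app(2.6), 3)
})

test_that("binned least-squares path agrees with unbinned MLE", {
  x <- sample_dwell_times(6, 0.1, n = 2000, seed = 31)
  f_mle <- fit_dwell(x, model = "gamma")
  f_hist <- fit_dwell(x, model = "gamma", method = "histogram")
  # agreement within the ~25% parameter uncertainty typical of such fits
  expect_lt(abs(f_hist$n_app - f_mle$n_app) / f_mle$n_app, 0.25)
  expect_lt(abs(f_hist$k_app - f_mle$k_app) / f_mle$k_app, 0.25)
})

test_that("parameter recovery holds across seeds (median relative error)", {
  for (truth in list(c(3, 0.3), c(6, 0.1))) {
    errs <- t(sapply(1:20, function(s) {
      x <- sample_dwell_times(truth[1], truth[2], n = 2000, seed = 400 + s)
      f <- fit_dwell(x, model = "gamma")
      c(abs(f$n_app - truth[1]) / truth[1],
        abs(f$k_app - truth[2]) / truth[2])
    }))
    expect_lte(median(errs[, 1]), 0.15)
    expect_lte(median(errs[, 2]), 0.15)
  }
})

test_that("censoring-aware likelihood uses censored exposure", {
  x <- sample_dwell_times(1, 0.5, n = 500, seed = 55)
  cens <- x$values > quantile(x$values, 0.7)
  xc <- dwell_times(x$values, censored = cens)
  f_excl <- fit_dwell(xc, model = "exponential")
  f_incl <- fit_dwell(xc, model = "exponential", use_censored = TRUE)
  # dropping the long censored dwells biases the rate upward; the
  # censoring-aware estimate should sit closer to the truth
  expect_gt(f_excl$k_app, f_incl$k_app)
  expect_lt(abs(f_incl$k_app - 0.5) / 0.5, abs(f_excl$k_app - 0.5) / 0.5)
  expect_equal(f_incl$n_censored_used, sum(cens))
})

test_that("model selection separates gamma from exponential regimes", {
  g <- sample_dwell_times(6, 0.1, n = 2000, seed = 61)
  expect_identical(select_model(g), "gamma")
  e <- sample_dwell_times(1, 0.3, n = 2000, seed = 62)
  expect_identical(select_model(e), "exponential")
  expect_identical(select_model(g, criterion = "lrt"), "gamma")
  expect_identical(select_model(e, criterion = "lrt"), "exponential")
  small <- sample_dwell_times(6, 0.1, n = 10, seed = 63)
  expect_error(select_model(small), class = "remkin_insufficient_data")
  expect_error(fit_dwell(small), class = "remkin_insufficient_data")
})

test_that("unmasking sweep reproduces both regime limits", {
  sw <- unmasking_sweep(6, extra_rate = 1,
                        rate_grid = c(0.01, 100), n_per_point = 2000,
                        seed = 71)
  expect_equal(nrow(sw), 2L)
  # slow identical steps: distinct step invisible, N_app = true step count
  expect_equal(sw$n_app_rounded[1], 6)
  expect_identical(sw$model[1], "gamma")
  # fast identical steps: distinct step rate-determining, N_app -> 1
  expect_lt(sw$n_app[2], 1.5)
  expect_identical(sw$model[2], "exponential")
  # strict monotonicity between the extreme ratios
  expect_lt(sw$n_app[2], sw$n_app[1])

  one <- unmasking_sweep(6, extra_rate = 1, rate_grid = 0.1,
                         n_per_point = 500, seed = 72)
  expect_equal(nrow(one), 1L)
  expect_error(unmasking_sweep(6, 1, numeric(0)),
               class = "remkin_domain_error")
})

test_that("dwell tables round-trip through delimited text", {
  x <- dwell_times(c(3.5, 12.25, 8), censored = c(FALSE, TRUE, FALSE),
                   condition = "wt_10uM")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dwell_times(x, path)
  y <- read_dwell_times(path)
  expect_equal(y$values, x$values)
  expect_equal(y$censored, x$censored)
  expect_identical(y$condition, "wt_10uM")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("condition\tseconds\n a\t1", bad)
  expect_error(read_dwell_times(bad), class = "remkin_format_error")
})
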