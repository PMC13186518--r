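# brute-force oracle: scan acrophase on a fine grid, solving mesor and
# amplitude in closed form for each candidate peak time
grid_cosinor <- function(times, counts, period = 24, step = 0.02) {
  tp_grid <- seq(0, period - step, by = step)
  best <- NULL
  for (tp in tp_grid) {
    z <- cos(2 * pi * (times - tp) / period)
    fit <- lm(counts ~ z)
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(tp = tp, mesor = coef(fit)[1], amplitude = coef(fit)[2],
                   sse = sse)
    }
  }
  # a negative amplitude means the true peak is half a period away
  if (best$amplitude < 0) {
    best$amplitude <- -best$amplitude
    best$tp <- (best$tp + period / 2) %% period
  }
  best
}

test_that("cosinor recovers noiseless parameters exactly", {
  t <- seq(0, 24 - 0.25, by = 0.25)
  y <- 50 + 30 * cos(2 * pi * (t - 15) / 24)
  fit <- fit_cosinor(t, y)
  expect_equal(fit$mesor, 50, tolerance = 1e-10)
  expect_equal(fit$amplitude, 30, tolerance = 1e-10)
  expect_equal(fit$acrophase_time, 15, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("constant series degenerates to zero amplitude and zero R^2", {
  t <- seq(0, 23, by = 1)
  fit <- fit_cosinor(t, rep(7, 24))
  expect_equal(fit$mesor, 7)
  expect_equal(fit$amplitude, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
  expect_error(fit_cosinor(c(1, 1, 1), c(1, 2, 3)), "distinct|degenerate")
})

test_that("least-squares cosinor matches the brute-force grid optimum", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      n <- sample(12:48, 1)
      t <- sort(runif(n, 0, 24))
      y <- runif(1, 10, 100) +
        runif(1, 5, 50) * cos(2 * pi * (t - runif(1, 0, 24)) / 24) +
        rnorm(n, 0, 5)
      fit <- fit_cosinor(t, y)
      oracle <- grid_cosinor(t, y)
      delta <- abs(fit$acrophase_time - oracle$tp)
      expect_lte(min(delta, 24 - delta), 0.02)
      expect_equal(fit$amplitude, unname(oracle$amplitude), tolerance = 0.02)
      expect_equal(fit$mesor, unname(oracle$mesor), tolerance = 0.02)
    }
  })
})

test_that("noisy sinusoid parameters are recovered at day resolution", {
  withr::with_seed(7, {
    t <- (seq_len(2880) - 1) * 30 / 3600
    y <- 50 + 30 * cos(2 * pi * (t - 15) / 24) + rnorm(2880, 0, 5)
    fit <- fit_cosinor(t, y)
    # asymptotic SEs: sigma/sqrt(n) for mesor, sigma*sqrt(2/n) for amplitude
    se_amp <- 5 * sqrt(2 / 2880)
    expect_lt(abs(fit$mesor - 50), 3 * 5 / sqrt(2880))
    expect_lt(abs(fit$amplitude - 30), 3 * se_amp)
    expect_lt(abs(fit$acrophase_time - 15), 3 * (se_amp / 30) * 24 / (2 * pi))
  })
})

test_that("scaling counts scales location features and fixes shape features", {
  withr::with_seed(13, {
    t <- (seq_len(2880) - 1) * 30 / 3600
    y <- pmax(0, 60 + 40 * cos(2 * pi * (t - 14) / 24) + rnorm(2880, 0, 10))
    c_scale <- 3.7
    f1 <- nonparametric_day_features(y)
    f2 <- nonparametric_day_features(c_scale * y)
    for (nm in c("mean_activity", "sd_activity", "rmssd_activity", "m10", "l5")) {
      expect_equal(f2[[nm]], c_scale * f1[[nm]], tolerance = 1e-10)
    }
    expect_equal(f2$intradaily_variability, f1$intradaily_variability,
                 tolerance = 1e-10)
    expect_equal(f2$relative_amplitude, f1$relative_amplitude,
                 tolerance = 1e-10)
    fit1 <- fit_cosinor(t, y); fit2 <- fit_cosinor(t, c_scale * y)
    expect_equal(fit2$mesor, c_scale * fit1$mesor)
    expect_equal(fit2$amplitude, c_scale * fit1$amplitude)
    expect_equal(fit2$acrophase_time, fit1$acrophase_time)
    expect_equal(fit2$r_squared, fit1$r_squared)
  })
})

test_that("shifting the sinusoid phase shifts the acrophase equally", {
  t <- seq(0, 23.5, by = 0.5)
  base <- fit_cosinor(t, 50 + 30 * cos(2 * pi * (t - 15) / 24))
  shifted <- fit_cosinor(t, 50 + 30 * cos(2 * pi * (t - 17) / 24))
  expect_equal((shifted$acrophase_time - base$acrophase_time) %% 24, 2,
               tolerance = 1e-8)
})

test_that("IV separates smooth rhythms from white noise", {
  t <- (seq_len(2880) - 1) * 30 / 3600
  smooth <- nonparametric_day_features(100 + 50 * cos(2 * pi * (t - 14) / 24))
  expect_lte(smooth$intradaily_variability, 0.1)

  withr::with_seed(17, {
    ivs <- replicate(200, {
      nonparametric_day_features(rexp(2880, 1 / 50))$intradaily_variability
    })
    expect_gt(mean(ivs), 1.8)
    expect_lt(mean(ivs), 2.2)
  })

  expect_true(is.na(nonparametric_day_features(rep(5, 2880))$intradaily_variability))
})

test_that("M10/L5 hit their boundary values on a two-level day", {
  counts <- c(rep(0, 7 * 120), rep(100, 10 * 120), rep(0, 7 * 120))
  f <- nonparametric_day_features(counts)
  expect_equal(f$m10, 100)
  expect_equal(f$l5, 0)
  expect_equal(f$relative_amplitude, 1)
})

test_that("interdaily stability is 1 for identical days and ~1/n for noise", {
  t <- (seq_len(2880) - 1) * 30 / 3600
  day <- 100 + 50 * cos(2 * pi * (t - 14) / 24)
  expect_equal(interdaily_stability(rep(list(day), 5)), 1)
  expect_true(is.na(interdaily_stability(list(day))))

  withr::with_seed(23, {
    # hourly-resolution white noise days: E[IS] = 1/n_days
    vals <- replicate(300, {
      days <- replicate(5, rep(rnorm(24), each = 120), simplify = FALSE)
      interdaily_stability(days)
    })
    expect_lt(abs(mean(vals) - 1 / 5), 0.03)
  })
})

test_that("circadian rhythm strength tracks noise monotonically", {
  withr::with_seed(29, {
    t <- (seq_len(2880) - 1) * 30 / 3600
    clean <- 100 + 50 * cos(2 * pi * (t - 14) / 24)
    expect_equal(circadian_rhythm_strength(t, clean), 1, tolerance = 1e-10)
    noise_only <- circadian_rhythm_strength(t, rnorm(2880, 100, 20))
    expect_lte(noise_only, 0.05)
    half <- circadian_rhythm_strength(t, clean + rnorm(2880, 0, 25))
    expect_gt(half, noise_only)
    expect_lt(half, 1)
  })
})

test_that("day-row assembly drops incomplete rows and rejects duplicates", {
  es <- make_sine_series(days = 4, mesor = 60, amplitude = 60)
  logs <- make_clean_logs(days = 4)
  days <- apply_exclusions(segment_days(es), logs)
  nights <- score_nights(es, logs)
  circ <- circadian_day_features(es, days)
  rows <- assemble_day_rows(circ, nights, logs)
  expect_equal(nrow(rows), 2)           # days 2 and 3 retained
  expect_true(all(feature_names() %in% names(rows)))

  # a night without metrics loses its day row
  nights2 <- nights
  nights2$waso[1] <- NA
  expect_message(rows2 <- assemble_day_rows(circ, nights2, logs), "dropped")
  expect_equal(nrow(rows2), 1)

  expect_error(assemble_day_rows(dplyr::bind_rows(circ, circ), nights, logs),
               "duplicate")
  expect_equal(nrow(assemble_day_rows(circ[0, ], nights, logs)), 0)
})
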