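test_that("diffusion fit recovers D exactly on noiseless decays", {
  cv <- make_curves("decay", truth = list(D = 1e-10), noise = 0)
  fit <- fit_diffusion(cv$x, cv$y)
  expect_lt(abs(fit$estimates[["D"]] - 1e-10), 1e-13)
  expect_equal(fit$estimates[["I0"]], 100, tolerance = 1e-6)
  expect_true(fit$converged)
  # D = 0: constant intensity
  flat <- make_curves("decay", truth = list(D = 0), noise = 0)
  expect_warning(fit0 <- fit_diffusion(flat$x, flat$y), "attenuation")
  expect_lt(abs(fit0$estimates[["D"]]), 1e-12)
})

test_that("noiseless log-decay fit equals the linear-regression slope", {
  cv <- make_curves("decay", truth = list(D = 8e-11), noise = 0)
  g <- cv$x * 0.01
  k <- (2.6752218744e8 * g * 8.6e-3)^2 * (70e-3 - 8.6e-3 / 3 - 0.226e-3 / 2)
  slope <- -coef(lm(log(cv$y) ~ k))[[2]]
  fit <- fit_diffusion(cv$x, cv$y)
  expect_equal(fit$estimates[["D"]], slope, tolerance = 1e-10)
})

test_that("mean D over 50 noisy decays is within 1% with honest SEs", {
  est <- se <- numeric(50)
  for (s in 1:50) {
    cv <- make_curves("decay", truth = list(D = 1e-10), noise = 0.01,
                      seed = s)
    fit <- fit_diffusion(cv$x, cv$y)
    est[s] <- fit$estimates[["D"]]
    se[s] <- fit$se[["D"]]
  }
  expect_lt(abs(mean(est) / 1e-10 - 1), 0.01)
  # spread across fits is consistent with the per-fit standard error
  expect_gt(sd(est) / mean(se), 0.5)
  expect_lt(sd(est) / mean(se), 2.0)
})

test_that("4PL fits recover the planted EC50 and satisfy the midpoint", {
  dr <- make_curves("dose_response", truth = list(ec50 = 8.4), noise = 0)
  fit <- fit_ec50_4pl(dr$x, dr$y)
  expect_lt(abs(fit$estimates[["ec50"]] / 8.4 - 1), 1e-6)
  # response at c = EC50 is (top+bottom)/2 on the fitted curve
  cf <- fit$estimates
  mid <- predict(fit$fit, newdata = list(logc = log10(cf[["ec50"]])))
  expect_equal(unname(mid), (cf[["top"]] + cf[["bottom"]]) / 2,
               tolerance = 1e-10)
  expect_true(attr(fit, "ec50_in_range"))
})

test_that("the F-test arithmetic matches its closed form and null case", {
  dr <- make_curves("dose_response", noise = 1, seed = 2)
  # identical datasets duplicated: F ~ 0, shared preferred
  ft0 <- compare_curves_ftest(list(dr$x, dr$x), list(dr$y, dr$y))
  expect_lt(ft0$F, 1e-6)
  expect_equal(ft0$preferred, "shared")
  # hand recomputation from the two RSS values
  dr2 <- make_curves("dose_response", truth = list(ec50 = 13.7), noise = 1,
                     seed = 3)
  ft <- compare_curves_ftest(list(dr$x, dr2$x), list(dr$y, dr2$y))
  n <- length(dr$x) + length(dr2$x)
  Fhand <- ((ft$rss_shared - ft$rss_separate) / 4) / (ft$rss_separate / (n - 8))
  expect_equal(ft$F, Fhand, tolerance = 1e-12)
  expect_equal(ft$p_value, pf(Fhand, 4, n - 8, lower.tail = FALSE))
})

test_that("Tm extraction is accurate and rejects transition-free data", {
  ml <- make_curves("melt", truth = list(tm = 67.8), noise = 0)
  expect_lt(abs(melt_tm(ml$x, ml$y)$tm - 67.8), 0.1)  # grid/10
  # linear baseline only: no interior extremum
  tt <- seq(20, 80, by = 1)
  expect_error(melt_tm(tt, 0.3 * tt - 12), "extremum")
})

test_that("SG-derivative Tm agrees with a dense numeric derivative oracle", {
  for (s in 1:50) {
    set.seed(s)
    tm <- runif(1, 40, 70); width <- runif(1, 1.5, 3)
    ml <- make_curves("melt", truth = list(tm = tm, width = width),
                      noise = 0.02, seed = s)
    got <- melt_tm(ml$x, ml$y)$tm
    # oracle: derivative of the noiseless closed form on a dense grid
    tt <- seq(min(ml$x), max(ml$x), by = 0.001)
    yy <- ml$truth$folded + (ml$truth$unfolded - ml$truth$folded) /
      (1 + exp(-(tt - tm) / width))
    oracle <- tt[which.max(abs(diff(yy) / diff(tt)))]
    expect_lt(abs(got - oracle), 1.0)  # one grid step
  }
})

test_that("dimer exchange fits recover Kd and conserve protomer mass", {
  ex <- make_curves("exchange", noise = 0)
  fit <- fit_dimer_kd(ex$x, ex$y)
  expect_lt(abs(fit$estimates[["kd"]] / 0.06 - 1), 1e-6)
  # mass action conserves total protomer at every titration point
  fr <- dimer_monomer_fractions(ex$x, 0.06)
  expect_close(fr$monomer + 2 * fr$dimer, fr$total, 1e-10)
  # Kd -> infinity limit: flat signal at the free plateau
  flat <- dimer_monomer_fractions(ex$x, 1e9)
  expect_close(flat$fraction_dimer, 0, 1e-3)
})

test_that("fitters are scale-equivariant in the response", {
  a <- 3.7
  dec <- make_curves("decay", noise = 0.005, seed = 4)
  d1 <- fit_diffusion(dec$x, dec$y)
  d2 <- fit_diffusion(dec$x, a * dec$y)
  expect_equal(d2$estimates[["D"]], d1$estimates[["D"]], tolerance = 1e-8)
  expect_equal(d2$estimates[["I0"]], a * d1$estimates[["I0"]],
               tolerance = 1e-8)
  dr <- make_curves("dose_response", noise = 1, seed = 4)
  e1 <- fit_ec50_4pl(dr$x, dr$y)
  e2 <- fit_ec50_4pl(dr$x, a * dr$y)
  expect_equal(e2$estimates[["ec50"]], e1$estimates[["ec50"]],
               tolerance = 1e-6)
  expect_equal(e2$estimates[["top"]], a * e1$estimates[["top"]],
               tolerance = 1e-6)
  ml <- make_curves("melt", noise = 0.02, seed = 4)
  expect_equal(melt_tm(ml$x, a * ml$y)$tm, melt_tm(ml$x, ml$y)$tm,
               tolerance = 1e-8)
  ex <- make_curves("exchange", noise = 0.005, seed = 4)
  k1 <- fit_dimer_kd(ex$x, ex$y)
  k2 <- fit_dimer_kd(ex$x, a * ex$y)
  expect_equal(k2$estimates[["kd"]], k1$estimates[["kd"]], tolerance = 1e-6)
})

test_that("invalid decay timings and grids are rejected", {
  cv <- make_curves("decay", noise = 0)
  expect_error(fit_diffusion(cv$x, cv$y, Delta = 1e-3), "timing")
  expect_error(fit_diffusion(rev(cv$x), cv$y), "increasing|not TRUE")
  expect_error(melt_tm(seq(20, 40, by = 1), rnorm(21), window = 8),
               "window|not TRUE")
})
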