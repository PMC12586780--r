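test_that("forward simulation matches closed-form recursions", {
  # equilibrium: no gradient and no heat production leaves tb unchanged
  eq <- predict_muscle_temperature(rep(20, 50),
                                   heat_params(k = 0.3, tm_dot = 0), 20)
  expect_equal(eq, rep(20, 50))

  # pure linear heating at k = 0
  lin <- predict_muscle_temperature(rep(10, 101),
                                    heat_params(k = 0, tm_dot = 0.01), 20)
  expect_equal(lin[101], 21)

  # geometric (euler) and exponential (exact) decay toward ambient
  pars <- heat_params(k = 0.05, tm_dot = 0)
  ta <- rep(10, 61)
  eul <- predict_muscle_temperature(ta, pars, 20, scheme = "euler")
  expect_equal(eul[61], 10 + 10 * 0.95^60)
  exa <- predict_muscle_temperature(ta, pars, 20, scheme = "exact_step")
  expect_equal(exa[61], 10 + 10 * exp(-3))

  expect_error(
    predict_muscle_temperature(ta, heat_params(k = 1, tm_dot = 0), 20,
                               dt = 1, scheme = "euler"),
    "exact_step")
  # exact scheme handles the same parameters fine
  expect_silent(predict_muscle_temperature(ta, heat_params(k = 1, tm_dot = 0),
                                           20, scheme = "exact_step"))
})

test_that("euler converges to the exact step at first order in dt", {
  pars <- heat_params(k = 0.05, tm_dot = 0.01)
  scen <- function(dt) {
    tt <- seq(0, 480, by = dt)
    ta <- 20 + 5 * sin(2 * pi * tt / 240)
    e <- predict_muscle_temperature(ta, pars, 22, dt = dt, scheme = "euler")
    x <- predict_muscle_temperature(ta, pars, 22, dt = dt,
                                    scheme = "exact_step")
    max(abs(e - x))
  }
  ratio <- scen(1) / scen(0.25)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)

  # with no heat production and constant ambient, |tb - ta| never grows
  for (scheme in c("euler", "exact_step")) {
    tb <- predict_muscle_temperature(rep(15, 200),
                                     heat_params(k = 0.08, tm_dot = 0), 24,
                                     scheme = scheme)
    expect_true(all(diff(abs(tb - 15)) <= 1e-12))
  }

  # exact-step steady state is ta + tm_dot / k
  pars2 <- heat_params(k = 0.05, tm_dot = 0.01)
  long <- predict_muscle_temperature(rep(15, 401), pars2, 20,
                                     scheme = "exact_step")
  expect_equal(long[401], 15 + 0.01 / 0.05, tolerance = 1e-6 / 15.2)
})

test_that("goodness of fit computes rss, mae and Gaussian AIC", {
  g0 <- goodness_of_fit(rep(1, 100), rep(1, 100), p = 2)
  expect_equal(g0$mae, 0)
  expect_equal(g0$rss, 0)
  expect_identical(as.numeric(g0$aic), -Inf)
  expect_true(attr(g0$aic, "flagged"))

  obs <- rnorm(100)
  g1 <- goodness_of_fit(obs, obs - 1, p = 2)  # rss = 100, n = 100
  expect_equal(as.numeric(g1$aic), 100 * log(1) + 2 * 3)

  g2 <- goodness_of_fit(c(1, 2, 3), c(2, 2, 2), p = 0)
  expect_equal(g2$mae, 2 / 3)
  expect_equal(g2$rss, 2)

  expect_error(goodness_of_fit(1:3, 1:2, p = 0), "lengths differ")
  expect_error(goodness_of_fit(1:3, 1:3, p = 2), "n >= p \\+ 2")
})

test_that("noiseless fits recover the generating parameters", {
  # constant-k truth
  cpars <- heat_params(k = 0.01, tm_dot = 0.005)
  ser_c <- make_deployment(seed = 21, noise_sd = 0, params = cpars)
  fc <- fit_heat_model(ser_c, kind = "constant")
  expect_equal(fc$params$k, 0.01, tolerance = 1e-4 / 0.01)
  expect_equal(fc$params$tm_dot, 0.005, tolerance = 1e-4 / 0.005)

  # two-regime truth at the scale of the largest tagged individual
  vpars <- heat_params(k_warm = 0.075, k_cool = 0.0016, tm_dot = 0.0017)
  ser_v <- make_deployment(seed = 22, noise_sd = 0, params = vpars)
  fv <- fit_heat_model(ser_v, kind = "variable")
  expect_equal(fv$params$k_warm, 0.075, tolerance = 1e-3)
  expect_equal(fv$params$k_cool, 0.0016, tolerance = 1e-3)
  expect_equal(fv$params$tm_dot, 0.0017, tolerance = 1e-3)
  expect_equal(fv$ratio, 0.075 / 0.0016, tolerance = 1e-2)
  expect_equal(round(fv$ratio, 1), 46.9)

  # nesting: the constant model is the variable model with equal ks
  ser_n <- make_deployment(seed = 23, noise_sd = 0.05, params = cpars)
  fcn <- fit_heat_model(ser_n, kind = "constant")
  tied <- heat_params(k_warm = fcn$params$k, k_cool = fcn$params$k,
                      tm_dot = fcn$params$tm_dot)
  pred_tied <- predict_muscle_temperature(ser_n$ta_c, tied, ser_n$tb_c[1])
  expect_equal(sum((ser_n$tb_c - pred_tied)^2), fcn$rss, tolerance = 1e-10)
  fvn <- fit_heat_model(ser_n, kind = "variable")
  expect_lte(fvn$rss, fcn$rss * (1 + 1e-6))

  # an equilibrated, constant-ambient series carries no information about k
  n <- 100
  flat <- tag_series(0:(n - 1), rep(10, n), ta = rep(20, n),
                     tb = rep(20, n))
  expect_error(fit_heat_model(flat), "degenerate")
})

test_that("fits recover two-regime truths under measurement noise", {
  truth <- mako1_params()
  ser <- make_deployment(seed = 31, noise_sd = 0.1, params = truth)
  f <- fit_heat_model(ser, kind = "variable")
  rel <- c(abs(f$params$k_warm - 0.052) / 0.052,
           abs(f$params$k_cool - 0.0036) / 0.0036,
           abs(f$params$tm_dot - 0.0062) / 0.0062)
  expect_true(all(rel < 0.25))
})

test_that("model selection prefers lower AIC unless the MAE guard trips", {
  stub <- function(mae, aic, n = 1321) {
    structure(list(mae = mae, aic = aic, n = n), class = "heat_fit")
  }
  # strong two-regime signal: variable model wins outright
  s1 <- select_heat_model(stub(0.566, -901.4), stub(0.243, -3119.1))
  expect_equal(s1$selected, "variable")
  expect_false(s1$guard_applied)
  expect_gt(s1$mae_improvement, 0.5)

  # near-identical errors: overfit guard keeps the constant model
  s4 <- select_heat_model(stub(0.164, -2212.0), stub(0.157, -2306.4))
  expect_equal(s4$selected, "constant")
  expect_true(s4$guard_applied)
  expect_lt(s4$mae_improvement, 0.10)

  tie <- select_heat_model(stub(0.2, -100), stub(0.2, -100))
  expect_equal(tie$selected, "constant")

  expect_error(select_heat_model(stub(0.2, -100, n = 50),
                                 stub(0.2, -100, n = 60)),
               "identical data")
})
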