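test_that("triexponential fitting recovers a noiseless curve by RMSE", {
  tt <- seq(0, 120, length.out = 30)
  y <- -20 * exp(-0.5 * tt) + 12 * exp(-0.05 * tt) + 8 * exp(-0.049 * tt)
  m <- fit_triexponential(ts_profile(tt, y, "min", "mg", "amount"), seed = 1)
  expect_lt(m$fit_rmse, 0.001 * max(abs(y)))  # curve agreement, not parameters
  expect_equal(triexp_value(m, 0), 0, tolerance = 1e-9)  # f(0) = 0 constraint
})

test_that("degenerate triexponential inputs are handled exactly", {
  tt <- seq(0, 60, length.out = 12)
  zero <- ts_profile(tt, rep(0, 12), "min", "mg", "amount")
  m0 <- fit_triexponential(zero)
  expect_equal(m0$fit_rmse, 0)
  expect_equal(triexp_value(m0, tt), rep(0, 12))
  # monoexponential data: surplus terms absorb into one
  y1 <- 5 * exp(-0.1 * tt)
  m1 <- fit_triexponential(ts_profile(tt, y1, "min", "mg", "amount"),
                           constrain_origin = FALSE, seed = 1)
  expect_lt(m1$fit_rmse, 0.001 * 5)
  expect_error(fit_triexponential(ts_profile(c(0, 1), c(0, 1), "min", "mg", "amount")),
               "at least 6")
})

test_that("profile extension continues a pure exponential exactly", {
  k <- 0.08
  ref <- triexp_model(0, 0, 10, 1, 1, k, t_end = 120)
  tt <- seq(0, 40, by = 5)
  trunc <- ts_profile(tt, 10 * exp(-k * tt), "min", "mg", "amount")
  ext <- extend_profile(trunc, ref, n_points = 2)
  expect_equal(length(ext$times), length(tt) + 2)
  expect_equal(ext$values, 10 * exp(-k * ext$times), tolerance = 1e-9)
  expect_equal(ext$values[seq_along(tt)], trunc$values)  # originals untouched
  expect_identical(extend_profile(trunc, ref, n_points = 0), trunc)
  expect_error(extend_profile(trunc, "not a model"), "reference")
})

test_that("extension slope matches the reference terminal slope", {
  fam <- sim_family(c(0.2), duration = 43)
  jj_trunc <- compartment_profile(fam[[1]], "jejunum")
  # reference descent fitted on a full-length analogue (known rise-and-fall)
  ref <- triexp_model(-30, 18, 12, 0.4, 0.04, 0.039, t_end = 215)
  ext <- extend_profile(jj_trunc, ref, n_points = 2)
  n <- length(ext$values)
  got <- -diff(log(ext$values[(n - 1):n])) / diff(ext$times[(n - 1):n])
  want <- -(log(triexp_value(ref, ref$t_end)) -
              log(triexp_value(ref, ref$t_end - 1e-4))) / 1e-4
  expect_equal(got, want, tolerance = 0.01)
})

test_that("the logarithmic time scaling satisfies its anchors and inverts", {
  sc <- fit_time_scaling(13, 0.75, 43, 12)
  expect_equal(scale_time(sc, 0.75), 13, tolerance = 1e-8)
  expect_equal(scale_time(sc, 12), 43, tolerance = 1e-8)
  set.seed(9)
  tt <- runif(100, 0, 24)
  expect_equal(unscale_time(sc, scale_time(sc, tt)), tt, tolerance = 1e-9)
  expect_true(all(diff(scale_time(sc, sort(tt))) > 0))  # strictly increasing
  # linear-compatible anchors collapse to the beta -> 0 series limit
  sc_lin <- fit_time_scaling(10, 1, 120, 12)
  expect_equal(scale_time(sc_lin, c(1, 6, 12)), c(10, 60, 120), tolerance = 1e-4)
  expect_error(fit_time_scaling(50, 0.75, 43, 12), "anchors")
})

test_that("scaling constants are recovered from self-generated plasma", {
  tt <- seq(0, 120, length.out = 30)
  m1 <- triexp_model(-30, 18, 12, 0.4, 0.04, 0.039, t_end = 120)
  m2 <- triexp_model(-20, 12, 8, 0.5, 0.05, 0.049, t_end = 120)
  sc <- fit_time_scaling(13, 0.75, 43, 12)
  times_h <- seq(0.25, 12, by = 0.25)
  plasma <- lapply(list(m1, m2), function(m)
    ts_profile(times_h, 50 * triexp_value(m, scale_time(sc, times_h)),
               "h", "ng/mL", "concentration"))
  consts <- fit_scaling_constants(list(m1, m2), plasma, sc, seed = 1)
  expect_equal(consts$const1, 50, tolerance = 1e-6)
  expect_equal(consts$const2, 0, tolerance = 1e-5)
  # nested models: with a true nonzero offset, forcing CONST2 = 0 must fit worse
  plasma_off <- lapply(plasma, function(p)
    ts_profile(p$times, p$values + 5, "h", "ng/mL", "concentration"))
  two <- fit_scaling_constants(list(m1, m2), plasma_off, sc, seed = 1)
  one <- fit_scaling_constants(list(m1, m2), plasma_off, sc,
                               fix_const2 = TRUE, seed = 1)
  expect_equal(two$const2, 5, tolerance = 1e-4)
  expect_gt(one$pooled_rmse, two$pooled_rmse)
})

test_that("compartmental predictions respect the scaling geometry", {
  m <- triexp_model(-20, 12, 8, 0.5, 0.05, 0.049, t_end = 120)
  sc <- fit_time_scaling(13, 0.75, 43, 12)
  model <- compartmental_ivivr(list(a = m), sc,
                               list(const1 = 50, const2 = 0))
  times_h <- seq(0.01, 12, by = 0.01)
  pred <- predict_plasma_compartmental(model, m, times_h)
  # Tmax of the prediction sits at the unscaled in vitro peak time
  vitro_t <- seq(0.01, 43, by = 0.01)
  peak_vitro <- vitro_t[which.max(triexp_value(m, vitro_t))]
  expect_equal(cmax_tmax(pred)$tmax, unscale_time(sc, peak_vitro), tolerance = 0.05)
  # const1 = 0 gives a flat profile at const2 (constructed directly;
  # the constructor itself requires a nonzero const1)
  flat <- structure(list(scaling = sc, const1 = 0, const2 = 7),
                    class = "compartmental_ivivr")
  expect_equal(predict_plasma_compartmental(flat, m, c(1, 2))$values, c(7, 7))
  expect_error(compartmental_ivivr(list(a = m), sc, list(const1 = 0, const2 = 1)),
               "nonzero")
  expect_error(predict_plasma_compartmental(model, m, c(-1, 1)), "t >= 0")
})

test_that("the full compartmental pipeline recovers a held-out middle batch", {
  fam <- sim_family(c(0.1, 0.2, 0.4), duration = 215)
  curves <- lapply(fam, compartment_profile, compartment = "jejunum")
  fits <- lapply(1:3, function(i)
    fit_triexponential(curves[[i]], deps = fast_triexp_deps(i, 500L)))
  sc <- fit_time_scaling(cmax_tmax(curves[[1]])$tmax, 0.8,
                         max(curves[[1]]$times), 12)
  times_h <- seq(0.25, 12, by = 0.25)
  # ground-truth plasma generated from the model family itself
  plasma <- lapply(fits, function(m)
    ts_profile(times_h, pmax(50 * triexp_value(m, scale_time(sc, times_h)), 0),
               "h", "ng/mL", "concentration"))
  consts <- fit_scaling_constants(fits[c(1, 3)], plasma[c(1, 3)], sc, seed = 4)
  model <- compartmental_ivivr(fits[c(1, 3)], sc, consts)
  pred <- suppressWarnings(predict_plasma_compartmental(model, fits[[2]], times_h))
  rep <- prediction_error(plasma[[2]], pred, mode = "external")
  expect_lt(rep$cmax_pe_percent, 2)
  expect_lt(rep$pauc_pe_percent, 2)
})
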