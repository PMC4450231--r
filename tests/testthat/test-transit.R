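test_that("weak-acid solubility follows the Henderson-Hasselbalch form", {
  expect_equal(solubility_at_ph(0.01, 4.33, 4.33), 0.02)  # pH = pKa: 2 S0
  expect_equal(solubility_at_ph(0.01, 4.33, 2.4), 0.01 * (1 + 10^(-1.93)))
  # ceiling binds when the ionized fraction explodes
  expect_equal(solubility_at_ph(0.01, 4.33, 7.5, ceiling = 0.5), 0.5)
  expect_true(0.01 * (1 + 10^(7.5 - 4.33)) > 0.5)
})

test_that("the transit schedule moves exactly the mobile 200 mL to the canister", {
  ds <- simulate_transit(golem_method(215, withdrawal_mL = 0), buffered_crystal())
  nt <- length(ds$times_min)
  expect_equal(ds$compartments$canister$volume$values[nt], 200, tolerance = 1e-9)
  for (nm in c("duodenum", "jejunum", "ileum"))
    expect_equal(ds$compartments[[nm]]$volume$values[nt], 33, tolerance = 1e-9)
  expect_equal(ds$compartments$stomach$volume$values[nt], 30, tolerance = 1e-9)
})

test_that("each compartment fills, plateaus and returns to its residual volume", {
  ds <- simulate_transit(golem_method(215, withdrawal_mL = 0), nonbuffered_amorphous())
  duo <- ds$compartments$duodenum$volume$values
  expect_gt(max(duo), 33)          # fills above its starting volume
  expect_equal(duo[length(duo)], 33, tolerance = 1e-9)
  # volume conservation at all sampling times
  tot <- Reduce(`+`, lapply(ds$compartments, function(cp) cp$volume$values))
  expect_equal(tot, rep(230 + 3 * 33, length(tot)), tolerance = 1e-9)
})

test_that("gastric dissolution discriminates buffered from nonbuffered designs", {
  method <- golem_method(43)
  non <- simulate_transit(method, nonbuffered_amorphous())
  buf <- simulate_transit(method, buffered_crystal())
  pct_non <- 100 * max(non$compartments$stomach$dissolved$values) / non$dose_mg
  pct_buf <- 100 * max(buf$compartments$stomach$dissolved$values) / buf$dose_mg
  expect_lt(pct_non, 0.5)   # rounds to 0% of dose
  expect_gt(pct_buf, 0)     # strictly positive under the raised gastric pH
  expect_gt(pct_buf, pct_non)
})

test_that("a zero-dose run dissolves nothing but follows the same transit", {
  method <- golem_method(43)
  zero <- simulate_transit(method, formulation_spec("blank", dose_mg = 0))
  dosed <- simulate_transit(method, nonbuffered_amorphous())
  for (nm in names(zero$compartments)) {
    expect_true(all(zero$compartments[[nm]]$dissolved$values == 0))
    expect_equal(zero$compartments[[nm]]$volume$values,
                 dosed$compartments[[nm]]$volume$values, tolerance = 1e-9)
  }
})

test_that("drug mass is conserved for randomized configurations", {
  set.seed(101)
  for (i in 1:6) {
    method <- golem_method(sample(c(43, 90, 215), 1),
                           withdrawal_mL = runif(1, 0, 2),
                           integration_step_min = runif(1, 0.05, 0.5))
    form <- formulation_spec(paste0("rnd", i), dose_mg = runif(1, 20, 160),
                             buffered = runif(1) < 0.5,
                             intrinsic_solubility_mg_per_mL = runif(1, 5e-4, 5e-3),
                             dissolution_rate_coeff_z = runif(1, 0.02, 0.5),
                             disintegration_time_min = runif(1, 0, 5))
    ds <- simulate_transit(method, form)
    expect_lt(attr(ds, "mass_balance"), 1e-6)
  }
})

test_that("halving the integration step barely moves the results", {
  coarse <- simulate_transit(golem_method(43, integration_step_min = 0.2),
                             buffered_crystal())
  fine <- simulate_transit(golem_method(43, integration_step_min = 0.1),
                           buffered_crystal())
  for (nm in c("stomach", "jejunum", "canister")) {
    a <- coarse$compartments[[nm]]$dissolved$values
    b <- fine$compartments[[nm]]$dissolved$values
    expect_lt(max(abs(a - b)) / max(max(b), 1e-9), 0.005)
  }
})

test_that("the integration step stability guard rejects coarse steps", {
  expect_error(golem_method(43, integration_step_min = 2), "stability guard")
  expect_error(golem_method(43, integration_step_min = 0), "positive")
})

test_that("observation noise is lognormal, seeded and reproducible", {
  a <- simulate_transit(golem_method(43), nonbuffered_amorphous(),
                        noise_sd = 0.05, seed = 7)
  b <- simulate_transit(golem_method(43), nonbuffered_amorphous(),
                        noise_sd = 0.05, seed = 7)
  cc <- simulate_transit(golem_method(43), nonbuffered_amorphous(),
                         noise_sd = 0.05, seed = 8)
  expect_identical(a$compartments$jejunum$dissolved$values,
                   b$compartments$jejunum$dissolved$values)
  expect_false(identical(a$compartments$jejunum$dissolved$values,
                         cc$compartments$jejunum$dissolved$values))
  expect_true(all(a$compartments$jejunum$dissolved$values >= 0))
})

test_that("buffered formulations dissolve more in the stomach by 43 min", {
  buf <- simulate_transit(golem_method(43), buffered_crystal())
  non <- simulate_transit(golem_method(43), nonbuffered_amorphous())
  cf_buf <- cumulative_fraction(buf, "stomach")
  cf_non <- cumulative_fraction(non, "stomach")
  nt <- length(cf_buf$values)
  expect_gt(cf_buf$values[nt], cf_non$values[nt])
})
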