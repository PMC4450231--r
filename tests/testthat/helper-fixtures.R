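# shared fixtures, all generated in code

# random biexponential disposition kernel with well-separated phases
make_random_uir <- function(seed) {
  set.seed(seed)
  uir_spec(data.frame(C = c(runif(1, 50, 200), runif(1, 10, 50)),
                      lambda = c(runif(1, 1.5, 3), runif(1, 0.1, 0.5))),
           dose_basis_mg = 80)
}

# random monotone cumulative absorption curve on [0, 12] h
make_monotone_fabs <- function(seed, times_h = seq(0, 12, by = 0.05)) {
  set.seed(seed)
  ka <- runif(1, 0.5, 3)
  fmax <- runif(1, 0.6, 1)
  tlag <- runif(1, 0, 0.5)
  v <- fmax * (1 - exp(-ka * pmax(times_h - tlag, 0)))
  ts_profile(times_h, v, "h", "fraction", "fraction")
}

# hand-made two-compartment dataset: 40 of 80 mg dissolved at the end,
# 8 mg of it sitting in the ileum
tiny_dataset <- function() {
  tt <- c(5, 10, 20)
  mk <- function(v) ts_profile(tt, v, "min", "mg", "amount")
  comps <- list(
    jejunum = list(dissolved = mk(c(10, 20, 32)), volume = mk(c(33, 40, 33)),
                   ph = mk(c(6.6, 6.6, 6.6))),
    ileum = list(dissolved = mk(c(0, 4, 8)), volume = mk(c(33, 33, 33)),
                 ph = mk(c(7.4, 7.4, 7.4))))
  dissolution_dataset("tiny", 80, comps)
}

# simulated formulation family with slow/medium/fast dissolution rates
sim_family <- function(z_values = c(0.1, 0.2, 0.4), duration = 43) {
  method <- golem_method(duration)
  lapply(seq_along(z_values), function(i)
    simulate_transit(method,
                     nonbuffered_amorphous(sprintf("batch%02d", i),
                                           dissolution_rate_coeff_z = z_values[i])))
}

# reduced DEPS budget for fits inside tests (numerics verified at full
# budget in the dedicated fitting tests)
fast_triexp_deps <- function(seed, generations = 500L) {
  deps_config(rbind(c(0, 1)), seed = seed, population_size = 80L,
              max_generations = generations, stagnation_window = 400L,
              tolerance = 1e-12)
}
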