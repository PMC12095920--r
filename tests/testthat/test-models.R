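test_that("kinetic_model validates parameters per mechanism", {
  expect_error(kinetic_model("fragmentation", kn = 1e-4, kplus = 5),
               "kminus")
  expect_error(kinetic_model("nucleation_elongation", kn = 1e-4, kplus = 5,
                             kminus = 1), "irrelevant")
  expect_error(kinetic_model("fragmentation", kn = -1, kplus = 5,
                             kminus = 1), "nonnegative")
  m <- frag_model()
  expect_s3_class(m, "kinetic_model")
  expect_null(m$k2)
})

test_that("simulate_model conserves mass and stays monotone in [0,1]", {
  times <- seq(0, 30, by = 0.1)
  zero <- kinetic_model("fragmentation", kn = 0, kplus = 0, kminus = 0)
  expect_equal(simulate_model(zero, 10, times), rep(0, length(times)))
  set.seed(31)
  for (r in 1:8) {
    nm <- sample(c("nucleation_elongation", "secondary_nucleation",
                   "fragmentation", "saturating_elongation_fragmentation"), 1)
    args <- list(name = nm, kn = 10^runif(1, -8, -3),
                 kplus = 10^runif(1, 0, 2))
    if (nm %in% c("fragmentation", "saturating_elongation_fragmentation"))
      args$kminus <- 10^runif(1, -3, -1)
    if (nm == "secondary_nucleation") args$k2 <- 10^runif(1, -5, -2)
    if (nm == "saturating_elongation_fragmentation")
      args$KS <- 10^runif(1, -1, 1)
    mass <- simulate_model(do.call(kinetic_model, args), 10, times)
    expect_true(all(diff(mass) >= -1e-10))
    expect_true(all(mass >= 0 & mass <= 1))
  }
  expect_error(simulate_model(frag_model(), -1, times), "positive")
  expect_error(simulate_model(frag_model(), 10, c(1, 2)), "from 0")
})

test_that("integrator matches an independent fixed-step RK4 oracle", {
  times <- seq(0, 10, by = 1)
  for (model in list(frag_model(), ne_model(), sat_model())) {
    fast <- simulate_model(model, 10, times, atol = 1e-30)
    slow <- rk4_oracle(model, 10, times, dt = 1e-3)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("tightening the integrator tolerance changes nothing above 1e-6", {
  times <- seq(0, 30, by = 0.1)
  a <- simulate_model(frag_model(), 10, times, rtol = 1e-8, atol = 1e-30)
  b <- simulate_model(frag_model(), 10, times, rtol = 1e-10, atol = 1e-30)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("half-time scaling exponents match mechanism theory", {
  sc_frag <- halftime_scaling(scaling_m0s, model_halftimes(frag_model()))
  expect_lt(abs(sc_frag$slope - (-0.5)), 0.05)
  expect_gt(sc_frag$r_squared, 0.99)
  sc_ne <- halftime_scaling(scaling_m0s, model_halftimes(ne_model()))
  expect_lt(abs(sc_ne$slope - (-1)), 0.1)
  sc_sn <- halftime_scaling(scaling_m0s, model_halftimes(sn_model()))
  expect_lt(abs(sc_sn$slope - (-1.5)), 0.1)
  sc_sat <- halftime_scaling(scaling_m0s, model_halftimes(sat_model()))
  expect_lt(abs(sc_sat$slope), 0.1)
})

test_that("global_fit recovers the identifiable fragmentation combination", {
  df <- gen_model_series(frag_model(), c(2.5, 5, 10, 20),
                         times = seq(0, 48, by = 0.25), noise_sd = 0.01,
                         seed = 42)
  curves <- series_to_curves(df)
  res <- global_fit("fragmentation", curves, seed = 7)
  expect_true(res$converged)
  # kappa = sqrt(2 kplus kminus m0) is the identifiable combination
  kap_true <- sqrt(2 * 80 * 0.01)
  kap_fit <- sqrt(2 * res$fitted_params[["kplus"]] *
                    res$fitted_params[["kminus"]])
  expect_lt(abs(kap_fit - kap_true) / kap_true, 0.1)
  # MRE ordering mirrors the model-selection logic
  mre_ne <- global_fit("nucleation_elongation", curves, seed = 7)$mre
  mre_sn <- global_fit("secondary_nucleation", curves, seed = 7)$mre
  expect_lt(res$mre, mre_ne)
  expect_lt(res$mre, mre_sn)
  # invariance under curve reordering
  res_rev <- global_fit("fragmentation", rev(curves), seed = 7)
  expect_equal(res_rev$mre, res$mre, tolerance = 1e-8)
})

test_that("fitting a model to its own noiseless output is near-exact", {
  df <- gen_model_series(ne_model(), c(5, 10, 20),
                         times = seq(0, 48, by = 0.5), noise_sd = 0)
  res <- global_fit("nucleation_elongation", series_to_curves(df), seed = 3)
  expect_true(res$converged)
  expect_lt(res$mre, 1e-6)
})

test_that("global_fit rejects degenerate inputs", {
  good <- series_to_curves(gen_model_series(ne_model(), c(5, 10, 20),
                                            times = seq(0, 20, by = 0.5)))
  expect_error(global_fit("fragmentation", good[1:2]), "at least 3")
  flat <- lapply(c(5, 10, 20), function(m0)
    list(m0 = m0, times = 0:20, mass = rep(0, 21)))
  expect_false(global_fit("fragmentation", flat, n_starts = 2)$converged)
})

test_that("select_model takes the MRE argmin and refuses ties", {
  mk <- function(name, mre)
    structure(list(model = list(name = name), mre = mre,
                   converged = TRUE), class = "global_fit_result")
  sel <- select_model(list(mk("a", 0.01), mk("b", 0.07)))
  expect_equal(sel$best, "a")
  expect_equal(sel$mre_table$mre, c(0.01, 0.07))
  expect_error(select_model(list(mk("a", 0.05), mk("b", 0.05))), "tie")
  expect_error(select_model(list()), "no fit results")
})

test_that("cross-model selection study picks the generating mechanism", {
  df <- gen_model_series(sn_model(), c(2.5, 5, 10),
                         times = seq(0, 30, by = 0.25), noise_sd = 0.01,
                         seed = 11)
  curves <- series_to_curves(df)
  res <- lapply(c("nucleation_elongation", "secondary_nucleation",
                  "fragmentation"), global_fit, curves = curves, seed = 5)
  expect_equal(select_model(res)$best, "secondary_nucleation")
})
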