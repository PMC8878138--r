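test_that("piecewise activity law hits its published anchors", {
  p <- activity_params()
  # homeostasis: both activities vanish at and below W0
  expect_identical(osteoblast_activity(p$W0, p), 0)
  expect_identical(osteoclast_activity(p$W0, p), 0)
  expect_identical(combined_activity(0, p), 0)
  # caps at the upper thresholds equal the printed A1/A2
  expect_equal(osteoblast_activity(p$W1, p), 1992.36, tolerance = 1e-3)
  expect_equal(osteoclast_activity(p$W3, p), -2232.38, tolerance = 1e-3)
  # halfway up the formation ramp: half the cap
  expect_equal(osteoblast_activity((p$W0 + p$W1) / 2, p), 996.18,
               tolerance = 1e-3)
  # at the balance energy the osteoclasts exactly cancel the A1 cap
  expect_equal(osteoclast_activity(p$W2, p), -p$A1, tolerance = 1e-6)
})

test_that("published parameter row is internally consistent", {
  p <- activity_params()
  expect_lt(abs(p$A1 - p$k1 * (p$W1 - p$W0)) / p$A1, 1e-3)
  expect_lt(abs(p$A2 - p$k2 * (p$W3 - p$W0)) / abs(p$A2), 1e-3)
  # inconsistent rows are refused
  expect_error(activity_params(A1 = 1000), "A1")
})

test_that("net activity has zeros exactly at W0 and W2 and caps above W3", {
  p <- activity_params()
  expect_identical(combined_activity(p$W0, p), 0)
  expect_equal(combined_activity(p$W2, p), 0, tolerance = 1e-9)
  expect_equal(combined_activity(p$W1, p), 59.985, tolerance = 1e-3)
  # at W3 the k2 ramp meets the printed cap to its rounding precision ...
  expect_equal(combined_activity(p$W3, p), -240.02, tolerance = 1e-4)
  # ... and well above W3 both caps apply exactly
  expect_identical(combined_activity(1.5 * p$W3, p), p$A1 + p$A2)
  # sign pattern over the whole range
  W <- seq(p$W0, p$W3 * 1.5, length.out = 400)
  s <- combined_activity(W, p)
  expect_true(all(s[W > p$W0 & W < p$W2] > 0))
  expect_true(all(s[W > p$W2] < 0))
  # monotone up on [W0, W1], monotone down on [W1, W3]
  up <- combined_activity(seq(p$W0, p$W1, length.out = 50), p)
  dn <- combined_activity(seq(p$W1, p$W3, length.out = 50), p)
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(dn) <= 0))
})

test_that("modulation factor behaves as (alpha - rho)^n", {
  expect_identical(modulation(1, 1, 13.6), 0)
  expect_identical(modulation(0, 1, 13.6), 1)
  expect_equal(modulation(0.56, 1.0009, 13.6), 1.455e-5, tolerance = 1e-3)
  rho <- seq(0, 1, by = 0.05)
  expect_true(all(diff(modulation(rho, 1.0009, 5)) < 0))
  expect_warning(out <- modulation(1.2, 1, 5), "clamped")
  expect_identical(out, 0)
})

test_that("modulation power and ceilings interpolate in energy", {
  p <- activity_params()
  m <- modulation_params()
  expect_equal(interpolate_n(p$W1, m, p)$n, 13.6)
  expect_equal(interpolate_n(p$W3, m, p)$n, 5)
  expect_equal(interpolate_n(p$W0, m, p)$n, 13.6)      # clamped below W1
  expect_equal(interpolate_n(2 * p$W3, m, p)$n, 5)     # clamped above W3
  mid <- (p$W1 + p$W3) / 2
  expect_equal(interpolate_n(mid, m, p)$n, 9.3)
  expect_equal(interpolate_n(mid, m, p)$alpha_ob, (1.0009 + 1.0007) / 2)
  mq <- modulation_params(n_interpolation = "quadratic")
  expect_equal(interpolate_n(mid, mq, p)$n, 13.6 + (5 - 13.6) * 0.25)
})

test_that("activation delay filters toward the target and none passes through", {
  none <- delay_params("none")
  expect_identical(delayed_activity(5, 0, none, 0.1), 5)
  slow <- delay_params("slow")
  expect_equal(slow$coefficient, 1e-5)
  expect_gt(slow$rate_per_day, delay_params("low")$rate_per_day)
  # constant target: monotone convergence to the fixed point
  a <- 0
  hist <- replicate(200, a <<- delayed_activity(10, a, delay_params("slow",
    rate_per_day = 0.2), 0.5))
  expect_true(all(diff(hist) > 0))
  expect_lt(abs(hist[200] - 10), 1e-7)
  expect_error(delay_params("slow", coefficient = -1), "positive")
})

test_that("slow delay retards the density response of an overload run", {
  t_drop <- function(res, pct = 0.25) {
    s <- res$snapshots
    rel <- (s$mean_density / s$mean_density[1] - 1) * 100
    s$time_days[which(rel <= -pct)[1]]
  }
  rn <- run_scenario(fast_config("continuous", duration = 21))
  rs <- run_scenario(fast_config("continuous", duration = 21,
                                 delay = delay_params("slow")))
  expect_gt(t_drop(rs), t_drop(rn))
  # delayed activities are weaker early on
  expect_lt(abs(rs$snapshots$global_oc_activity[2]),
            abs(rn$snapshots$global_oc_activity[2]))
})

test_that("homeostatic energy leaves the density field unchanged", {
  res <- run_scenario(fast_config("sedentary", duration = 14))
  expect_equal(res$final_density, res$initial_density, tolerance = 1e-14)
  expect_identical(res$net_mass, 0)
})

test_that("uniform balance energy with equal ceilings is stationary", {
  p <- activity_params()
  mod_eq <- modulation_params(alpha_oc_W1 = 1.0009, alpha_oc_W3 = 1.0007)
  m <- coarse_mesh(0.3, 1L)
  state <- list(time = 0, density = rep(0.5, m$n_elem),
                activity_ob = numeric(m$n_elem),
                activity_oc = numeric(m$n_elem),
                W = rep(p$W2, m$n_elem),
                formed_mass = 0, resorbed_mass = 0, net_mass = 0)
  st <- step_density(state, 0.5, m, p, mod_eq)
  expect_equal(st$density, state$density, tolerance = 1e-12)
})

test_that("uniform fields evolve homogeneously (modulation cannot break symmetry)", {
  p <- activity_params()
  m <- coarse_mesh(0.3, 2L)
  state <- list(time = 0, density = rep(0.3, m$n_elem),
                activity_ob = numeric(m$n_elem),
                activity_oc = numeric(m$n_elem),
                W = rep(p$W1, m$n_elem),
                formed_mass = 0, resorbed_mass = 0, net_mass = 0)
  for (i in 1:20) state <- step_density(state, 0.5, m, p)
  expect_lt(diff(range(state$density)), 1e-14)
  # formation regime at low density: density rose
  expect_gt(state$density[1], 0.3)
})

test_that("explicit step rejects unstable inputs", {
  p <- activity_params()
  m <- coarse_mesh(0.3, 1L)
  state <- list(time = 0, density = rep(0.5, m$n_elem),
                activity_ob = numeric(m$n_elem),
                activity_oc = numeric(m$n_elem),
                W = rep(p$W1, m$n_elem),
                formed_mass = 0, resorbed_mass = 0, net_mass = 0)
  expect_error(step_density(state, 1, m, p), "0.5")
  state$W <- rep(NaN, m$n_elem)
  expect_error(step_density(state, 0.1, m, p))
})

test_that("mass ledger balances the density change exactly", {
  res <- run_scenario(fast_config("continuous", duration = 14))
  drho <- res$final_density - res$initial_density
  net <- sum(drho * res$mesh$elem_volume) * 1  # rho_ref = 1 mg/mm^3
  expect_equal(res$net_mass, net, tolerance = 1e-9)
  expect_equal(res$net_mass, res$formed_mass + res$resorbed_mass,
               tolerance = 1e-9)
  expect_lt(res$resorbed_mass, 0)
})

test_that("density stays inside [floor, alpha] in formation and resorption runs", {
  ri <- run_scenario(fast_config("intermittent", duration = 21))
  rc <- run_scenario(fast_config("continuous", duration = 21))
  for (r in list(ri, rc)) {
    expect_gte(min(r$final_density), 0.01 - 1e-12)
    expect_lte(max(r$final_density), 1.0009 + 1e-12)
  }
})
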