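test_that("closed-form ferric yield matches the stoichiometric relation", {
  y <- primary_yields()  # g(H)+g(eaq) = 3.70, g(OH) = 2.92, g(H2O2) = 0.78
  expect_equal(g_value_closed_form(y, aerated = TRUE), 15.58)
  expect_equal(g_value_closed_form(y, aerated = FALSE), 8.18)
  expect_equal(g_value_closed_form(primary_yields(0, 0, 0, 0)), 0)
  # hydrated electrons count with H atoms
  split <- primary_yields(g_eaq = 1.5, g_h = 2.2)
  expect_equal(g_value_closed_form(split), 15.58)
})

test_that("network construction enforces balance and rate-constant validity", {
  net <- fricke_reaction_network()
  expect_s3_class(net, "reaction_network")
  expect_length(net$k, 7)
  expect_equal(net$k, c(1.12e10, 2.1e10, 1.3e7, 3.4e8, 7.9e5, 2.66e10, 52))
  expect_error(fricke_reaction_network(k = c(1, 2)), "seven")
  expect_error(fricke_reaction_network(k = c(-1, rep(1, 6))), "positive")
})

test_that("zero dose rate leaves the solution unoxidized", {
  prof <- dose_rate_profile("constant", 0)
  traj <- simulate_fricke_kinetics(prof, duration_s = 60, n_out = 11)
  expect_true(all(traj$Fe3 == 0))
  expect_equal(traj$Fe2, rep(1e-3, 11))
})

test_that("simulated G-value agrees with the closed form within 1%", {
  g_aer <- g_value_ode()
  expect_lt(abs(g_aer / g_value_closed_form() - 1), 0.01)
  g_anox <- g_value_ode(aerated = FALSE)
  expect_lt(abs(g_anox / g_value_closed_form(aerated = FALSE) - 1), 0.01)
  # splitting the reducing yield between e_aq and H changes nothing: the
  # acid converts hydrated electrons to H atoms quantitatively
  g_split <- g_value_ode(yields = primary_yields(g_eaq = 1.85, g_h = 1.85))
  expect_equal(g_split, g_aer, tolerance = 1e-4)
})

test_that("iron is conserved along every trajectory", {
  prof <- dose_rate_profile("constant", 0.78 / 60, beam_on_s = 30)
  for (aer in c(TRUE, FALSE)) {
    traj <- simulate_fricke_kinetics(
      prof, 330, initial = initial_fricke_state(aerated = aer))
    expect_lt(max(abs(traj$Fe2 + traj$Fe3 - 1e-3)), 1e-9)
    expect_true(all(traj[-1] > -1e-12))
  }
})

test_that("a decaying radiotracer source drives dose-proportional oxidation", {
  lam_s <- decay_constant(f18(), "per_sec")
  prof <- dose_rate_profile("decaying_source", 1e-4, lambda_s = lam_s)
  traj <- simulate_fricke_kinetics(prof, duration_s = 2 * 3600, n_out = 101)
  # cumulative ferric ion curve tracks the cumulative dose curve once past
  # the initial chemical lag (the slow ferrous + peroxide step, ~20 s)
  dose_curve <- prof$cumulative(traj$time_s)
  keep <- dose_curve > 0.1 * max(dose_curve)
  shape <- traj$Fe3[keep] / dose_curve[keep]
  expect_lt(diff(range(shape)) / mean(shape), 0.05)
  expect_lt(abs(g_value_from_simulation(traj) / g_value_closed_form() - 1),
            0.01)
})

test_that("oxygen depletion time is finite under heavy beams and infinite otherwise", {
  expect_identical(oxygen_depletion_time(dose_rate_profile("constant", 0), 100),
                   Inf)
  t_dep <- vapply(c(5, 10, 20), function(r) {
    oxygen_depletion_time(dose_rate_profile("constant", r), 300, n_out = 601)
  }, numeric(1))
  expect_true(all(is.finite(t_dep)))
  expect_true(all(diff(t_dep) < 0))  # harder beams deplete sooner
})

test_that("radiotracer-scale exposures barely touch the dissolved oxygen", {
  # 12.5 Gy total from a decaying source: O2 consumption is bounded by the
  # H-atom yield and stays far below the 0.25 mM air saturation level
  lam_s <- decay_constant(f18(), "per_sec")
  r0 <- 12.5 * lam_s  # total cumulative dose 12.5 Gy
  prof <- dose_rate_profile("decaying_source", r0, lambda_s = lam_s)
  traj <- simulate_fricke_kinetics(prof, duration_s = 8 * 3600, n_out = 51)
  o2_drop <- 0.25e-3 - min(traj$O2)
  stoich_bound <- per_100ev_to_mol_per_joule(3.70) * 12.5 * 1.0227
  expect_lt(o2_drop, 1.05 * stoich_bound)
  expect_lt(o2_drop / 0.25e-3, 0.05)
})
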