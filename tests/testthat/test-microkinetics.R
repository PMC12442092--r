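test_that("Eyring constant matches direct formula evaluation", {
  # zero barrier: prefactor only
  expect_equal(eyring_rate(0, 393.15), KB * 393.15 / H, tolerance = 1e-12)
  # frozen hand-calculator value at 29 kcal/mol, 120 degC
  expect_equal(eyring_rate(29, 393.15), 6.205456402e-4, tolerance = 1e-8)
  # algebraic identity: adding RT ln(10) x divides k by 10^x
  T <- 393.15
  for (x in c(0.5, 1, 2.7)) {
    ratio <- eyring_rate(20 + R_KCAL * T * log(10) * x, T) /
      eyring_rate(20, T)
    expect_equal(ratio, 10^-x, tolerance = 1e-10)
  }
  expect_error(eyring_rate(-1, 300), "non-negative")
  expect_error(eyring_rate(10, -300), "positive")
})

test_that("rate constants fall with barrier and rise with temperature", {
  Ts <- seq(250, 500, by = 25)
  for (T in Ts) {
    k <- eyring_rate(seq(5, 45, by = 5), T)
    expect_true(all(diff(k) < 0))
  }
  k_T <- vapply(Ts, function(T) eyring_rate(20, T), numeric(1))
  expect_true(all(diff(k_T) > 0))
})

test_that("network construction obeys per-step free-energy bookkeeping", {
  net <- build_network(cu_acetone_profile())
  RT <- R_KCAL * 393.15
  for (s in net$steps) {
    # detailed balance: dG_forward - dG_back = dG_rxn exactly
    if (s$reversible) {
      expect_equal(log(s$k_f / s$k_b) * RT, -s$dG_rxn, tolerance = 1e-8)
    }
    expect_gte(s$dG_forward, 0)
    expect_gte(s$dG_forward - s$dG_rxn, -1e-12)
  }
  # the C-C addition forward barrier is measured TS2 - I4, while the overall
  # span from the I3 resting state is 45.4
  cc <- net$steps[[which(vapply(net$steps, `[[`, "", "step") == "cc_addition")]]
  expect_equal(cc$dG_forward, 44.0, tolerance = 1e-9)
  expect_equal(overall_barrier(cu_acetone_profile())$delta_G_dd, 45.4)
  # missing template position
  expect_error(build_network(gibbs_profile(data.frame(
    label = c("I1", "TS1", "I2"),
    role = c("intermediate", "transition_state", "intermediate"),
    G_rel = c(0, 10, -2)))), "missing template position")
})

test_that("thermoneutral barrierless step has equal forward/backward rates", {
  tpl <- data.frame(step = "iso", from = "A", to_species = "B",
                    to_energy = "B", ts = NA, co_react = NA, co_prod = NA,
                    reversible = TRUE, stringsAsFactors = FALSE)
  p <- gibbs_profile(data.frame(label = c("A", "B"),
                                role = c("intermediate", "intermediate"),
                                G_rel = c(0, 0)))
  net <- build_network(p, template = tpl)
  expect_equal(net$steps[[1]]$k_f, net$steps[[1]]$k_b, tolerance = 1e-12)
})

test_that("closed two-state system relaxes to the Boltzmann ratio", {
  # A <-> B with dG_rxn = -1 kcal/mol at 393.15 K
  tpl <- data.frame(step = "iso", from = "A", to_species = "B",
                    to_energy = "B", ts = "TSab", co_react = NA, co_prod = NA,
                    reversible = TRUE, stringsAsFactors = FALSE)
  p <- gibbs_profile(data.frame(
    label = c("A", "TSab", "B"),
    role = c("intermediate", "transition_state", "intermediate"),
    G_rel = c(0, 18, -1)))
  net <- build_network(p, template = tpl)
  cond <- sim_conditions(conc = c(A = 1), t_end = 1e6)
  tr <- simulate_network(net, cond)
  ratio <- tr$B[nrow(tr)] / tr$A[nrow(tr)]
  expect_equal(ratio, exp(1 / (R_KCAL * 393.15)), tolerance = 0.01)
})

test_that("catalytic traces conserve Cu, B and ketone-carbon totals", {
  tr <- simulate_network(build_network(cu_acetone_profile()))
  cu <- tr$I1 + tr$I2 + tr$I3 + tr$I4 + tr$I5
  b  <- tr$RB + tr$I3 + tr$BF
  ke <- tr$ketone + tr$I5 + tr$product
  expect_lt(max(abs(cu - cu[1])), 1e-9)
  expect_lt(max(abs(b - b[1])), 1e-9)
  expect_lt(max(abs(ke - ke[1])), 1e-9)
  expect_gte(min(as.matrix(tr[-1])), -1e-8)
})

test_that("no catalyst means no product", {
  cond <- sim_conditions(conc = c(I1 = 0, RB = 1, ketone = 1, CsF = 2))
  tr <- simulate_network(build_network(cu_acetone_profile()), cond)
  expect_equal(max(tr$product), 0)
  expect_equal(product_yield(tr, cond$t_end), 0)
})

test_that("yield queries: t = 0, completion limit, out-of-range errors", {
  prof <- generate_profile(20, generator_spec())
  tr <- simulate_network(build_network(prof))
  expect_equal(product_yield(tr, 0), 0)
  # a fast, strongly exergonic cycle runs to (numerically) full conversion
  expect_gt(product_yield(tr, hours16), 0.99)
  expect_error(product_yield(tr, 2 * hours16), "span")
  # the reference acetone system is kinetically dead over 16 h
  tra <- simulate_network(build_network(cu_acetone_profile()))
  expect_lt(product_yield(tra, hours16), 1e-6)
})
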