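test_that("profile validation enforces the structural invariants", {
  expect_error(gibbs_profile(data.frame(
    label = c("TS", "I"), role = c("transition_state", "intermediate"),
    G_rel = c(0, 1))), "start with a transition state")
  expect_error(gibbs_profile(data.frame(
    label = c("I", "I"), role = c("intermediate", "intermediate"),
    G_rel = c(0, 1))), "duplicate")
  expect_error(gibbs_profile(data.frame(
    label = c("I", "T1", "T2"),
    role = c("intermediate", "transition_state", "transition_state"),
    G_rel = c(0, 5, 6))), "consecutive")
  expect_error(gibbs_profile(data.frame(
    label = c("I", "T"), role = c("intermediate", "transition_state"),
    G_rel = c(1, 5))), "reference")
})

test_that("assembly from thermo records matches pre-subtracted energies", {
  s <- standard_state(T = 393.15)
  recs <- list(
    thermo_record("A", -500.0, 1.2, 0.010, role = "intermediate"),
    thermo_record("T", -480.0, 1.1, 0.009, role = "transition_state"),
    thermo_record("B", -505.0, 1.3, 0.011, role = "intermediate"))
  p <- assemble_profile(recs, system_id = "rec", state = s)
  G <- vapply(recs, gibbs_energy, numeric(1), state = s)
  p2 <- assemble_profile(data.frame(
    label = c("A", "T", "B"),
    role = c("intermediate", "transition_state", "intermediate"),
    G_rel = G - G[1]), system_id = "rel", state = s)
  expect_equal(p$points$G_rel, p2$points$G_rel, tolerance = 1e-12)
  expect_equal(p$points$G_rel[1], 0)
  # mixed units across records are rejected
  recs[[2]]$unit <- "hartree"
  expect_error(assemble_profile(recs, state = s), "mixed units")
})

test_that("reference acetone cycle gives the 45.4 kcal/mol span from I3", {
  br <- overall_barrier(cu_acetone_profile())
  expect_equal(br$delta_G_dd, 45.4)
  expect_equal(br$determining_ts, "TS2")
  expect_equal(br$resting_intermediate, "I3")
  expect_equal(br$regime, "cc_addition")
  # alternative reading of the TS1 placement does not change the span,
  # which is set by the C-C addition TS
  br2 <- overall_barrier(cu_acetone_profile(ts1_from = "I1"))
  expect_equal(br2$delta_G_dd, 45.4)
})

test_that("minimal profiles and regime fallbacks behave", {
  p <- gibbs_profile(data.frame(
    label = c("I", "TS", "P"),
    role = c("intermediate", "transition_state", "product"),
    G_rel = c(0, 10, -5)))
  br <- overall_barrier(p)
  expect_equal(br$delta_G_dd, 10)
  expect_equal(br$regime, "other")
  expect_error(overall_barrier(gibbs_profile(data.frame(
    label = c("I", "P"), role = c("intermediate", "product"),
    G_rel = c(0, -1)))), "no transition state")
})

test_that("span rule agrees with brute-force enumeration on random profiles", {
  set.seed(42)
  for (rep in 1:100) {
    p <- random_profile(n_ts = sample(1:3, 1))
    br <- overall_barrier(p)
    bf <- brute_force_barrier(p$points)
    expect_equal(br$delta_G_dd, bf$span, tolerance = 1e-10)
    expect_equal(br$determining_ts, bf$ts)
    expect_equal(br$resting_intermediate, bf$rest)
  }
})

test_that("span is invariant under uniform shifts and grows monotonically", {
  set.seed(11)
  p <- random_profile(n_ts = 3)
  br <- overall_barrier(p)$delta_G_dd
  # translation invariance: adding a constant to every level and
  # re-anchoring at the first point leaves the span unchanged
  shifted <- p$points
  shifted$G_rel <- (shifted$G_rel + 7.3) - (shifted$G_rel[1] + 7.3)
  expect_equal(overall_barrier(gibbs_profile(shifted))$delta_G_dd, br,
               tolerance = 1e-10)
  # removing a non-determining TS never increases the span
  det <- overall_barrier(p)$determining_ts
  other_ts <- setdiff(p$points$label[p$points$role == "transition_state"], det)
  for (ts in other_ts) {
    i <- match(ts, p$points$label)
    pr <- gibbs_profile(p$points[-i, ])
    expect_lte(overall_barrier(pr)$delta_G_dd, br + 1e-10)
  }
})

test_that("shift_ts realises a target span and warns below the floor", {
  p <- cu_acetone_profile()
  sh <- shift_ts(p, "TS2", 29)
  expect_equal(overall_barrier(sh)$delta_G_dd, 29, tolerance = 1e-12)
  # everything but TS2 untouched
  keep <- sh$points$label != "TS2"
  expect_equal(sh$points$G_rel[keep], p$points$G_rel[keep])
  # below the transmetalation-determined floor (16.9): regime switch warning
  expect_warning(sh2 <- shift_ts(p, "TS2", 10), "floor")
  expect_equal(overall_barrier(sh2)$delta_G_dd, 16.9, tolerance = 1e-12)
  expect_equal(overall_barrier(sh2)$regime, "transmetalation")
})
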