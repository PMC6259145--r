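test_that("atom-percent SA definition and edge cases", {
  expect_equal(sa_atom_percent(5, 5), 100)    # carrier-free
  expect_equal(sa_atom_percent(0, 7), 0)
  expect_equal(sa_atom_percent(1, 4), 25)
  expect_error(sa_atom_percent(1, 0), "undefined")
  expect_error(sa_atom_percent(3, 2), "exceed")
  expect_error(sa_atom_percent(-1, 2), "non-negative")
})

test_that("unit conversions are mutually consistent and invertible", {
  lam <- decay_constant("6.71d")
  sa <- specific_activity(100, 177, lam)
  # independent arithmetic: lambda * N_Av / M for the carrier-free case
  expect_equal(sa$bq_per_g, lam * 6.02214076e23 / 177)
  expect_equal(sa$bq_per_g, 4.07e15, tolerance = 1e-3)
  expect_equal(specific_activity(0, 177, lam)$bq_per_g, 0)
  # round trips through each unit
  for (from in c("bq_per_g", "bq_per_mol")) {
    back <- convert_sa(sa[[from]], from, 177, lam)
    expect_equal(back$atom_percent, 100, tolerance = 1e-12)
  }
  rt <- convert_sa(convert_sa(37.5, "atom_percent", 175.5, lam)$bq_per_g,
                   "bq_per_g", 175.5, lam)
  expect_equal(rt$atom_percent, 37.5, tolerance = 1e-12)
  # replication mode only swaps the Avogadro constant
  expect_equal(specific_activity(100, 177, lam, replication = TRUE)$bq_per_mol,
               lam * 6.02e23)
  expect_error(specific_activity(100, 177, 0), "decay constant")
  expect_error(specific_activity(101, 177, lam), "0, 100")
})

test_that("material atomic weight is the weight-percent harmonic mean", {
  expect_equal(material_atomic_weight(50, 123), 123)
  expect_equal(material_atomic_weight(c(50, 50), c(100, 200)), 100 / 0.75)
  expect_equal(material_atomic_weight(c(97.41, 2.59), c(175, 176)),
               100 / (97.41 / 175 + 2.59 / 176))
  expect_equal(material_atomic_weight(c(97.41, 2.59), c(175, 176)),
               175.03, tolerance = 1e-4)
  expect_error(material_atomic_weight(c(1, 2), 3), "equal length")
  expect_error(material_atomic_weight(0, 100), "positive")
})

test_that("two-isotope SA matches pooled-atom oracle trajectories", {
  set.seed(99)
  for (k in 1:30) {
    r <- rand_rates(2)
    sys <- toy_direct_system(r[1], r[2], P1 = stats::runif(1, 30, 95))
    consts <- depletion_constants(r[1], r[2])
    N0 <- initial_atoms(sys$target)
    ts <- rand_times(r)
    net <- capture_network(r[1], r[2], N0 = N0[[1]])
    tr <- integrate_network(net, ts)
    pooled <- 100 * tr[, "R"] / (tr[, "S"] + N0[[2]] + tr[, "R"])
    sa <- sa_two_isotope(sys$target, sys$channels, sys$field, ts)
    expect_rel(sa, pooled, 1e-8)
    expect_true(all(sa >= 0 & sa <= 100))
  }
})

test_that("SA shapes: interior maximum with impurity, monotone without", {
  lu <- load_fixture("lu176_enriched")
  f <- neutron_field(2.5e14, R_epi = 0.02)
  ts <- seq(1, 80 * 86400, length.out = 300)
  sa <- sa_two_isotope(lu$target, lu$channels, f, ts, production = "Lu-1")
  im <- which.max(sa)
  expect_gt(im, 1); expect_lt(im, length(ts))

  pure <- target_spec(1e-3, "Lu", list(isotope("Lu-176", 176,
                                               weight_percent = 100)))
  sa1 <- sa_one_isotope(pure, lu$channels, f, ts, production = "Lu-1")
  expect_true(all(diff(sa1) > 0))
  expect_equal(sa1[1], sa_general(pure, lu$channels, f, ts[1],
                                  production = "Lu-1"))
  expect_equal(sa_two_isotope(lu$target, lu$channels, f, 0,
                              production = "Lu-1"), 0)
  expect_error(sa_one_isotope(lu$target, lu$channels, f, ts,
                              production = "Lu-1"), "exactly one")
  expect_error(sa_two_isotope(pure, lu$channels, f, ts,
                              production = "Lu-1"), "exactly two")
})

test_that("a heavily burning impurity turns the target one-isotope-like", {
  # impurity with large elemental depletion burns away; SA approaches the
  # pure-target curve at long times
  parent <- isotope("S1-176", 176, weight_percent = 70)
  imp <- isotope("S2-175", 175, weight_percent = 30)
  prod <- isotope("R-177", 177, half_life = "6.71d")
  leak <- isotope("Q-175", 175, half_life = "1d")   # other element
  f <- neutron_field(1e14)
  chans <- list(
    prod = reaction_channel(parent, prod, 2000, label = "prod"),
    burn = reaction_channel(imp, leak, 8000, elemental_loss = TRUE,
                            label = "burn"))
  tgt <- target_spec(1e-3, "S", list(parent, imp))
  pure <- target_spec(1e-3, "S",
                      list(isotope("S1-176", 176, weight_percent = 100)))
  t_long <- 10 / (1e14 * 8000e-24)
  sa_imp <- sa_general(tgt, chans, f, t_long)
  sa_pure <- sa_general(pure, chans["prod"], f, t_long)
  expect_lt(abs(sa_imp - sa_pure) / sa_pure, 2e-3)
  # and the reductions are consistent at g = 1, 2
  expect_equal(sa_general(tgt, chans, f, 1e5),
               sa_two_isotope(tgt, chans, f, 1e5))
})

test_that("multi_as_two collapses impurities with harmonic atomic weight", {
  yb <- load_fixture("yb176_enriched")
  red <- multi_as_two(yb$target)
  expect_length(red$isotopes, 2)
  P <- vapply(yb$target$isotopes[-1], `[[`, numeric(1), "weight_percent")
  M <- vapply(yb$target$isotopes[-1], `[[`, numeric(1), "atomic_mass")
  expect_equal(red$isotopes[[2]]$weight_percent, sum(P))
  expect_equal(red$isotopes[[2]]$weight_percent, 2.41, tolerance = 1e-6)
  expect_equal(red$isotopes[[2]]$atomic_mass, sum(P) / sum(P / M))
  expect_equal(red$mass, yb$target$mass)
  # depleting impurities are refused when channels are supplied
  f <- neutron_field(1e14, R_epi = 0.02)
  expect_error(multi_as_two(yb$target, yb$channels, f), "depletion")
  # two-isotope target passes through untouched
  lu <- load_fixture("lu176_enriched")
  expect_identical(multi_as_two(lu$target), lu$target)
})

test_that("time_of_max_sa agrees with a grid-search oracle", {
  lu <- load_fixture("lu176_enriched")
  f <- neutron_field(2.5e14, R_epi = 0.02)
  t_star <- time_of_max_sa(lu$target, lu$channels, f, production = "Lu-1")
  expect_true(is.finite(t_star))
  ts <- seq(t_star / 5, t_star * 5, length.out = 4001)
  sa <- sa_two_isotope(lu$target, lu$channels, f, ts, production = "Lu-1")
  i <- which.max(sa)
  expect_equal(ts[i], t_star, tolerance = 2 * diff(ts[1:2]) / t_star)
  sa_star <- sa_two_isotope(lu$target, lu$channels, f, t_star,
                            production = "Lu-1")
  expect_gte(sa_star, max(sa) - 1e-9 * max(sa))
  # SA-optimal and yield-optimal times genuinely differ
  s <- saforge:::.sa_setup(lu$target, lu$channels, f, production = "Lu-1")
  t_y <- time_of_max_yield(s$consts)
  expect_gt(abs(t_star / t_y - 1), 0.1)
  # pure target: no maximum
  pure <- target_spec(1e-3, "Lu", list(isotope("Lu-176", 176,
                                               weight_percent = 100)))
  expect_true(is.na(time_of_max_sa(pure, lu$channels, f,
                                   production = "Lu-1")))
})

test_that("sa_at_max_yield: direct and auxiliary paths agree", {
  lu <- load_fixture("lu176_enriched")
  f <- neutron_field(2.5e14, R_epi = 0.02)
  a <- sa_at_max_yield(lu$target, lu$channels, f, production = "Lu-1",
                       method = "direct")
  b <- sa_at_max_yield(lu$target, lu$channels, f, production = "Lu-1",
                       method = "auxiliary")
  expect_rel(a, b, 1e-9)
  # SA at the yield optimum cannot beat the SA optimum
  t_sa <- time_of_max_sa(lu$target, lu$channels, f, production = "Lu-1")
  expect_lte(a, sa_two_isotope(lu$target, lu$channels, f, t_sa,
                               production = "Lu-1"))
  # randomized systems
  set.seed(5)
  for (k in 1:10) {
    r <- rand_rates(2, 1e-8, 1e-4)
    sys <- toy_direct_system(r[1], r[2])
    expect_rel(
      sa_at_max_yield(sys$target, sys$channels, sys$field,
                      method = "direct"),
      sa_at_max_yield(sys$target, sys$channels, sys$field,
                      method = "auxiliary"), 1e-9)
  }
})

test_that("SA increases with target enrichment at fixed time", {
  lu <- load_fixture("lu176_enriched")
  f <- neutron_field(1.7e14, R_epi = 0.02)
  t_fix <- 15 * 86400
  enr <- c(50, 60, 70, 74.1, 80, 90, 99)
  sa <- vapply(enr, function(e) {
    tgt <- target_spec(1e-3, "Lu",
                       list(isotope("Lu-176", 176, weight_percent = e),
                            isotope("Lu-175", 175,
                                    weight_percent = 100 - e)))
    sa_two_isotope(tgt, lu$channels, f, t_fix, production = "Lu-1")
  }, numeric(1))
  expect_true(all(diff(sa) > 0))
})
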