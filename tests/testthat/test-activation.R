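test_that("burn-up closed forms behave", {
  expect_equal(remaining_atoms(1e18, 1e-6, 0), 1e18)
  expect_equal(remaining_atoms(1e18, 1e-6, 1e6), 1e18 * exp(-1), tolerance = 1e-12)
  expect_equal(burned_atoms(1e18, 1e-6, 1e6), 1e18 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_error(remaining_atoms(1, 1e-6, -1), "non-negative")

  d <- 1.0005e-6                       # Lu-176 at 2.5e14 with k*sigma0
  expect_equal(half_burnup_time(d), log(2) / d)
  expect_equal(half_burnup_time(d) / 86400, 8.0, tolerance = 0.02)
  expect_equal(half_burnup_time(2 * d), half_burnup_time(d) / 2)
  expect_error(half_burnup_time(0), "positive")
  # half-burn-up definition round-trip
  expect_equal(remaining_atoms(10, d, half_burnup_time(d)), 5)
})

test_that("depletion_constant sums channels and scales with flux", {
  lu <- load_fixture("lu176_enriched")
  f <- neutron_field(2.5e14, R_epi = 0.02)
  ch1 <- lu$channels[["Lu-1"]]
  expect_equal(depletion_constant(ch1, f), 2.5e14 * 4002e-24)
  chs <- Filter(function(ch) ch$parent$symbol == "Lu-176", lu$channels)
  d_all <- depletion_constant(chs, f)
  expect_equal(d_all, 1.00e-6, tolerance = 2e-3)
  expect_equal(d_all,
               sum(vapply(chs, function(ch) depletion_constant(ch, f),
                          numeric(1))))
  expect_error(depletion_constant(list(), f), "at least one")
  expect_error(depletion_constant(unname(lu$channels[c(1, 4)]), f),
               "same parent")
})

test_that("product yield matches the linear-ODE oracle on random draws", {
  set.seed(42)
  for (k in 1:100) {
    r <- rand_rates(2)
    Delta1 <- r[1]; lambda <- r[2]
    Delta_Ri <- if (k %% 3 == 0) rand_rates(1) else 0
    sys <- toy_direct_system(Delta1, lambda)
    consts <- depletion_constants(Delta1, lambda, Delta_Ri)
    N0 <- initial_atoms(sys$target)[[1]]
    om <- omega(sys$channels$prod, sys$field)
    ts <- rand_times(c(r, if (Delta_Ri > 0) Delta_Ri))
    net <- capture_network(Delta1, lambda, Delta_Ri, N0 = N0)
    tr <- integrate_network(net, ts)
    # Eq for un-burned target atoms
    expect_rel(remaining_atoms(N0, Delta1, ts), tr[, "S"], 1e-8)
    # product atoms and activity
    na <- product_atoms(N0, om, sys$field, consts, ts)
    expect_rel(na, tr[, "R"], 1e-8)
    expect_equal(product_activity(N0, om, sys$field, consts, ts),
                 lambda * na)
    # conservation: burned target atoms always exceed surviving product
    expect_true(all(burned_atoms(N0, Delta1, ts) >= na * (1 - 1e-12)))
  }
})

test_that("cooling applies a pure decay factor", {
  sys <- toy_direct_system(1e-6, 3e-6)
  consts <- depletion_constants(1e-6, 3e-6)
  N0 <- initial_atoms(sys$target)[[1]]
  om <- omega(sys$channels$prod, sys$field)
  a0 <- product_activity(N0, om, sys$field, consts, 1e5)
  ac <- product_activity(N0, om, sys$field, consts, 1e5, t_c = 4e5)
  expect_equal(ac, a0 * exp(-3e-6 * 4e5))
  expect_equal(product_atoms(N0, om, sys$field, consts, 0), 0)
})

test_that("the degenerate Lambda = Delta case is seamless", {
  d <- 1e-6
  sys <- toy_direct_system(d, d)
  N0 <- initial_atoms(sys$target)[[1]]
  om <- omega(sys$channels$prod, sys$field)
  ts <- c(1e4, 1e6, 5e6)
  exact <- depletion_constants(d, d)
  near <- depletion_constants(d, d * (1 + 1e-9))
  a <- product_atoms(N0, om, sys$field, exact, ts)
  b <- product_atoms(N0, om, sys$field, near, ts)
  expect_rel(a, b, 1e-6)
  # analytic limit rate * t * exp(-d t)
  rate <- sys$field$phi_th * barns_to_cm2(om) * N0
  expect_rel(a, rate * ts * exp(-d * ts), 1e-10)
  expect_equal(time_of_max_yield(exact), 1 / d)
})

test_that("classic activation limit: Delta_S -> 0 gives saturation", {
  lambda <- 1e-5
  sys <- toy_direct_system(1e-15, lambda)   # burn-up vanishes
  consts <- depletion_constants(1e-15, lambda)
  N0 <- initial_atoms(sys$target)[[1]]
  om <- omega(sys$channels$prod, sys$field)
  ts <- c(1e4, 1e5, 1e6)
  expect_rel(product_atoms(N0, om, sys$field, consts, ts),
             sys$field$phi_th * barns_to_cm2(om) * N0 / lambda *
               (1 - exp(-lambda * ts)), 1e-6)
  # at exactly Delta_S = 0 the peak escapes to infinity and the
  # saturation activity is reported instead
  consts0 <- depletion_constants(0, lambda)
  my <- max_yield(consts0, N0, om, sys$field)
  expect_true(my$saturation)
  expect_equal(my$t_max, Inf)
  expect_equal(my$activity_Bq,
               sys$field$phi_th * barns_to_cm2(om) * N0)
})

test_that("time_of_max_yield agrees with brute-force maximization", {
  set.seed(7)
  for (k in 1:20) {
    r <- rand_rates(2, 1e-8, 1e-4)
    consts <- depletion_constants(r[1], r[2])
    sys <- toy_direct_system(r[1], r[2])
    N0 <- initial_atoms(sys$target)[[1]]
    om <- omega(sys$channels$prod, sys$field)
    t_star <- time_of_max_yield(consts)
    expect_equal(t_star, log(r[2] / r[1]) / (r[2] - r[1]), tolerance = 1e-12)
    o <- stats::optimize(function(t)
      product_activity(N0, om, sys$field, consts, t),
      c(t_star / 50, t_star * 50), maximum = TRUE,
      tol = 1e-8 * t_star)
    expect_equal(o$maximum, t_star, tolerance = 1e-4)
    # maximality on the curve
    a_star <- product_activity(N0, om, sys$field, consts, t_star)
    expect_gte(a_star,
               product_activity(N0, om, sys$field, consts, t_star * 1.1))
    expect_gte(a_star,
               product_activity(N0, om, sys$field, consts, t_star * 0.9))
  }
  # Lambda = 2, Delta = 1 -> ln 2; the removable D = 1 point -> 1/Lambda
  expect_equal(time_of_max_yield(depletion_constants(1, 2)), log(2),
               tolerance = 1e-9)
  expect_equal(time_of_max_yield(depletion_constants(1, 1)), 1)
})

test_that("max_yield: direct and auxiliary (D, p, h, q) paths agree", {
  set.seed(11)
  for (k in 1:25) {
    r <- rand_rates(2)
    consts <- depletion_constants(r[1], r[2])
    sys <- toy_direct_system(r[1], r[2])
    N0 <- initial_atoms(sys$target)[[1]]
    om <- omega(sys$channels$prod, sys$field)
    a <- max_yield(consts, N0, om, sys$field, method = "direct")
    b <- max_yield(consts, N0, om, sys$field, method = "auxiliary")
    expect_rel(a$atoms, b$atoms, 1e-9)
    expect_rel(a$activity_Bq, b$activity_Bq, 1e-9)
  }
})

test_that("auxiliaries of the depletion bundle satisfy their identities", {
  cs <- depletion_constants(2e-6, 3e-6, 1e-6)
  expect_equal(cs$Lambda_Ri, 4e-6)
  expect_equal(cs$D, 2)
  expect_equal(cs$f, 0.75)
  expect_equal(cs$p, log(2))
  expect_equal(cs$h, 2 * log(2))
  expect_equal(cs$q, -1)
  expect_gte(cs$Lambda_Ri, cs$lambda_total)
})

test_that("product yield is non-negative and unimodal under burn-up", {
  sys <- toy_direct_system(2e-6, 1e-6)
  consts <- depletion_constants(2e-6, 1e-6)
  N0 <- initial_atoms(sys$target)[[1]]
  om <- omega(sys$channels$prod, sys$field)
  ts <- seq(0, 2e7, length.out = 400)
  y <- product_atoms(N0, om, sys$field, consts, ts)
  expect_true(all(y >= 0))
  d <- diff(y)
  # rises then falls: exactly one sign change in the difference sequence
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
})

test_that("activation_series is continuous across the EOB boundary", {
  lu <- load_fixture("lu176_enriched")
  f <- neutron_field(2.5e14, R_epi = 0.02)
  ts <- seq(0, 10 * 86400, length.out = 11)
  ser <- activation_series(lu$target, lu$channels, f, ts,
                           production = "Lu-1",
                           cooling_times = c(0, 86400))
  irr_end <- ser[ser$phase == "irradiation" & ser$isotope == "Lu-177" &
                   ser$time_s == max(ts), ]
  cool0 <- ser[ser$phase == "cooling" & ser$time_s == max(ts), ]
  expect_equal(irr_end$atoms, cool0$atoms)
  expect_true(all(ser$atoms >= 0))
  expect_setequal(unique(ser$isotope), c("Lu-176", "Lu-175", "Lu-177"))
})
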