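# Builders for randomized toy systems used by the oracle-equivalence and
# property tests.  All fixtures are constructed in code; no files.

expect_rel <- function(actual, expected, tol, info = NULL) {
  s <- pmax(abs(actual), abs(expected))
  d <- abs(actual - expected)
  expect_true(all(d <= tol * pmax(s, .Machine$double.xmin)), info = info)
}

# log-uniform rate draws, 1/s
rand_rates <- function(n, lo = 1e-9, hi = 1e-3) {
  10^stats::runif(n, log10(lo), log10(hi))
}

# times probing the dynamic range of a system with the given rates
rand_times <- function(rates, n = 5) {
  gm <- exp(mean(log(rates)))
  10^stats::runif(n, -2, 1) / gm
}

# a two-isotope toy target + single production channel realizing the given
# burn-up constant Delta1 (via sigma0) and product decay constant lambda,
# in a pure-thermal field of flux phi.
toy_direct_system <- function(Delta1, lambda, phi = 1e14,
                              P1 = 70, M1 = 176, M2 = 175, mass = 1e-3) {
  sigma0 <- Delta1 / (phi * 1e-24)
  parent <- isotope("S1-176", M1, weight_percent = P1)
  imp <- isotope("S2-175", M2, weight_percent = 100 - P1)
  prod <- isotope("R-177", 177, half_life = log(2) / lambda)
  list(
    target = target_spec(mass, "S", list(parent, imp)),
    channels = list(prod = reaction_channel(parent, prod, sigma0,
                                            label = "prod")),
    field = neutron_field(phi)
  )
}

# chain toy system: parent capture (Delta_S via sigma0) -> intermediate
# (lambda_x) -> product (lambda_i)
toy_chain_system <- function(Delta_S, lambda_x, lambda_i, phi = 1e14,
                             Delta_int = 0, Delta_prod = 0) {
  sigma0 <- Delta_S / (phi * 1e-24)
  parent <- isotope("S-176", 176, weight_percent = 100)
  interm <- isotope("X-177", 177, half_life = log(2) / lambda_x)
  prod <- isotope("R-177", 177, half_life = log(2) / lambda_i)
  ch <- reaction_channel(parent, interm, sigma0, label = "cap")
  field <- neutron_field(phi)
  chain_system(ch, prod, field, Delta_int = Delta_int,
               Delta_prod = Delta_prod)
}

# oracle for irradiation followed by cooling: integrate the network to
# t_irr, switch off capture (zero the capture edges), continue for t_c.
oracle_irradiate_then_cool <- function(net, net_cool, t_irr, t_c) {
  eob <- integrate_network(net, t_irr)[1, ]
  cool <- linear_network(net_cool$states, net_cool$rate_matrix, eob)
  integrate_network(cool, t_c)[1, ]
}
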