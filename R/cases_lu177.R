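## Pre-wired Lu-177 production scenarios: the direct Lu-176(n,gamma) route,
## a flux/enrichment scan of its yield- and SA-optimal irradiation times,
## and the indirect Yb-176(n,gamma)Yb-177 -> beta -> Lu-177 route with
## carrier in-growth and elemental-Lu impurity dilution.

## Lu target at arbitrary enrichment, channel set from the bundled fixture.
.lu_target <- function(enrichment, mass = 1e-3) {
  if (enrichment <= 0 || enrichment > 100)
    stop("enrichment must lie in (0, 100]")
  fx <- load_fixture("lu176_enriched")
  isos <- if (enrichment == 100) {
    list(isotope("Lu-176", 176, weight_percent = 100))
  } else {
    list(isotope("Lu-176", 176, weight_percent = enrichment),
         isotope("Lu-175", 175, weight_percent = 100 - enrichment))
  }
  list(target = target_spec(mass, "Lu", isos), channels = fx$channels)
}

#' Direct-route Lu-177 production scenario
#'
#' Lu-176(n,gamma)Lu-177 in an enriched Lu target: parent depletion,
#' product build-up, SA versus irradiation time, and the yield- and
#' SA-optimal irradiation times.  The Lu-176 capture is non-1/v and uses
#' the Westcott k-factor 1.74; the Lu-175 impurity pool does not deplete
#' (its captures keep the atoms inside the element).
#'
#' @param enrichment Lu-176 weight percent in (0, 100].
#' @param phi_th thermal flux, n cm^-2 s^-1.
#' @param t_grid irradiation time grid, s (default 201 points over 40 d).
#' @param R_epi epithermal-to-thermal flux ratio.
#' @param t_c cooling time applied to the reported series, s.
#' @param mass target mass (element basis), g.
#' @return object of class `scenario_result`: `series` (data.frame with
#'   time_s, n_S1, n_S2, n_Ri, a_Ri_Bq, sa_atom_percent), `t_yield_max`,
#'   `t_sa_max` (NA when no interior maximum), `ratio`, `sa_max`.
#' @export
direct_route <- function(enrichment = 74.1, phi_th = 2.5e14, t_grid = NULL,
                         R_epi = 0.02, t_c = 0, mass = 1e-3) {
  lu <- .lu_target(enrichment, mass)
  field <- neutron_field(phi_th, R_epi = R_epi)
  if (is.null(t_grid)) t_grid <- seq(0, 40 * 86400, length.out = 201)

  s <- .sa_setup(lu$target, lu$channels, field, production = "Lu-1")
  N0 <- s$N0
  n_s1 <- remaining_atoms(N0[[1]], s$dS1, t_grid)
  n_s2 <- if (length(N0) > 1)
    remaining_atoms(N0[[2]], s$d_imp[[1]], t_grid) else rep(0, length(t_grid))
  n_ri <- product_atoms(N0[[1]], s$om_prod, field, s$consts, t_grid, t_c)
  sa <- sa_general(lu$target, lu$channels, field, t_grid, t_c,
                   production = "Lu-1")
  t_y <- time_of_max_yield(s$consts)
  t_sa <- time_of_max_sa(lu$target, lu$channels, field, production = "Lu-1")
  sa_max <- if (is.finite(t_sa))
    sa_general(lu$target, lu$channels, field, t_sa, 0, production = "Lu-1")
  else NA_real_
  structure(list(
    series = data.frame(time_s = t_grid, n_S1 = n_s1, n_S2 = n_s2,
                        n_Ri = n_ri, a_Ri_Bq = s$consts$lambda_total * n_ri,
                        sa_atom_percent = sa),
    enrichment = enrichment, phi_th = phi_th,
    t_yield_max = t_y, t_sa_max = t_sa,
    ratio = if (is.finite(t_sa)) t_sa / t_y else NA_real_,
    sa_max = sa_max,
    constants = s$consts
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  if (!is.null(x$enrichment))
    cat(sprintf("  target: %.4g%% Lu-176, phi_th = %.3g n/cm2/s\n",
                x$enrichment, x$phi_th))
  if (!is.null(x$sources) && length(x$sources)) {
    n <- nrow(x$series)
    cat(sprintf("  indirect route: phi_th = %.3g, t_c = %.3g s\n",
                x$phi_th, x$t_c))
    cat(sprintf("  at t_irr = %.4g s: A = %.4g Bq, SA_mix = %.4g atom%%\n",
                x$series$t_irr_s[n], x$series$a_total_Bq[n],
                x$series$sa_mix_atom_percent[n]))
    return(invisible(x))
  }
  cat(sprintf("  t_yield_max = %.4g s (%.3g d)\n",
              x$t_yield_max, x$t_yield_max / 86400))
  if (is.finite(x$t_sa_max)) {
    cat(sprintf("  t_sa_max    = %.4g s (%.3g d), ratio = %.4g\n",
                x$t_sa_max, x$t_sa_max / 86400, x$ratio))
    cat(sprintf("  SA at t_sa_max = %.4g atom%%\n", x$sa_max))
  } else {
    cat("  t_sa_max    = none (SA increases monotonically)\n")
  }
  invisible(x)
}

#' Flux/enrichment scan of the direct route
#'
#' For each (enrichment, flux) cell: the yield-optimal and SA-optimal
#' irradiation times, their ratio, and the maximum SA.  The ratio peaks at
#' an intermediate flux (about 3e14 n cm^-2 s^-1 for the Lu system) where
#' burn-up and product depression rates interact most strongly.
#'
#' @param enrichments Lu-176 weight percents.
#' @param phi_grid thermal flux grid; default 12 log-spaced points in
#'   \[5e13, 1e15\].
#' @param R_epi epithermal-to-thermal flux ratio.
#' @return data.frame with columns enrichment, phi_th, t_yield_max_s,
#'   t_sa_max_s, ratio, sa_max_atom_percent; attribute `argmax` holds the
#'   ratio-maximizing flux per enrichment.
#' @export
flux_scan <- function(enrichments = c(60, 74.1, 90, 99.9),
                      phi_grid = 10^seq(log10(5e13), 15, length.out = 12),
                      R_epi = 0.02) {
  if (length(enrichments) == 0 || length(phi_grid) == 0)
    stop("enrichment and flux grids must be non-empty")
  rows <- expand.grid(enrichment = enrichments, phi_th = phi_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    lu <- .lu_target(rows$enrichment[i])
    field <- neutron_field(rows$phi_th[i], R_epi = R_epi)
    s <- .sa_setup(lu$target, lu$channels, field, production = "Lu-1")
    t_y <- time_of_max_yield(s$consts)
    t_sa <- time_of_max_sa(lu$target, lu$channels, field,
                           production = "Lu-1")
    sa_max <- if (is.finite(t_sa))
      sa_general(lu$target, lu$channels, field, t_sa, 0, production = "Lu-1")
    else NA_real_
    c(t_yield_max_s = t_y, t_sa_max_s = t_sa,
      ratio = if (is.finite(t_sa)) t_sa / t_y else NA_real_,
      sa_max_atom_percent = sa_max)
  })
  out <- cbind(rows, do.call(rbind, res))
  argmax <- vapply(enrichments, function(e) {
    sub <- out[out$enrichment == e & is.finite(out$ratio), ]
    if (nrow(sub) == 0) return(NA_real_)
    sub$phi_th[which.max(sub$ratio)]
  }, numeric(1))
  attr(out, "argmax") <- stats::setNames(argmax, enrichments)
  out
}

#' Indirect-route Lu-177 production scenario
#'
#' Yb-176(n,gamma)Yb-177 -> beta -> Lu-177 in an enriched Yb target.  Two
#' radioactive sources share the product element: S1, the carrier-free
#' chain product diluted only by Lu-175 grown in from the Yb-174 impurity
#' (via Yb-175, 4.2 d), and S2, Lu-177 activated directly on the natural-
#' abundance elemental Lu impurity.  The reported SA is their
#' isotopic-dilution mixture; total activity is A1 + A2.
#'
#' @param phi_th thermal flux, n cm^-2 s^-1.
#' @param t_irr irradiation time grid, s (default 121 points over 600 h).
#' @param t_c cooling time, s; default 24 h, which lets essentially all
#'   Yb-177 (1.911 h) convert to Lu-177 before the product is reported.
#' @param target a `target_spec` from the Yb fixture (or a modified copy).
#' @param channels channel list matching `target`.
#' @param lu_ppm elemental Lu impurity, ppm of the Yb element mass; default
#'   taken from the target's impurity table.
#' @param R_epi epithermal-to-thermal flux ratio.
#' @return object of class `scenario_result` with the SA/activity series
#'   of both sources and of the mixture, and the final-time
#'   [radioactive_source()] pair.
#' @export
indirect_route <- function(phi_th = 5e13, t_irr = NULL, t_c = 86400,
                           target = NULL, channels = NULL, lu_ppm = NULL,
                           R_epi = 0.02) {
  if (is.null(target) || is.null(channels)) {
    fx <- load_fixture("yb176_enriched")
    if (is.null(target)) target <- fx$target
    if (is.null(channels)) channels <- fx$channels
  }
  if (is.null(t_irr)) t_irr <- seq(0, 600 * 3600, length.out = 121)
  field <- neutron_field(phi_th, R_epi = R_epi)
  if (is.null(lu_ppm)) {
    lu_imp <- Filter(function(i) identical(i$element, "Lu"),
                     target$impurities)
    lu_ppm <- if (length(lu_imp)) lu_imp[[1]]$ppm else 0
  }
  N0 <- initial_atoms(target)
  lam_lu177 <- decay_constant("6.71d")

  ## --- source S1: chain product + Lu-175 in-growth from Yb-174 ----------
  sys1 <- chain_system(channels[["Yb-1"]], isotope("Lu-177", 177, "6.71d"),
                       field)
  n1_177 <- chain_product_atoms(sys1, N0[["Yb-176"]], t_irr, t_c)
  a1 <- sys1$lambda_i * n1_177
  n1_175 <- if ("Yb-174" %in% names(N0) && N0[["Yb-174"]] > 0) {
    stable_ingrowth(channels[["Yb-2"]], field, N0[["Yb-174"]], t_irr, t_c)
  } else rep(0, length(t_irr))
  sa1 <- ifelse(n1_177 + n1_175 == 0, NA_real_,
                100 * n1_177 / (n1_177 + n1_175))

  ## --- source S2: direct activation of the elemental Lu impurity --------
  if (lu_ppm > 0) {
    lu_fx <- load_fixture("lu_natural")
    m_lu <- lu_ppm * 1e-6 * target$mass
    lu_target <- target_spec(m_lu, "Lu", lu_fx$target$isotopes)
    s2 <- .sa_setup(lu_target, lu_fx$channels, field, production = "Lu-1")
    n2_177 <- product_atoms(s2$N0[[1]], s2$om_prod, field, s2$consts,
                            t_irr, t_c)
    a2 <- s2$consts$lambda_total * n2_177
    sa2 <- sa_general(lu_target, lu_fx$channels, field, t_irr, t_c,
                      production = "Lu-1")
  } else {
    n2_177 <- a2 <- rep(0, length(t_irr))
    sa2 <- rep(NA_real_, length(t_irr))
  }

  ## --- mixture (isotopic dilution) --------------------------------------
  sa_mix <- ifelse(
    a1 + a2 == 0, NA_real_,
    ifelse(a2 == 0, sa1,
           ifelse(a1 == 0, sa2, (a1 + a2) / (a1 / sa1 + a2 / sa2))))

  i_end <- length(t_irr)
  sources <- list()
  if (a1[i_end] > 0)
    sources$S1 <- radioactive_source("S1-chain", a1[i_end], sa1[i_end])
  if (a2[i_end] > 0)
    sources$S2 <- radioactive_source("S2-Lu-impurity", a2[i_end], sa2[i_end])
  structure(list(
    series = data.frame(t_irr_s = t_irr, t_c_s = t_c,
                        n1_Lu177 = n1_177, n1_Lu175 = n1_175,
                        a1_Bq = a1, sa1_atom_percent = sa1,
                        n2_Lu177 = n2_177, a2_Bq = a2,
                        sa2_atom_percent = sa2,
                        a_total_Bq = a1 + a2,
                        sa_mix_atom_percent = sa_mix),
    phi_th = phi_th, t_c = t_c, lu_ppm = lu_ppm,
    t_yield_max = NA_real_, t_sa_max = NA_real_,
    sources = sources
  ), class = "scenario_result")
}
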