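## Simple-target activation: isotope burn-up, product yield, maximum-yield
## time, and post-irradiation decay.  All internal rates in 1/s, with
## cross-sections converted to cm^2 at the module boundary.

#' Total burn-up (depletion) constant of a target isotope
#'
#' Delta_S = phi_th * sum_i Omega_i over every reaction channel that
#' consumes the isotope, Omega in cm^2.
#'
#' @param channels list of [reaction_channel()], all sharing one parent.
#' @param field a [neutron_field()].
#' @return Delta_S in 1/s.
#' @export
depletion_constant <- function(channels, field) {
  if (inherits(channels, "reaction_channel")) channels <- list(channels)
  if (length(channels) == 0) stop("at least one reaction channel required")
  parents <- vapply(channels, function(ch) ch$parent$symbol, character(1))
  if (length(unique(parents)) != 1L)
    stop("all channels must share the same parent isotope")
  om <- vapply(channels, omega, numeric(1), field = field)
  field$phi_th * sum(barns_to_cm2(om))
}

#' Depletion constants bundle for one product
#'
#' Collects the rate constants governing one production reaction: the
#' target burn-up constant `Delta_S`, the product's total decay constant
#' `lambda_total`, its neutron-destruction constant `Delta_Ri` (zero when
#' product burn-up is negligible against its decay) and the resulting
#' depression factor `Lambda_Ri = lambda_total + Delta_Ri`.  The
#' dimensionless auxiliaries of the maximum-yield formulas are included:
#' D = Lambda/Delta, f = lambda/Lambda, p = ln D/(D-1), h = D p,
#' q = 1/(1-D).
#'
#' @param Delta_S target burn-up constant, 1/s (> 0).
#' @param lambda_total product total decay constant, 1/s.
#' @param Delta_Ri product destruction constant, 1/s (default 0).
#' @return object of class `depletion_constants`.
#' @export
depletion_constants <- function(Delta_S, lambda_total, Delta_Ri = 0) {
  if (Delta_S < 0 || lambda_total < 0 || Delta_Ri < 0)
    stop("rate constants must be non-negative")
  Lambda <- lambda_total + Delta_Ri
  D <- if (Delta_S > 0) Lambda / Delta_S else Inf
  near1 <- is.finite(D) && abs(D - 1) < 1e-10
  p <- if (!is.finite(D)) NA_real_ else if (near1) 1 else log(D) / (D - 1)
  structure(list(
    Delta_S = Delta_S, Delta_Ri = Delta_Ri,
    lambda_total = lambda_total, Lambda_Ri = Lambda,
    D = D, f = if (Lambda > 0) lambda_total / Lambda else NA_real_,
    p = p, h = if (is.na(p)) NA_real_ else D * p,
    q = if (near1 || !is.finite(D)) NA_real_ else 1 / (1 - D)
  ), class = "depletion_constants")
}

#' Un-burned target atoms after irradiation
#'
#' N(t) = N0 exp(-Delta_S t).
#'
#' @param N0 initial atoms.
#' @param delta_S burn-up constant, 1/s.
#' @param t irradiation time(s), s (>= 0).
#' @return remaining atoms.
#' @export
remaining_atoms <- function(N0, delta_S, t) {
  if (any(t < 0)) stop("irradiation time must be non-negative")
  if (any(N0 < 0)) stop("N0 must be non-negative")
  N0 * exp(-delta_S * t)
}

#' Burned-up target atoms
#'
#' @inheritParams remaining_atoms
#' @return N0 - N(t).
#' @export
burned_atoms <- function(N0, delta_S, t) {
  if (any(t < 0)) stop("irradiation time must be non-negative")
  N0 * -expm1(-delta_S * t)
}

#' Half-burn-up time of a target isotope
#'
#' Time at which half of the initial target atoms have been destroyed:
#' ln 2 / Delta_S.
#'
#' @param delta_S burn-up constant, 1/s (> 0).
#' @return seconds.
#' @export
half_burnup_time <- function(delta_S) {
  if (any(delta_S <= 0)) stop("delta_S must be positive")
  log(2) / delta_S
}

#' Product atoms from a single-capture reaction
#'
#' N_Ri(t) = phi Omega N0 / (Lambda - Delta_S) * (exp(-Delta_S t) -
#' exp(-Lambda t)), evaluated through a cancellation-free divided-difference
#' kernel so the removable Lambda = Delta_S singularity needs no special
#' casing by the caller.  Cooling multiplies by exp(-lambda_total t_c).
#'
#' @param N0 initial parent atoms.
#' @param omega_prod production-channel Omega, barns.
#' @param field a [neutron_field()].
#' @param consts a [depletion_constants()] bundle.
#' @param t_irr irradiation time(s), s.
#' @param t_c post-irradiation cooling time, s (default 0).
#' @return product atoms (vectorized over `t_irr`).
#' @export
product_atoms <- function(N0, omega_prod, field, consts, t_irr, t_c = 0) {
  stopifnot(inherits(consts, "depletion_constants"))
  if (any(t_irr < 0) || any(t_c < 0)) stop("times must be non-negative")
  rate <- field$phi_th * barns_to_cm2(omega_prod) * N0
  rate * .bateman2(consts$Delta_S, consts$Lambda_Ri, t_irr) *
    exp(-consts$lambda_total * t_c)
}

#' Product activity from a single-capture reaction
#'
#' A = lambda_total * N_Ri.
#'
#' @inheritParams product_atoms
#' @return activity in Bq.
#' @export
product_activity <- function(N0, omega_prod, field, consts, t_irr, t_c = 0) {
  consts$lambda_total *
    product_atoms(N0, omega_prod, field, consts, t_irr, t_c)
}

#' Irradiation time of maximum product yield
#'
#' t* = ln(Lambda/Delta_S) / (Lambda - Delta_S); the removable D = 1
#' degeneracy returns 1/Lambda.  For Delta_S -> 0 the activity saturates
#' instead of peaking and the function returns `Inf`.
#'
#' @param consts a [depletion_constants()] bundle.
#' @return seconds.
#' @export
time_of_max_yield <- function(consts) {
  stopifnot(inherits(consts, "depletion_constants"))
  if (consts$Lambda_Ri <= 0) stop("Lambda_Ri must be positive")
  if (consts$Delta_S <= 0) return(Inf)
  if (abs(consts$D - 1) < 1e-10) return(1 / consts$Lambda_Ri)
  log(consts$Lambda_Ri / consts$Delta_S) /
    (consts$Lambda_Ri - consts$Delta_S)
}

#' Maximum product yield
#'
#' Atoms and activity at the maximum-yield time.  Two algebraically
#' equivalent routes exist: direct evaluation of the yield formula at t*,
#' or the auxiliary form through D, p, h (at t* the target and product
#' exponentials collapse to exp(-p) and exp(-h)).  Both are available via
#' `method` and must agree; the tests enforce 1e-9 relative agreement.
#'
#' @inheritParams product_atoms
#' @param method "direct" or "auxiliary".
#' @return list with `t_max` (s), `atoms`, `activity_Bq`.
#' @export
max_yield <- function(consts, N0, omega_prod, field,
                      method = c("direct", "auxiliary")) {
  method <- match.arg(method)
  t_max <- time_of_max_yield(consts)
  if (!is.finite(t_max)) {
    ## Delta_S -> 0: classic saturation, report the asymptotic activity.
    sat <- field$phi_th * barns_to_cm2(omega_prod) * N0 / consts$Lambda_Ri
    return(list(t_max = Inf, atoms = sat,
                activity_Bq = consts$lambda_total * sat, saturation = TRUE))
  }
  atoms <- if (method == "direct") {
    product_atoms(N0, omega_prod, field, consts, t_max)
  } else {
    rate <- field$phi_th * barns_to_cm2(omega_prod) * N0
    if (abs(consts$D - 1) < 1e-10) {
      rate * t_max * exp(-consts$Delta_S * t_max)
    } else {
      ## 1/(Lambda - Delta) = -q/Delta_S with q = 1/(1-D)
      rate * (-consts$q / consts$Delta_S) *
        (exp(-consts$p) - exp(-consts$h))
    }
  }
  list(t_max = t_max, atoms = atoms,
       activity_Bq = consts$lambda_total * atoms, saturation = FALSE)
}

#' Activation time series for a simple target
#'
#' Tabulates un-burned parent isotopes, product atoms and product activity
#' over an irradiation grid, then (optionally) a cooling grid.  Atom
#' numbers are continuous across the end-of-bombardment boundary.
#'
#' @param target a [target_spec()]; isotope 1 is the production parent.
#' @param channels named list of [reaction_channel()] for this target.
#' @param field a [neutron_field()].
#' @param times irradiation time grid, s.
#' @param production index or label of the production channel (default 1).
#' @param cooling_times optional cooling grid, s (measured from EOB at
#'   `max(times)`).
#' @param Delta_Ri product destruction constant, 1/s.
#' @return data.frame with columns time_s, phase, isotope, atoms,
#'   activity_Bq.
#' @export
activation_series <- function(target, channels, field, times,
                              production = 1, cooling_times = NULL,
                              Delta_Ri = 0) {
  prod_ch <- channels[[production]]
  parent <- target$isotopes[[1]]
  if (!identical(prod_ch$parent$symbol, parent$symbol))
    stop("production channel parent must be the first target isotope")
  N0 <- initial_atoms(target)
  dS1 <- depletion_constant(.channels_of(channels, parent$symbol), field)
  consts <- depletion_constants(dS1, prod_ch$product$lambda_total, Delta_Ri)

  rows <- list()
  for (k in seq_along(target$isotopes)) {
    iso <- target$isotopes[[k]]
    dk <- if (k == 1) dS1 else .elemental_depletion(channels, iso, field)
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = times, phase = "irradiation", isotope = iso$symbol,
      atoms = remaining_atoms(N0[[k]], dk, times), activity_Bq = 0)
  }
  np <- product_atoms(N0[[1]], omega(prod_ch, field), field, consts, times)
  rows[[length(rows) + 1L]] <- data.frame(
    time_s = times, phase = "irradiation", isotope = prod_ch$product$symbol,
    atoms = np, activity_Bq = consts$lambda_total * np)
  if (!is.null(cooling_times)) {
    eob <- max(times)
    n_eob <- product_atoms(N0[[1]], omega(prod_ch, field), field, consts, eob)
    nc <- n_eob * exp(-consts$lambda_total * cooling_times)
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = eob + cooling_times, phase = "cooling",
      isotope = prod_ch$product$symbol,
      atoms = nc, activity_Bq = consts$lambda_total * nc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## channels consuming a given parent isotope
.channels_of <- function(channels, parent_symbol) {
  Filter(function(ch) identical(ch$parent$symbol, parent_symbol), channels)
}

## elemental depletion constant of an impurity isotope: only channels that
## remove atoms from the element count (same-element products keep the
## elemental pool intact).
.elemental_depletion <- function(channels, iso, field) {
  chs <- Filter(function(ch) ch$elemental_loss,
                .channels_of(channels, iso$symbol))
  if (length(chs) == 0) return(0)
  depletion_constant(chs, field)
}
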