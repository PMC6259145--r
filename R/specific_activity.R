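## Specific radioactivity (SA): definitions, unit conversions, closed-form
## SA of one-, two- and multi-isotope targets, and maximum-SA time solving.
##
## SA in "atom %" is 100 * (hot atoms of the radioisotope) / (atoms of its
## chemical element).  A carrier-free radioisotope therefore has SA = 100.

#' SA in atom percent
#'
#' @param hot_atoms atoms of the radioisotope.
#' @param element_atoms total atoms of its chemical element (including the
#'   hot atoms themselves).
#' @return SA in atom percent.
#' @export
sa_atom_percent <- function(hot_atoms, element_atoms) {
  if (any(hot_atoms < 0) || any(element_atoms < 0))
    stop("atom numbers must be non-negative")
  if (any(element_atoms == 0 & hot_atoms > 0) || all(element_atoms == 0))
    stop("SA undefined: element atom number is zero")
  if (any(hot_atoms > element_atoms))
    stop("hot atoms cannot exceed element atoms")
  ifelse(element_atoms == 0, 0, 100 * hot_atoms / element_atoms)
}

#' Specific-activity record with unit conversions
#'
#' Converts between atom percent, Bq/mol and Bq/g:
#' Bq/mol = (atom percent / 100) * lambda * N_Avogadro, Bq/g = Bq/mol / M.
#'
#' @param atom_percent SA in atom percent.
#' @param atomic_weight atomic weight M of the material of given isotopic
#'   composition, g/mol.
#' @param lambda_total total decay constant of the radioisotope, 1/s.
#' @param replication use the rounded Avogadro constant.
#' @return object of class `specific_activity` with fields `atom_percent`,
#'   `bq_per_mol`, `bq_per_g`.
#' @export
specific_activity <- function(atom_percent, atomic_weight, lambda_total,
                              replication = FALSE) {
  if (any(atom_percent < 0) || any(atom_percent > 100))
    stop("atom percent must lie in [0, 100]")
  if (atomic_weight <= 0) stop("atomic weight must be positive")
  if (lambda_total <= 0)
    stop("a finite decay constant is required (stable reference has no SA)")
  bq_mol <- atom_percent / 100 * lambda_total * avogadro(replication)
  structure(list(atom_percent = atom_percent,
                 bq_per_mol = bq_mol,
                 bq_per_g = bq_mol / atomic_weight,
                 atomic_weight = atomic_weight,
                 lambda_total = lambda_total),
            class = "specific_activity")
}

#' @export
print.specific_activity <- function(x, ...) {
  cat(sprintf("<specific_activity> %.6g atom%%  = %.6g Bq/mol = %.6g Bq/g\n",
              x$atom_percent[1], x$bq_per_mol[1], x$bq_per_g[1]))
  if (length(x$atom_percent) > 1)
    cat(sprintf("  (... %d values)\n", length(x$atom_percent)))
  invisible(x)
}

#' Convert an SA value between units
#'
#' @param value numeric SA value.
#' @param from unit of `value`: "atom_percent", "bq_per_mol" or "bq_per_g".
#' @inheritParams specific_activity
#' @return a [specific_activity()] object (all units populated).
#' @export
convert_sa <- function(value, from = c("atom_percent", "bq_per_mol",
                                       "bq_per_g"),
                       atomic_weight, lambda_total, replication = FALSE) {
  from <- match.arg(from)
  if (lambda_total <= 0)
    stop("a finite decay constant is required (stable reference has no SA)")
  nav <- avogadro(replication)
  ap <- switch(from,
    atom_percent = value,
    bq_per_mol = 100 * value / (lambda_total * nav),
    bq_per_g = 100 * value * atomic_weight / (lambda_total * nav))
  specific_activity(ap, atomic_weight, lambda_total, replication)
}

#' Atomic weight of a multi-isotope material
#'
#' Weight-percent harmonic combination: M = sum(P) / sum(P / M_i).
#'
#' @param percents weight percents (need not sum to 100).
#' @param masses isotope atomic weights, g/mol.
#' @return g/mol.
#' @export
material_atomic_weight <- function(percents, masses) {
  if (length(percents) != length(masses))
    stop("percents and masses must have equal length")
  if (any(masses <= 0)) stop("atomic weights must be positive")
  if (sum(percents) <= 0) stop("total weight percent must be positive")
  sum(percents) / sum(percents / masses)
}

## ---- target SA closed forms ------------------------------------------------

## Resolve the pieces shared by the SA formulas: initial atoms, burn-up of
## the production parent (all its channels), elemental depletion of each
## impurity isotope, and the production-rate constants.
.sa_setup <- function(target, channels, field, production = 1,
                      Delta_Ri = 0, replication = FALSE) {
  prod_ch <- channels[[production]]
  parent <- target$isotopes[[1]]
  if (!identical(prod_ch$parent$symbol, parent$symbol))
    stop("production channel parent must be the first target isotope")
  N0 <- initial_atoms(target, replication)
  dS1 <- depletion_constant(.channels_of(channels, parent$symbol), field)
  d_imp <- if (length(target$isotopes) > 1) {
    vapply(target$isotopes[-1], .elemental_depletion, numeric(1),
           channels = channels, field = field)
  } else numeric(0)
  list(prod_ch = prod_ch, N0 = N0, dS1 = dS1, d_imp = d_imp,
       consts = depletion_constants(dS1, prod_ch$product$lambda_total,
                                    Delta_Ri),
       om_prod = omega(prod_ch, field))
}

#' SA of the product in a simple multi-isotope target
#'
#' SA(t) = 100 N_Ri / (sum_g N_Sg(t) + N_Ri), where the production parent
#' depletes with its full burn-up constant and each impurity isotope with
#' its elemental depletion constant (zero when its reactions keep the atoms
#' inside the element).  Cooling decays the hot atoms only; the stable
#' pools are unchanged.
#'
#' @param target a [target_spec()]; isotope 1 is the production parent.
#' @param channels named list of [reaction_channel()].
#' @param field a [neutron_field()].
#' @param t_irr irradiation time(s), s.
#' @param t_c cooling time, s.
#' @param production production channel index or label.
#' @param Delta_Ri product destruction constant, 1/s.
#' @param replication use the rounded Avogadro constant (cancels here).
#' @return SA in atom percent, vectorized over `t_irr`.
#' @export
sa_general <- function(target, channels, field, t_irr, t_c = 0,
                       production = 1, Delta_Ri = 0, replication = FALSE) {
  s <- .sa_setup(target, channels, field, production, Delta_Ri, replication)
  n_ri <- product_atoms(s$N0[[1]], s$om_prod, field, s$consts, t_irr, t_c)
  den <- remaining_atoms(s$N0[[1]], s$dS1, t_irr)
  if (length(s$d_imp))
    for (k in seq_along(s$d_imp))
      den <- den + remaining_atoms(s$N0[[k + 1]], s$d_imp[[k]], t_irr)
  100 * n_ri / (den + n_ri)
}

#' SA of the product in a two-isotope target
#'
#' @inheritParams sa_general
#' @export
sa_two_isotope <- function(target, channels, field, t_irr, t_c = 0,
                           production = 1, Delta_Ri = 0) {
  if (length(target$isotopes) != 2L)
    stop("target must have exactly two stable isotopes; ",
         "reduce a multi-isotope target with multi_as_two() first")
  sa_general(target, channels, field, t_irr, t_c, production, Delta_Ri)
}

#' SA of the product in a one-isotope (isotopically pure) target
#'
#' With no impurity pool the SA rises monotonically and never reaches an
#' interior maximum.
#'
#' @inheritParams sa_general
#' @export
sa_one_isotope <- function(target, channels, field, t_irr, t_c = 0,
                           production = 1, Delta_Ri = 0) {
  if (length(target$isotopes) != 1L)
    stop("target must have exactly one stable isotope")
  sa_general(target, channels, field, t_irr, t_c, production, Delta_Ri)
}

#' Reduce a multi-isotope target to an equivalent two-isotope target
#'
#' All impurity isotopes (which must have zero elemental depletion) are
#' combined into one block with summed weight percent and harmonically
#' combined atomic weight.
#'
#' @param target a [target_spec()] with two or more isotopes.
#' @param channels channel list, used to verify the impurities really are
#'   depletion-free; omit to skip the check.
#' @param field needed with `channels`.
#' @return a two-isotope [target_spec()].
#' @export
multi_as_two <- function(target, channels = NULL, field = NULL) {
  if (length(target$isotopes) <= 2L) return(target)
  imp <- target$isotopes[-1]
  if (!is.null(channels)) {
    d <- vapply(imp, .elemental_depletion, numeric(1),
                channels = channels, field = field)
    if (any(d > 0))
      stop("impurity isotope with non-zero elemental depletion: ",
           paste(vapply(imp[d > 0], `[[`, character(1), "symbol"),
                 collapse = ", "),
           "; use sa_general() instead")
  }
  P <- vapply(imp, `[[`, numeric(1), "weight_percent")
  M <- vapply(imp, `[[`, numeric(1), "atomic_mass")
  block <- isotope(paste0(target$element, "-imp"),
                   material_atomic_weight(P, M),
                   weight_percent = sum(P))
  target_spec(target$mass, target$element,
              list(target$isotopes[[1]], block), target$impurities)
}

#' Irradiation time of maximum SA
#'
#' Solves d(SA)/dt = 0.  SA is a monotone transform of r(t) = N_Ri / sum_g
#' N_Sg, so the sign of the analytic derivative r'(t) is scanned on a
#' log-spaced grid over (0, `horizon_halves` half-burn-up times] and the
#' sign change bracketed with `uniroot` to 1e-6 relative.  Returns `NA`
#' when the target is isotopically pure (P2 = 0) or no interior maximum
#' exists on the horizon.
#'
#' @inheritParams sa_general
#' @param horizon_halves search horizon in units of the target
#'   half-burn-up time.
#' @return time in seconds, or `NA_real_`.
#' @export
time_of_max_sa <- function(target, channels, field, production = 1,
                           Delta_Ri = 0, horizon_halves = 20) {
  s <- .sa_setup(target, channels, field, production, Delta_Ri)
  if (length(s$N0) < 2 || sum(s$N0[-1]) == 0) return(NA_real_)
  rate <- field$phi_th * barns_to_cm2(s$om_prod) * s$N0[[1]]
  Lam <- s$consts$Lambda_Ri
  d_all <- c(s$dS1, s$d_imp)
  num <- function(t) rate * .bateman2(s$dS1, Lam, t)       # N_Ri
  den <- function(t) sum(s$N0 * exp(-d_all * t))
  dden <- function(t) -sum(s$N0 * d_all * exp(-d_all * t))
  sgn <- function(t) {
    n <- num(t)
    (rate * exp(-s$dS1 * t) - Lam * n) * den(t) - n * dden(t)
  }
  t_hi <- horizon_halves * half_burnup_time(s$dS1)
  t_seed <- time_of_max_yield(s$consts)
  if (!is.finite(t_seed)) t_seed <- 1 / Lam
  grid <- exp(seq(log(t_seed * 1e-3), log(t_hi), length.out = 400))
  sg <- vapply(grid, sgn, numeric(1))
  flip <- which(sg[-length(sg)] > 0 & sg[-1] <= 0)
  if (length(flip) == 0) return(NA_real_)
  i <- flip[1]
  r <- stats::uniroot(sgn, lower = grid[i], upper = grid[i + 1],
                      tol = 1e-6 * grid[i + 1])
  r$root
}

#' SA evaluated at the maximum-yield time
#'
#' Either direct evaluation of the SA formula at t* from
#' [time_of_max_yield()], or the auxiliary route in which the exponentials
#' at t* collapse to exp(-p) and exp(-h).  The two must agree to 1e-9
#' relative (enforced in the tests).
#'
#' @inheritParams sa_general
#' @param method "direct" or "auxiliary".
#' @return SA in atom percent.
#' @export
sa_at_max_yield <- function(target, channels, field, production = 1,
                            Delta_Ri = 0,
                            method = c("direct", "auxiliary")) {
  method <- match.arg(method)
  s <- .sa_setup(target, channels, field, production, Delta_Ri)
  t_max <- time_of_max_yield(s$consts)
  if (!is.finite(t_max))
    stop("maximum yield time is infinite (Delta_S = 0); SA has no value there")
  if (method == "direct")
    return(sa_general(target, channels, field, t_max, 0, production,
                      Delta_Ri))
  cs <- s$consts
  rate <- field$phi_th * barns_to_cm2(s$om_prod) * s$N0[[1]]
  n_ri <- if (abs(cs$D - 1) < 1e-10) {
    rate * t_max * exp(-cs$Delta_S * t_max)
  } else {
    rate / (cs$Lambda_Ri - cs$Delta_S) * (exp(-cs$p) - exp(-cs$h))
  }
  den <- s$N0[[1]] * exp(-cs$p)
  if (length(s$d_imp))
    for (k in seq_along(s$d_imp))
      den <- den + s$N0[[k + 1]] * exp(-s$d_imp[[k]] * t_max)
  100 * n_ri / (den + n_ri)
}
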