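## Two-step production S(n,gamma)Rx(beta-)Ri, stable-carrier in-growth from
## an impurity chain, SA with in-growth, and isotopic-dilution mixture SA.

#' Construct a capture-plus-decay chain system
#'
#' Models S (n,gamma) Rx (beta-) Ri: neutron capture on the stable parent
#' feeds a short-lived intermediate whose beta decay yields the product.
#'
#' @param capture_channel [reaction_channel()] from the stable parent to
#'   the intermediate; its product must be the intermediate.
#' @param product `isotope`; the decay daughter of the intermediate.
#' @param field a [neutron_field()].
#' @param Delta_int neutron-destruction constant of the intermediate, 1/s
#'   (default 0: usually unavailable and negligible against its decay).
#' @param Delta_prod neutron-destruction constant of the product, 1/s.
#' @param branch fraction of intermediate decays feeding the product.
#' @return object of class `chain_system`.
#' @export
chain_system <- function(capture_channel, product, field,
                         Delta_int = 0, Delta_prod = 0, branch = 1) {
  stopifnot(inherits(capture_channel, "reaction_channel"),
            inherits(product, "isotope"),
            inherits(field, "neutron_field"))
  intermediate <- capture_channel$product
  if (!is.finite(intermediate$half_life))
    stop("chain intermediate must be radioactive")
  if (branch < 0 || branch > 1) stop("branch fraction must be in [0, 1]")
  structure(list(
    capture_channel = capture_channel,
    parent = capture_channel$parent,
    intermediate = intermediate,
    product = product,
    field = field,
    Delta_S = depletion_constant(capture_channel, field),
    Lambda_x = intermediate$lambda_total + Delta_int,
    lambda_x_feed = intermediate$lambda_total * branch,
    lambda_i = product$lambda_total,
    Lambda_i = product$lambda_total + Delta_prod
  ), class = "chain_system")
}

#' Product atoms of a capture-plus-decay chain
#'
#' Three-exponential Bateman solution in the rates (Delta_S, Lambda_x,
#' Lambda_i), scaled by phi * Omega_capture * N0 * lambda_x.  Repeated-rate
#' degeneracies are absorbed by the confluent divided-difference kernel.
#' Cooling multiplies by exp(-lambda_i t_c); the produced source alone is
#' carrier-free (SA = 100 atom percent).
#'
#' @param system a [chain_system()].
#' @param N0 initial parent atoms.
#' @param t_irr irradiation time(s), s.
#' @param t_c cooling time, s.
#' @return product atoms, vectorized over `t_irr`.
#' @export
chain_product_atoms <- function(system, N0, t_irr, t_c = 0) {
  stopifnot(inherits(system, "chain_system"))
  if (any(t_irr < 0) || any(t_c < 0)) stop("times must be non-negative")
  rate <- system$field$phi_th *
    barns_to_cm2(omega(system$capture_channel, system$field)) * N0
  rate * system$lambda_x_feed *
    .bateman3(system$Delta_S, system$Lambda_x, system$Lambda_i, t_irr) *
    exp(-system$lambda_i * t_c)
}

#' Chain product activity
#'
#' @inheritParams chain_product_atoms
#' @return Bq.
#' @export
chain_product_activity <- function(system, N0, t_irr, t_c = 0) {
  system$lambda_i * chain_product_atoms(system, N0, t_irr, t_c)
}

#' Intermediate radionuclide yield of an impurity channel
#'
#' Atoms and activity of the radionuclide Ry produced by single capture on
#' an impurity isotope (same closed form as the simple-target yield).
#'
#' @param channel capture [reaction_channel()] on the impurity isotope.
#' @param field a [neutron_field()].
#' @param N0 initial impurity atoms.
#' @param t_irr irradiation time(s), s.
#' @param Delta_Ry destruction constant of Ry, 1/s.
#' @return list with `atoms` and `activity_Bq`.
#' @export
intermediate_yield <- function(channel, field, N0, t_irr, Delta_Ry = 0) {
  consts <- depletion_constants(depletion_constant(channel, field),
                                channel$product$lambda_total, Delta_Ry)
  at <- product_atoms(N0, omega(channel, field), field, consts, t_irr)
  list(atoms = at, activity_Bq = consts$lambda_total * at)
}

#' Partial activity of one decay branch
#'
#' @param activity total activity, Bq.
#' @param branch_fraction branch ratio in [0, 1].
#' @return Bq.
#' @export
branch_partial_activity <- function(activity, branch_fraction) {
  if (any(branch_fraction < 0) || any(branch_fraction > 1))
    stop("branch fraction must lie in [0, 1]")
  activity * branch_fraction
}

#' Stable-carrier atoms grown in from an impurity chain
#'
#' The impurity chain S2 (n,gamma) Ry (beta-) Sg deposits stable carrier
#' Sg of the product's element.  During irradiation the in-growth is the
#' time integral of the Ry partial activity (a three-rate kernel with one
#' zero rate, since Sg accumulates); after EOB the remaining Ry atoms keep
#' feeding Sg as exp(-lambda_Ry t_c) with neutron destruction switched off.
#' The result is monotone non-decreasing in both times.
#'
#' @param channel capture channel S2 -> Ry.
#' @param field a [neutron_field()].
#' @param N0 initial impurity atoms.
#' @param t_irr irradiation time, s (scalar or vector).
#' @param t_c cooling time, s.
#' @param branch fraction of Ry decays feeding Sg.
#' @param Delta_Ry destruction constant of Ry during irradiation, 1/s.
#' @return stable carrier atoms.
#' @export
stable_ingrowth <- function(channel, field, N0, t_irr, t_c = 0,
                            branch = 1, Delta_Ry = 0) {
  if (any(t_irr < 0) || any(t_c < 0)) stop("times must be non-negative")
  if (branch < 0 || branch > 1) stop("branch fraction must be in [0, 1]")
  lam_y <- channel$product$lambda_total
  Lambda_y <- lam_y + Delta_Ry
  dS2 <- depletion_constant(channel, field)
  rate <- field$phi_th * barns_to_cm2(omega(channel, field)) * N0
  lam_feed <- lam_y * branch
  ## during irradiation: integral of the Ry feed activity
  n_irr <- rate * lam_feed * .bateman3(dS2, Lambda_y, 0, t_irr)
  if (all(t_c == 0)) return(n_irr)
  ## after EOB: Ry decays freely; its branch share lands in Sg
  consts <- depletion_constants(dS2, lam_y, Delta_Ry)
  n_ry_eob <- product_atoms(N0, omega(channel, field), field, consts, t_irr)
  n_irr + (lam_feed / lam_y) * n_ry_eob * -expm1(-lam_y * t_c)
}

#' SA of a chain product degraded by carrier in-growth
#'
#' SA = 100 N_Ri / (N_Ri + N_Sg): the carrier-free chain product diluted by
#' the stable atoms grown in from the impurity chain.  Strictly decreasing
#' in cooling time, which is why post-irradiation processing should be as
#' short as the chemistry allows.
#'
#' @param system_main [chain_system()] producing Ri.
#' @param impurity_channel capture channel of the carrier-producing chain.
#' @param N0_main,N0_imp initial atoms of the two stable parents.
#' @param t_irr,t_c times, s.
#' @param branch branch fraction of the impurity intermediate into the
#'   carrier.
#' @return SA in atom percent.
#' @export
sa_with_ingrowth <- function(system_main, impurity_channel, N0_main, N0_imp,
                             t_irr, t_c = 0, branch = 1) {
  n_ri <- chain_product_atoms(system_main, N0_main, t_irr, t_c)
  n_sg <- stable_ingrowth(impurity_channel, system_main$field, N0_imp,
                          t_irr, t_c, branch)
  ifelse(n_ri + n_sg == 0, NA_real_, 100 * n_ri / (n_ri + n_sg))
}

#' Construct a radioactive source for mixture-SA accounting
#'
#' @param label text label.
#' @param quantity hot atoms of the radioisotope, or its activity in Bq;
#'   all sources of one mixture must use the same convention (the decay
#'   constant cancels from the mixture SA either way).
#' @param sa SA of the source in atom percent, in (0, 100].
#' @return object of class `radioactive_source`.
#' @export
radioactive_source <- function(label, quantity, sa) {
  if (quantity < 0) stop("source quantity must be non-negative")
  if (sa <= 0 || sa > 100)
    stop("source SA must lie in (0, 100]; fold a stable pool into a ",
         "non-zero-SA source before mixing")
  structure(list(label = label, quantity = quantity, sa = sa),
            class = "radioactive_source")
}

#' SA of a mixture of radioactive sources (isotopic dilution)
#'
#' SA_mix = sum(A_j) / sum(A_j / SA_j): pooled hot atoms over pooled
#' element atoms.  Permutation-invariant, associative under pairwise
#' pooling, and bounded by the smallest and largest source SA.
#'
#' @param sources list of [radioactive_source()].
#' @return mixture SA in atom percent.
#' @export
mixture_sa <- function(sources) {
  if (length(sources) == 0) stop("at least one source required")
  stopifnot(all(vapply(sources, inherits, logical(1), "radioactive_source")))
  q <- vapply(sources, `[[`, numeric(1), "quantity")
  s <- vapply(sources, `[[`, numeric(1), "sa")
  if (sum(q) == 0) stop("mixture has zero total quantity")
  sum(q) / sum(q / s)
}
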