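## Domain types for nuclides, reaction channels, neutron fields and targets,
## plus the bundled nuclear-data fixtures (plain-text JSON under extdata/).

#' Construct an isotope
#'
#' @param symbol nuclide symbol, e.g. `"Lu-176"`.
#' @param atomic_mass atomic mass in g/mol.  The bundled fixtures use the
#'   integer mass number (176, 175, ...) exactly as the published yield
#'   formulas do; the sub-0.1 percent difference from the true atomic mass
#'   is irrelevant at the precision of activation cross-sections.
#' @param half_life half-life in seconds, a suffixed string ("6.71d",
#'   "1.911h"), or `"stable"`.
#' @param branches optional named numeric vector of decay-branch fractions
#'   (must sum to 1); per-branch decay constants are the total decay
#'   constant scaled by the fraction.
#' @param weight_percent weight percent of this isotope in its element (or
#'   target), NA if unspecified.
#' @return object of class `isotope`.
#' @export
isotope <- function(symbol, atomic_mass, half_life = "stable",
                    branches = NULL, weight_percent = NA_real_) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  if (!is.numeric(atomic_mass) || atomic_mass <= 0)
    stop("atomic_mass must be positive (g/mol)")
  hl <- parse_time(half_life)
  lam <- decay_constant(hl)
  if (is.null(branches)) {
    branches <- if (is.finite(hl)) c(total = 1) else numeric(0)
  }
  if (length(branches) && abs(sum(branches) - 1) > 1e-9)
    stop("decay branch fractions must sum to 1")
  structure(list(
    symbol = symbol,
    element = sub("-.*$", "", symbol),
    atomic_mass = as.numeric(atomic_mass),
    half_life = hl,
    lambda_total = lam,
    decay_constants = lam * branches,
    weight_percent = as.numeric(weight_percent)
  ), class = "isotope")
}

#' @export
print.isotope <- function(x, ...) {
  hl <- if (is.finite(x$half_life)) sprintf("T1/2 = %.4g s", x$half_life)
        else "stable"
  cat(sprintf("<isotope> %s  M = %g g/mol  %s", x$symbol, x$atomic_mass, hl))
  if (is.finite(x$weight_percent))
    cat(sprintf("  (%g wt%% of target element)", x$weight_percent))
  cat("\n")
  invisible(x)
}

is_stable <- function(iso) !is.finite(iso$half_life)

#' Construct a reaction channel
#'
#' One neutron-induced channel on a parent nuclide.  For 1/v nuclides the
#' effective cross-section combines `sigma0` with the resonance integral
#' `I0` through the epithermal flux ratio (Hogdahl convention); for non-1/v
#' nuclides (`non_1v = TRUE`) the thermal cross-section is instead scaled by
#' the Westcott `k_factor` which already absorbs the spectral detail.
#'
#' @param parent,product `isotope` objects.
#' @param sigma0 2200 m/s thermal cross-section, barns.
#' @param I0 infinite-dilution resonance integral, barns.
#' @param sigma_fast fast-neutron cross-section, barns (default 0; fast
#'   contributions are negligible in a well-moderated reactor but are
#'   carried for generality).
#' @param kind one of "n-gamma", "n-alpha", "n-p".
#' @param non_1v logical; nuclide deviates from 1/v in the thermal region.
#' @param k_factor Westcott k-factor (> 0); 1 for 1/v nuclides.
#' @param elemental_loss logical; does this channel remove atoms from the
#'   parent's chemical element (product chain ends outside the element)?
#'   Channels that merely shuffle isotopes of the same element leave the
#'   elemental pool intact and do not degrade specific activity.
#' @param label optional channel label, e.g. "Lu-1".
#' @return object of class `reaction_channel`.
#' @export
reaction_channel <- function(parent, product, sigma0, I0 = 0, sigma_fast = 0,
                             kind = c("n-gamma", "n-alpha", "n-p"),
                             non_1v = FALSE, k_factor = 1,
                             elemental_loss = NA, label = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(parent, "isotope"), inherits(product, "isotope"))
  if (sigma0 < 0 || I0 < 0 || sigma_fast < 0)
    stop("cross-sections must be non-negative")
  if (!is.numeric(k_factor) || k_factor <= 0)
    stop("k_factor must be positive")
  if (is.na(elemental_loss))
    elemental_loss <- !identical(parent$element, product$element)
  structure(list(
    label = if (is.null(label)) paste0(parent$symbol, "->", product$symbol)
            else label,
    parent = parent, product = product,
    sigma0 = as.numeric(sigma0), I0 = as.numeric(I0),
    sigma_fast = as.numeric(sigma_fast),
    kind = kind, non_1v = isTRUE(non_1v),
    k_factor = as.numeric(k_factor),
    elemental_loss = isTRUE(elemental_loss)
  ), class = "reaction_channel")
}

#' Construct a neutron field
#'
#' @param phi_th thermal neutron flux, n cm^-2 s^-1 (> 0).
#' @param R_epi epithermal-to-thermal flux ratio (the Hogdahl f_H).
#' @param R_fast fast-to-thermal flux ratio.
#' @param alpha epithermal spectrum shape parameter, practically within
#'   \[-0.15, +0.3\] (0 for an ideal 1/E spectrum).
#' @param E_Cd cadmium cut-off energy, eV.
#' @return object of class `neutron_field`.
#' @export
neutron_field <- function(phi_th, R_epi = 0, R_fast = 0, alpha = 0,
                          E_Cd = 0.55) {
  if (!is.numeric(phi_th) || phi_th <= 0) stop("phi_th must be positive")
  if (R_epi < 0 || R_fast < 0) stop("flux ratios must be non-negative")
  structure(list(phi_th = phi_th, R_epi = R_epi, R_fast = R_fast,
                 alpha = alpha, E_Cd = E_Cd, E0 = 0.0253),
            class = "neutron_field")
}

#' Construct a target specification
#'
#' @param mass target mass in grams, on the element basis (see
#'   [element_mass_from_oxide()] for oxide targets).
#' @param element chemical element symbol of the target.
#' @param isotopes list of `isotope` objects; the first one is the
#'   production parent S1.  Weight percents must sum to 100 within 0.1
#'   (enrichment certificates round).
#' @param impurities list of elemental impurities, each a list with fields
#'   `element`, `ppm` (by mass) and `abundances` (named weight-percent
#'   vector over that element's isotopes).
#' @return object of class `target_spec`.
#' @export
target_spec <- function(mass, element, isotopes, impurities = list()) {
  if (!is.numeric(mass) || mass <= 0) stop("target mass must be positive")
  stopifnot(all(vapply(isotopes, inherits, logical(1), "isotope")))
  tot <- sum(vapply(isotopes, function(i) i$weight_percent, numeric(1)))
  if (abs(tot - 100) > 0.1)
    stop(sprintf("isotope weight percents sum to %.4f, not 100 +/- 0.1", tot))
  for (imp in impurities)
    if (imp$ppm < 0) stop("impurity ppm must be non-negative")
  structure(list(mass = mass, element = element, isotopes = isotopes,
                 impurities = impurities),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec> %g g %s, %d isotopes\n",
              x$mass, x$element, length(x$isotopes)))
  for (i in x$isotopes)
    cat(sprintf("  %-8s %6.3f wt%%\n", i$symbol, i$weight_percent))
  for (imp in x$impurities)
    cat(sprintf("  impurity %s: %g ppm\n", imp$element, imp$ppm))
  invisible(x)
}

#' Element mass contained in an oxide target
#'
#' Sesquioxide stoichiometry M2O3 by default (Lu2O3, Yb2O3).
#'
#' @param mass_oxide oxide mass in grams.
#' @param atomic_mass metal atomic mass, g/mol.
#' @param n_metal,n_oxygen stoichiometric coefficients.
#' @return metal (element) mass in grams.
#' @export
element_mass_from_oxide <- function(mass_oxide, atomic_mass,
                                    n_metal = 2, n_oxygen = 3) {
  mass_oxide * n_metal * atomic_mass /
    (n_metal * atomic_mass + n_oxygen * 15.999)
}

#' Initial atom numbers of each target isotope
#'
#' N0 = N_Av * m * P / (100 * M) per isotope.
#'
#' @param target a `target_spec`.
#' @param replication use the rounded Avogadro constant.
#' @return named numeric vector of atoms, one per isotope.
#' @export
initial_atoms <- function(target, replication = FALSE) {
  nav <- avogadro(replication)
  out <- vapply(target$isotopes, function(i)
    nav * target$mass * i$weight_percent / (100 * i$atomic_mass), numeric(1))
  names(out) <- vapply(target$isotopes, `[[`, character(1), "symbol")
  out
}

## ---- fixtures --------------------------------------------------------------

.fixture_path <- function(name) {
  f <- system.file("extdata", paste0(name, ".json"), package = "saforge")
  if (!nzchar(f) || !file.exists(f))
    stop("fixture not found: '", name, "' (available: ",
         paste(sub("\\.json$", "", list.files(
           system.file("extdata", package = "saforge"), "\\.json$")),
           collapse = ", "), ")")
  f
}

.isotope_from_json <- function(j) {
  br <- NULL
  if (!is.null(j$branches)) br <- unlist(j$branches)
  isotope(j$symbol, j$atomic_mass, j$half_life, branches = br,
          weight_percent = if (is.null(j$weight_percent)) NA_real_
                           else j$weight_percent)
}

#' Load a bundled nuclear-data fixture
#'
#' Fixtures transcribe the published activation data for the Lu-177
#' production targets: `"lu176_enriched"` (74.1 percent Lu-176 target with
#' its six reaction channels), `"yb176_enriched"` (97.6 percent Yb-176
#' target, seven Yb channels, 50 ppm elemental Lu impurity) and
#' `"lu_natural"` (natural lutetium, 97.41 percent Lu-175 / 2.59 percent
#' Lu-176, same channel set as the enriched Lu target).
#'
#' Isotopes certified only as "< 0.01 percent" are stored at the interval
#' midpoint 0.005 with the bound kept in the fixture file.
#'
#' @param name fixture name.
#' @return list with elements `target` (a [target_spec()]) and `channels`
#'   (named list of [reaction_channel()]).
#' @export
load_fixture <- function(name) {
  raw <- jsonlite::read_json(.fixture_path(name))
  isos <- lapply(raw$isotopes, .isotope_from_json)
  names(isos) <- vapply(isos, `[[`, character(1), "symbol")
  prods <- lapply(raw$products, .isotope_from_json)
  names(prods) <- vapply(prods, `[[`, character(1), "symbol")
  all_iso <- c(isos, prods)
  channels <- lapply(raw$channels, function(ch) {
    parent <- all_iso[[ch$parent]]
    if (is.null(parent)) stop("fixture channel parent unknown: ", ch$parent)
    product <- all_iso[[ch$product]]
    if (is.null(product)) stop("fixture channel product unknown: ", ch$product)
    reaction_channel(
      parent = parent, product = product,
      sigma0 = ch$sigma0,
      I0 = if (is.null(ch$I0)) 0 else ch$I0,
      sigma_fast = if (is.null(ch$sigma_fast)) 0 else ch$sigma_fast,
      kind = if (is.null(ch$kind)) "n-gamma" else ch$kind,
      non_1v = isTRUE(ch$non_1v),
      k_factor = if (is.null(ch$k_factor)) 1 else ch$k_factor,
      elemental_loss = if (is.null(ch$elemental_loss)) NA
                       else ch$elemental_loss,
      label = ch$label)
  })
  names(channels) <- vapply(channels, `[[`, character(1), "label")
  impurities <- lapply(raw$target$impurities, function(imp)
    list(element = imp$element, ppm = imp$ppm,
         abundances = if (is.null(imp$abundances)) NULL
                      else unlist(imp$abundances)))
  target <- target_spec(mass = raw$target$mass_g, element = raw$target$element,
                        isotopes = isos, impurities = impurities)
  list(target = target, channels = channels)
}
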