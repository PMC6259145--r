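## Physical constants, unit helpers and shared numerical kernels.

.CODATA_AVOGADRO <- 6.02214076e23
.ROUNDED_AVOGADRO <- 6.02e23

#' Avogadro constant
#'
#' Full-precision CODATA value by default.  `replication = TRUE` switches to
#' the rounded 6.02e23 traditionally used in hand calculations, so that
#' digit-level replication of published numbers is possible.  The difference
#' is below 0.04 percent.
#'
#' @param replication logical; use the rounded historical value.
#' @return atoms per mole.
#' @export
avogadro <- function(replication = FALSE) {
  if (isTRUE(replication)) .ROUNDED_AVOGADRO else .CODATA_AVOGADRO
}

#' Convert a cross-section from barns to cm^2
#'
#' @param sigma cross-section in barns (>= 0).
#' @return cross-section in cm^2 (1 barn = 1e-24 cm^2).
#' @export
barns_to_cm2 <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("cross-section must be finite and non-negative (barns)")
  sigma * 1e-24
}

#' Parse a time value with unit suffix to seconds
#'
#' Accepts numbers (taken as seconds) or strings with a unit suffix:
#' "s" (seconds), "m" (minutes), "h" (hours), "d" (days), "y" (365.25-day
#' years).  The literal "stable" maps to `Inf`.
#'
#' @param x numeric or character vector.
#' @return numeric vector of seconds.
#' @export
parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  units <- c(s = 1, m = 60, h = 3600, d = 86400, y = 86400 * 365.25)
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (tolower(s) == "stable") return(Inf)
    m <- regmatches(s, regexec("^([0-9eE.+-]+)\\s*([smhdy]?)$", s))[[1]]
    if (length(m) == 0 || m[2] == "")
      stop("cannot parse time value: '", s, "'")
    v <- suppressWarnings(as.numeric(m[2]))
    if (!is.finite(v)) stop("cannot parse time value: '", s, "'")
    u <- if (m[3] == "") "s" else m[3]
    v * units[[u]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decay constant from a half-life
#'
#' @param half_life half-life in seconds, or a suffixed string ("6.71d").
#' @return lambda in 1/s (0 for a stable nuclide).
#' @export
decay_constant <- function(half_life) {
  t <- parse_time(half_life)
  ifelse(is.finite(t), log(2) / t, 0)
}

## ---- numerical kernels -----------------------------------------------------
## phi1(u) = (1 - exp(-u))/u, the first exponential divided difference.
## Stable for all u via expm1; series branch near 0.
.phi1 <- function(u) {
  small <- abs(u) < 1e-8
  out <- u
  out[small] <- 1 - u[small] / 2 + u[small]^2 / 6
  ub <- u[!small]
  out[!small] <- -expm1(-ub) / ub
  out
}

## d phi1 / du, used for the confluent (repeated-rate) branch below.
.dphi1 <- function(u) {
  small <- abs(u) < 1e-2
  out <- u
  us <- u[small]
  out[small] <- -1 / 2 + us / 3 - us^2 / 8 + us^3 / 30 - us^4 / 144
  ub <- u[!small]
  out[!small] <- (exp(-ub) * (1 + ub) - 1) / ub^2
  out
}

## psi(u, v) = (phi1(u) - phi1(v))/(u - v); confluent limit phi1'(u).
.psi <- function(u, v) {
  d <- u - v
  tol <- 1e-5 * (1 + abs(u) + abs(v))
  conf <- abs(d) <= tol
  out <- u
  out[conf] <- .dphi1((u[conf] + v[conf]) / 2)
  out[!conf] <- (.phi1(u[!conf]) - .phi1(v[!conf])) / d[!conf]
  out
}

## First-order Bateman kernel: (exp(-a t) - exp(-b t))/(b - a), the
## two-node divided difference of exp(-x t) (up to sign).  Symmetric in
## (a, b); stable for b ~ a where it tends to t*exp(-a t).
.bateman2 <- function(a, b, t) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  t * exp(-a * t) * .phi1((b - a) * t)
}

## Second-order Bateman kernel: the three-node divided difference of
## exp(-x t) over rates (a, b, c).  Equals the usual three-exponential
## Bateman bracket sum_i exp(-x_i t)/prod_{j!=i}(x_j - x_i).  Symmetric;
## repeated rates handled by the confluent psi branch.
.bateman3 <- function(a, b, c, t) {
  r <- sort(c(a, b, c))
  u <- (r[2] - r[1]) * t
  v <- (r[3] - r[1]) * t
  -t^2 * exp(-r[1] * t) * .psi(u, v)
}

## relative difference helper used across validation code
.reldiff <- function(x, y) {
  s <- pmax(abs(x), abs(y))
  d <- abs(x - y)
  ifelse(s == 0, 0, d / s)
}
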