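## Independent validator: a generalized first-order activation/decay
## network integrated by matrix exponential.  Every closed form in the
## package is tested against this route; it deliberately shares no code
## with the Bateman kernels.

#' Construct a linear activation/decay network
#'
#' States are isotope pools coupled by first-order rates: neutron capture
#' enters as a loss edge on the parent plus a gain edge on the product,
#' decay as a loss edge plus branch-gain edges.  Leaks to untracked sinks
#' are allowed (column loss may exceed tracked gains).
#'
#' @param states character vector of state labels.
#' @param rate_matrix square matrix M (1/s) with `dN/dt = M N`:
#'   off-diagonal `M[i, j]` is the rate from state j into state i
#'   (non-negative), diagonal entries are total losses (non-positive).
#' @param initial_atoms numeric vector of initial atoms per state.
#' @return object of class `linear_network`.
#' @export
linear_network <- function(states, rate_matrix, initial_atoms) {
  n <- length(states)
  rate_matrix <- as.matrix(rate_matrix)
  stopifnot(nrow(rate_matrix) == n, ncol(rate_matrix) == n,
            length(initial_atoms) == n)
  if (any(!is.finite(rate_matrix))) stop("rates must be finite")
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  if (any(diag(rate_matrix) > 1e-300))
    stop("diagonal entries must be non-positive (total losses)")
  if (any(colSums(off) > -diag(rate_matrix) + 1e-12 * pmax(1, colSums(off))))
    stop("gains out of a state exceed its total loss")
  dimnames(rate_matrix) <- list(states, states)
  structure(list(states = states, rate_matrix = rate_matrix,
                 initial_atoms = stats::setNames(initial_atoms, states)),
            class = "linear_network")
}

#' Integrate a linear network
#'
#' Solves dN/dt = M N by matrix exponential at each requested time; exact
#' to machine precision for the small systems used here.
#'
#' @param network a [linear_network()].
#' @param times non-negative times, s.
#' @return matrix of atoms, one row per time, one column per state.
#' @export
integrate_network <- function(network, times) {
  stopifnot(inherits(network, "linear_network"))
  if (any(times < 0)) stop("times must be non-negative")
  M <- network$rate_matrix
  m <- length(network$states)
  out <- vapply(times, function(t) {
    as.numeric(Matrix::expm(M * t) %*% network$initial_atoms)
  }, numeric(m))
  out <- if (m == 1L) matrix(out, ncol = 1L) else t(out)
  colnames(out) <- network$states
  out
}

#' Build the simple-target capture network, with sinks
#'
#' Three tracked states: parent S, product R, plus explicit sinks for
#' decayed and destroyed atoms so that conservation can be asserted.
#'
#' @param Delta_S parent burn-up constant (1/s); the share `omega_frac`
#'   of captures feeds R, the rest leaks to the "burned-other" sink.
#' @param lambda decay constant of R.
#' @param Delta_Ri destruction constant of R.
#' @param omega_frac fraction of parent captures that produce R.
#' @param N0 initial parent atoms.
#' @return a [linear_network()] with states S, R, decayed, destroyed.
#' @export
capture_network <- function(Delta_S, lambda, Delta_Ri = 0, omega_frac = 1,
                            N0 = 1) {
  M <- matrix(0, 4, 4)
  M[1, 1] <- -Delta_S
  M[2, 1] <- Delta_S * omega_frac
  M[4, 1] <- Delta_S * (1 - omega_frac)
  M[2, 2] <- -(lambda + Delta_Ri)
  M[3, 2] <- lambda
  M[4, 2] <- Delta_Ri
  linear_network(c("S", "R", "decayed", "destroyed"), M, c(N0, 0, 0, 0))
}

#' Build the two-step chain network, with sinks
#'
#' States: parent S, intermediate Rx, product Ri, and sinks for Ri decay
#' and neutron destruction.
#'
#' @param Delta_S,Lambda_x,lambda_x_feed,Lambda_i,lambda_i rate constants,
#'   1/s; `lambda_x_feed` is the share of `Lambda_x` feeding Ri.
#' @param omega_frac fraction of parent captures producing Rx.
#' @param N0 initial parent atoms.
#' @return a [linear_network()].
#' @export
chain_network <- function(Delta_S, Lambda_x, lambda_x_feed, Lambda_i,
                          lambda_i, omega_frac = 1, N0 = 1) {
  stopifnot(lambda_x_feed <= Lambda_x, lambda_i <= Lambda_i)
  M <- matrix(0, 5, 5)
  M[1, 1] <- -Delta_S
  M[2, 1] <- Delta_S * omega_frac
  M[5, 1] <- Delta_S * (1 - omega_frac)
  M[2, 2] <- -Lambda_x
  M[3, 2] <- lambda_x_feed
  M[5, 2] <- Lambda_x - lambda_x_feed
  M[3, 3] <- -Lambda_i
  M[4, 3] <- lambda_i
  M[5, 3] <- Lambda_i - lambda_i
  linear_network(c("S", "Rx", "Ri", "decayed", "other"), M,
                 c(N0, 0, 0, 0, 0))
}
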