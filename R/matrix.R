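#' Build the five-pool decomposition rate matrix
#'
#' Assembles the generator matrix `M` (yr^-1) of the linear pool system
#' `dx/dt = M x + b` for one combination of climate and woody-size
#' modifiers.  The effective first-order rate of labile pool i is
#' `k_i = alpha_i * climate_factor * size_factor`; the humus rate is
#' `k_H = alpha_H * climate_factor` (woody-size features do not apply to
#' humus).  Diagonal entries are `-k_i`; entry `(j, i)` is the transfer
#' `flow[i, j] * k_i`; the humus row receives `humus_fraction * k_i` from
#' every labile pool.  The part of each `k_i` not routed to another pool is
#' mass loss to the atmosphere, so every column's total outflow equals
#' `k_i` exactly.
#'
#' @param params An `awenh_params` set.
#' @param climate_factor Dimensionless climate dependence factor (>= 0),
#'   from [climate_modifier()].
#' @param size_factor Dimensionless woody-size modifier in (0, 1], from
#'   [size_modifier()].
#' @return A 5x5 matrix with rows/columns named A, W, E, N, H.
#' @export
build_rate_matrix <- function(params, climate_factor, size_factor = 1) {
  if (!is.finite(climate_factor) || climate_factor < 0)
    stop("climate_factor must be finite and >= 0")
  if (!is.finite(size_factor) || size_factor <= 0)
    stop("size_factor must be finite and > 0")
  k <- params$alpha * climate_factor * size_factor
  kh <- params$alpha_h * climate_factor
  m <- matrix(0, 5, 5, dimnames = list(POOLS, POOLS))
  diag(m) <- -c(k, kh)
  for (i in seq_along(LABILE)) for (j in seq_along(LABILE)) {
    if (i != j) m[j, i] <- params$flow[i, j] * k[i]
  }
  m["H", LABILE] <- params$humus_fraction * k
  m
}

#' Matrix exponential for pool generator matrices
#'
#' Thin wrapper around [Matrix::expm()] returning a base matrix; used as the
#' reference propagator.  Near-singularity is not an issue for the
#' exponential itself, but non-finite entries are rejected.
#' @param m A square matrix.
#' @return `exp(m)` as a base matrix.
#' @keywords internal
expm_pool <- function(m) {
  if (any(!is.finite(m))) stop("non-finite rate matrix entries")
  as.matrix(Matrix::expm(Matrix::Matrix(m)))
}

#' Advance the pool system by one year
#'
#' Exact solution of the linear system `dx/dt = M x + b` over a unit time
#' step with constant annual input `b`:
#' \deqn{x(t{+}1) = e^{M} x(t) + M^{-1}(e^{M} - I)\,b.}
#' For a (near-)singular `M` the input term falls back to the truncated
#' series \eqn{\sum_{k\ge 0} M^k/(k{+}1)!\; b}, which is exact in the limit
#' and covers the zero-matrix case (pure accumulation).  Because `M` is a
#' Metzler matrix (non-negative off-diagonal), non-negative states and
#' inputs stay non-negative.
#'
#' @param state Pool vector (length 5, kg C m^-2), non-negative.
#' @param annual_input Litter input over the year (length 5, kg C m^-2
#'   yr^-1), non-negative.
#' @param matrix Rate matrix from [build_rate_matrix()].
#' @return The pool vector after one year.
#' @export
step_annual <- function(state, annual_input, matrix) {
  st <- step_annual_fluxes(state, annual_input, matrix)
  st$state
}

#' One annual step with explicit mass bookkeeping
#'
#' Like [step_annual()], but also integrates the fluxes over the year so the
#' carbon balance can be audited: the change in total stock must equal total
#' litter input minus the mass decomposed and exported to the atmosphere.
#' The export is computed independently of the state update, as
#' \eqn{-\mathbf{1}^\top M \int_0^1 x(t)\,dt} corrected for internal
#' transfers (column sums of `M` give net loss per pool directly).
#'
#' @inheritParams step_annual
#' @return A list: `state` (pools after the step), `input_total` (kg C
#'   m^-2), `export_total` (kg C m^-2 lost to the atmosphere over the step).
#' @export
step_annual_fluxes <- function(state, annual_input, matrix) {
  if (any(!is.finite(matrix))) stop("non-finite rate matrix entries")
  state <- as.numeric(state); b <- as.numeric(annual_input)
  if (length(state) != nrow(matrix) || length(b) != nrow(matrix))
    stop("state/input length must match the rate matrix dimension")
  if (all(matrix == 0)) {
    return(list(state = state + b, input_total = sum(b), export_total = 0))
  }
  ph <- expm_pool(matrix)
  n <- nrow(matrix)
  rc <- tryCatch(rcond(matrix), error = function(e) 0)
  if (rc > 1e-12) {
    psi <- solve(matrix, ph - diag(n))            # M^-1 (e^M - I)
    psi2 <- solve(matrix, psi - diag(n))          # M^-2 (e^M - I - M)
  } else {
    psi <- phi_series(matrix, 1L)
    psi2 <- phi_series(matrix, 2L)
  }
  new_state <- as.numeric(ph %*% state + psi %*% b)
  # integral of x(t) over the year, for flux bookkeeping
  int_x <- as.numeric(psi %*% state + psi2 %*% b)
  export <- -sum(colSums(matrix) * int_x)
  list(state = new_state, input_total = sum(b), export_total = export)
}

# truncated series for phi_k(M) = sum_{j>=0} M^j / (j+k)!  (phi_1 covers
# M^-1(e^M - I), phi_2 covers M^-2(e^M - I - M)); converges fast for the
# annual-step magnitudes used here
phi_series <- function(m, k, terms = 40L) {
  n <- nrow(m)
  acc <- diag(n) / factorial(k)
  pw <- diag(n)
  for (j in seq_len(terms)) {
    pw <- pw %*% m
    acc <- acc + pw / factorial(j + k)
  }
  acc
}

#' Analytic steady state of the pool system
#'
#' Solves `M x + b = 0` for the equilibrium pools under constant climate and
#' constant annual input; this is the long-run limit of repeated
#' [step_annual()] and is what the spin-up converges to.  Steady-state
#' stocks are linear in the input and (for the same chemistry) inversely
#' proportional to the climate factor.
#'
#' @param params An `awenh_params` set.
#' @param climate_factor Dimensionless climate factor (> 0).
#' @param size_factor Woody-size modifier in (0, 1].
#' @param annual_input Constant annual litter input (length 5, kg C m^-2
#'   yr^-1).
#' @return Steady-state pool vector (named A, W, E, N, H).
#' @export
steady_state <- function(params, climate_factor, size_factor = 1,
                         annual_input) {
  if (climate_factor <= 0)
    stop("steady state undefined: climate_factor must be > 0 ",
         "(zero decomposition has no finite equilibrium)")
  m <- build_rate_matrix(params, climate_factor, size_factor)
  if (rcond(m) < 1e-12)
    stop("rate matrix is numerically singular (condition number > 1e12); ",
         "no reliable steady state")
  x <- solve(m, -as.numeric(annual_input))
  names(x) <- POOLS
  x
}

# --- cached eigen-propagator -------------------------------------------------
# Every rate matrix for a given (params, size_factor) is climate_factor * B
# where B = build_rate_matrix(params, 1, size_factor).  Diagonalizing B once
# makes the annual step for any climate factor c a pair of 5-vector
# operations: e^{cB} x = V diag(e^{c lambda}) V^-1 x and the input term uses
# phi1(c lambda) = (e^{c lambda}-1)/(c lambda).  Used by the landscape
# runner; equivalence with step_annual() is covered by tests.

pool_propagator <- function(params, size_factor = 1) {
  b <- build_rate_matrix(params, 1, size_factor)
  e <- eigen(b)
  v <- e$vectors
  if (rcond(abs(v)) < 1e-10)
    stop("pool matrix is too close to defective for the eigen propagator")
  list(lambda = e$values, v = v, vinv = solve(v), base = b,
       base_inv = solve(b))
}

phi1z <- function(z) {
  small <- abs(z) < 1e-8
  zz <- z
  zz[small] <- 1            # dodge 0/0; overwritten below
  out <- (exp(zz) - 1) / zz
  out[small] <- 1 + z[small] / 2
  out
}

# advance all rows of states (n x 5) one year; cf = climate factor per row,
# inputs = n x 5 annual litter input
propagate_pools <- function(states, inputs, prop, cf) {
  lam_c <- outer(prop$lambda, cf)            # 5 x n
  y1 <- prop$vinv %*% t(states)              # 5 x n
  y2 <- prop$vinv %*% t(inputs)
  out <- prop$v %*% (exp(lam_c) * y1) + prop$v %*% (phi1z(lam_c) * y2)
  t(Re(out))
}
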