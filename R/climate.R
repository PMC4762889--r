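#' Climate records
#'
#' Builds and validates a table of annual climate records: calendar year,
#' mean annual temperature (degC), lowest and highest monthly mean
#' temperature (degC) and annual precipitation (mm).  The monthly extremes
#' feed the optional sinusoid correction of [climate_modifier()].
#'
#' @param year Integer calendar year(s).
#' @param mat Mean annual temperature, degC.
#' @param t_min,t_max Lowest / highest monthly mean temperature, degC.
#' @param precip Annual precipitation, mm (non-negative).
#' @return A `data.frame` with columns `year`, `mat`, `t_min`, `t_max`,
#'   `precip`.
#' @export
climate_record <- function(year, mat, t_min = mat, t_max = mat, precip) {
  cl <- data.frame(year = as.integer(year), mat = mat,
                   t_min = t_min, t_max = t_max, precip = precip)
  validate_climate(cl)
  cl
}

validate_climate <- function(cl) {
  need <- c("year", "mat", "t_min", "t_max", "precip")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("climate table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(cl[need[-1]]))))
    stop("climate table contains non-finite values")
  if (any(cl$precip < 0)) stop("negative precipitation in climate table")
  if (any(cl$t_min > cl$mat + 1e-9) || any(cl$t_max < cl$mat - 1e-9))
    stop("monthly extremes must bracket the annual mean (t_min <= mat <= t_max)")
  invisible(cl)
}

#' Climate dependence factor for decomposition
#'
#' The dimensionless multiplier applied to the reference decomposition rates:
#' \deqn{f(T, P) = \exp(\beta_1 T + \beta_2 T^2)\,(1 - e^{\gamma P})}
#' with temperature \eqn{T} in degC and annual precipitation \eqn{P} in
#' metres (the `precip` argument is in mm and converted internally).  The
#' factor rises steeply with precipitation when dry and approaches a finite
#' asymptote beyond roughly 1500 mm; it rises with temperature over the
#' boreal range.
#'
#' With `use_sinusoid = TRUE` the temperature term is averaged over twelve
#' monthly temperatures \eqn{T_m = T + A \sin(2\pi m/12)} with amplitude
#' \eqn{A = (t_{max} - t_{min})/2}, accounting for intra-annual temperature
#' variation; by default the annual mean is used directly.
#'
#' @param mat Mean annual temperature, degC (vectorized).
#' @param precip Annual precipitation, mm (vectorized, non-negative).
#' @param params An `awenh_params` set; default the packaged published set.
#' @param t_min,t_max Lowest/highest monthly mean temperature, degC; only
#'   used when `use_sinusoid = TRUE`.
#' @param use_sinusoid Average the temperature response over a sinusoidal
#'   monthly cycle instead of using the annual mean.
#' @return Non-negative dimensionless factor(s), same length as the inputs.
#' @export
#' @examples
#' climate_modifier(3.5, 1150)  # the boreal "country mean" worked example
climate_modifier <- function(mat, precip, params = yasso07_params(),
                             t_min = mat, t_max = mat, use_sinusoid = FALSE) {
  if (any(!is.finite(mat)) || any(!is.finite(precip)))
    stop("non-finite climate input")
  if (any(precip < 0)) stop("negative precipitation")
  p_m <- precip / 1000  # mm -> m
  if (use_sinusoid) {
    amp <- (t_max - t_min) / 2
    if (any(amp < -1e-9)) stop("t_max < t_min")
    months <- sin(2 * pi * (1:12) / 12)
    tt <- outer(mat, rep(1, 12)) + outer(amp, months)
    temp_term <- rowMeans(exp(params$beta1 * tt + params$beta2 * tt^2))
  } else {
    temp_term <- exp(params$beta1 * mat + params$beta2 * mat^2)
  }
  temp_term * (1 - exp(params$gamma * p_m))
}

#' Woody-size modifier for decomposition rates
#'
#' Litter dimension slows decomposition of woody material: the labile rates
#' are multiplied by \eqn{h(d) = \min\{1, (1 + \phi_1 d + \phi_2 d^2)^r\}}
#' for diameter \eqn{d} in cm.  At \eqn{d = 0} (non-woody litter: foliage,
#' fine roots, bark, ground vegetation) the modifier is exactly 1, meaning
#' no woody-specific behaviour; it decreases with diameter so that coarse
#' woody litter (stems, stumps; 10 cm class) decomposes over a longer time
#' span than fine woody litter (branches, coarse roots; 2 cm class).
#'
#' @param diameter_cm Litter size class diameter, cm (vectorized,
#'   non-negative; the pipeline uses 0, 2 and 10).
#' @param params An `awenh_params` set.
#' @return Factor(s) in (0, 1].
#' @export
size_modifier <- function(diameter_cm, params = yasso07_params()) {
  if (any(!is.finite(diameter_cm))) stop("non-finite diameter")
  if (any(diameter_cm < 0)) stop("negative litter diameter")
  base <- 1 + params$size_phi1 * diameter_cm + params$size_phi2 * diameter_cm^2
  if (any(base <= 0))
    stop("size-modifier base (1 + phi1*d + phi2*d^2) must stay positive")
  pmin(1, base^params$size_r)
}
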