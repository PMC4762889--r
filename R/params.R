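#' Decomposition parameter sets
#'
#' An `awenh_params` object collects every constant of the five-pool
#' decomposition model: reference mass-loss rates of the four labile pools
#' (A: acid-hydrolyzeable, W: water-soluble, E: ethanol/non-polar-soluble,
#' N: non-soluble) and of humus (H), the relative mass-flow fractions among
#' the labile pools, the fraction of decomposed labile mass routed to humus,
#' the climate-response coefficients and the woody-size-modifier coefficients.
#'
#' The default set, shipped as a flat key/value file in
#' `inst/extdata/yasso07_map.txt`, is the published maximum-a-posteriori
#' Yasso07 estimate of Tuomi et al. (2011); all model functions accept
#' alternative sets.
#'
#' @param file Path to a flat `key = value` parameter file.  `NULL` (default)
#'   loads the packaged published set.
#' @return An object of class `awenh_params`: a list with elements
#'   `alpha` (named numeric, labile reference rates, yr^-1), `alpha_h`
#'   (humus rate, yr^-1), `flow` (4x4 matrix, `flow[i, j]` = fraction of
#'   decomposed mass of pool i routed to pool j, zero diagonal),
#'   `humus_fraction`, `beta1` (degC^-1), `beta2` (degC^-2), `gamma` (m^-1,
#'   negative), and `size_phi1`, `size_phi2`, `size_r` (woody-size modifier).
#' @seealso [climate_modifier()], [build_rate_matrix()], [write_params()]
#' @export
#' @examples
#' p <- yasso07_params()
#' p$alpha
yasso07_params <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "yasso07_map.txt", package = "awenh",
                        mustWork = TRUE)
  }
  read_params(file)
}

LABILE <- c("A", "W", "E", "N")
POOLS <- c("A", "W", "E", "N", "H")

#' Read a parameter file
#'
#' Parses a flat `key = value` text file (`#` comments allowed) whose keys
#' match the `awenh_params` fields: `alpha_A`, `alpha_W`, `alpha_E`,
#' `alpha_N`, `alpha_H`, the twelve `flow_<from>_<to>` fractions,
#' `humus_fraction`, `beta1`, `beta2`, `gamma`, `size_phi1`, `size_phi2`,
#' `size_r`.
#'
#' @param file Path to the parameter file.
#' @return An `awenh_params` object (validated).
#' @export
read_params <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric value for key(s): ",
                        paste(keys[is.na(vals)], collapse = ", "))
  names(vals) <- keys
  flow <- matrix(0, 4, 4, dimnames = list(LABILE, LABILE))
  for (i in LABILE) for (j in LABILE) {
    if (i == j) next
    key <- paste0("flow_", i, "_", j)
    if (!key %in% keys) stop("parameter file missing key: ", key)
    flow[i, j] <- vals[[key]]
  }
  need <- c("alpha_A", "alpha_W", "alpha_E", "alpha_N", "alpha_H",
            "humus_fraction", "beta1", "beta2", "gamma",
            "size_phi1", "size_phi2", "size_r")
  miss <- setdiff(need, keys)
  if (length(miss)) stop("parameter file missing key(s): ",
                         paste(miss, collapse = ", "))
  p <- structure(list(
    alpha = c(A = vals[["alpha_A"]], W = vals[["alpha_W"]],
              E = vals[["alpha_E"]], N = vals[["alpha_N"]]),
    alpha_h = vals[["alpha_H"]],
    flow = flow,
    humus_fraction = vals[["humus_fraction"]],
    beta1 = vals[["beta1"]], beta2 = vals[["beta2"]], gamma = vals[["gamma"]],
    size_phi1 = vals[["size_phi1"]], size_phi2 = vals[["size_phi2"]],
    size_r = vals[["size_r"]]
  ), class = "awenh_params")
  validate_params(p)
}

#' Write a parameter set to a flat key/value file
#'
#' @param params An `awenh_params` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_params <- function(params, file) {
  params <- validate_params(params)
  out <- c(
    sprintf("alpha_%s = %.17g", LABILE, params$alpha),
    sprintf("alpha_H = %.17g", params$alpha_h)
  )
  for (i in LABILE) for (j in LABILE) {
    if (i != j) out <- c(out, sprintf("flow_%s_%s = %.17g", i, j,
                                      params$flow[i, j]))
  }
  out <- c(out,
           sprintf("humus_fraction = %.17g", params$humus_fraction),
           sprintf("beta1 = %.17g", params$beta1),
           sprintf("beta2 = %.17g", params$beta2),
           sprintf("gamma = %.17g", params$gamma),
           sprintf("size_phi1 = %.17g", params$size_phi1),
           sprintf("size_phi2 = %.17g", params$size_phi2),
           sprintf("size_r = %.17g", params$size_r))
  writeLines(out, file)
  invisible(file)
}

#' Validate a parameter set
#'
#' Checks the structural invariants: positive labile and humus rates, a
#' negative precipitation coefficient `gamma`, non-negative flow fractions
#' with zero diagonal, and for each source pool a total routed fraction
#' (transfers plus humus share) of at most one — the remainder is the mass
#' lost to the atmosphere.
#'
#' @param params An `awenh_params` object (or a bare list with its fields).
#' @return The validated object, invisibly classed as `awenh_params`.
#' @export
validate_params <- function(params) {
  stopifnot(is.list(params))
  with(params, {
    if (length(alpha) != 4L || any(!is.finite(alpha)) || any(alpha <= 0))
      stop("labile reference rates must be four positive finite numbers")
    if (!is.finite(alpha_h) || alpha_h <= 0)
      stop("humus rate alpha_H must be positive")
    if (!is.finite(gamma) || gamma >= 0)
      stop("gamma must be negative (decomposition rises with precipitation)")
    if (!is.matrix(flow) || any(dim(flow) != 4L))
      stop("flow must be a 4x4 matrix")
    if (any(flow < 0) || any(diag(flow) != 0))
      stop("flow fractions must be >= 0 with a zero diagonal")
    if (humus_fraction < 0 || humus_fraction > 1)
      stop("humus_fraction must lie in [0, 1]")
    tot <- rowSums(flow) + humus_fraction
    if (any(tot > 1 + 1e-12))
      stop("outgoing flow fractions + humus_fraction exceed 1 for pool(s): ",
           paste(LABILE[tot > 1 + 1e-12], collapse = ", "))
  })
  names(params$alpha) <- LABILE
  if (!inherits(params, "awenh_params")) class(params) <- "awenh_params"
  invisible(params)
}

#' @export
print.awenh_params <- function(x, ...) {
  cat("Five-pool decomposition parameter set (awenh_params)\n")
  cat("  labile rates alpha (1/yr): ",
      paste(sprintf("%s=%.3g", LABILE, x$alpha), collapse = "  "), "\n")
  cat(sprintf("  humus rate alpha_H = %.3g 1/yr, humus fraction = %.3g\n",
              x$alpha_h, x$humus_fraction))
  cat(sprintf("  climate: beta1 = %.3g /degC, beta2 = %.3g /degC^2, gamma = %.3g /m\n",
              x$beta1, x$beta2, x$gamma))
  cat(sprintf("  woody size: phi1 = %.3g, phi2 = %.3g, r = %.3g\n",
              x$size_phi1, x$size_phi2, x$size_r))
  cat("  mass-flow fractions (from row to column):\n")
  print(round(x$flow, 3))
  invisible(x)
}

#' @export
coef.awenh_params <- function(object, ...) {
  fl <- object$flow
  flows <- fl[row(fl) != col(fl)]
  names(flows) <- paste0("flow_", LABILE[row(fl)[row(fl) != col(fl)]], "_",
                         LABILE[col(fl)[row(fl) != col(fl)]])
  c(setNames(object$alpha, paste0("alpha_", LABILE)),
    alpha_H = object$alpha_h, flows,
    humus_fraction = object$humus_fraction,
    beta1 = object$beta1, beta2 = object$beta2, gamma = object$gamma,
    size_phi1 = object$size_phi1, size_phi2 = object$size_phi2,
    size_r = object$size_r)
}
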