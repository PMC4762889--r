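# shared fixtures: everything is generated in code, nothing read from disk
# beyond the package's own shipped tables

p_def <- yasso07_params()

# a small landscape with matching climate and biomass, reused across files
tiny_world <- function(n = 60, seed = 7, ...) {
  plots <- filter_upland(generate_landscape(n, n_districts = min(19L, n),
                                            seed = seed))
  list(plots = plots,
       climate = generate_climate(plots, seed = seed + 1, ...),
       biomass = generate_biomass(plots, seed = seed + 2))
}

# random valid rate-matrix configuration for property loops
random_config <- function(params = p_def) {
  list(cf = runif(1, 0.2, 1.9),
       sf = size_modifier(sample(c(0, 2, 10), 1), params),
       b = runif(5, 0, 0.3) * c(1, 1, 1, 1, 0),
       x = runif(5, 0, 5))
}

# independent ODE oracle for the annual step (stiff solver, tight tolerance)
ode_step <- function(x0, b, m) {
  deriv <- function(t, y, parms) list(m %*% y + b)
  out <- deSolve::lsoda(y = x0, times = c(0, 1), func = deriv,
                        rtol = 1e-10, atol = 1e-12)
  as.numeric(out[2, -1])
}
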