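# shared fixtures: small grids and fast model configurations so the suite
# stays quick while exercising the full coupling

default_rates <- function(...) rate_parameters(...)

small_pop <- function(p = default_rates(), n_x = 121) {
  xb_populations(p, n_x = n_x, x_range = c(-2, 3))
}

quick_model <- function(...) {
  airway_model(...)
}

# reaction-only four-state ODE oracle at a single bond extension x,
# integrated with deSolve (dense output, tight tolerances)
ode_oracle_at_x <- function(x, p, times, init = c(1, 0, 0, 0)) {
  rt <- rate_functions(x, p)
  rhs <- function(t, y, parms) {
    dM <- -p$k1 * y[1] + p$k2 * y[2] + rt$g * y[4]
    dMp <- p$k1 * y[1] - (p$k2 + rt$fp) * y[2] + rt$gp * y[3]
    dAMp <- rt$fp * y[2] - (rt$gp + p$k2) * y[3] + p$k1 * y[4]
    dAM <- p$k2 * y[3] - (p$k1 + rt$g) * y[4]
    list(c(dM, dMp, dAMp, dAM))
  }
  deSolve::lsoda(y = init, times = times, func = rhs, parms = NULL,
                 rtol = 1e-11, atol = 1e-13)
}
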