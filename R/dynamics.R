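# Two-way coupling of wall mechanics and cross-bridge kinetics: a prescribed
# transmural-pressure waveform drives the quasistatic wall equilibrium; the
# rate of change of the mid-wall fiber stretch sets the filament sliding
# velocity; the populations evolve and feed active stress back to the wall.

#' Coupling between tissue stretch rate and filament sliding velocity
#'
#' The shortening velocity of one contractile unit is `L_cu/2` per unit
#' fiber stretch rate (two filament pairs slide per unit), with `L_cu` the
#' contractile-unit reference length expressed in powerstroke-reach units
#' `h`. `L_cu` is the single calibration constant mapping tissue-scale
#' strain rates onto the bond-extension coordinate; its default corresponds
#' to a contractile unit on the order of a hundred powerstrokes long.
#'
#' @param L_cu contractile-unit reference length in multiples of `h`.
#' @param n_series number of contractile units in series per fiber (enters
#'   reporting only; the sliding velocity depends on the per-unit length).
#' @param velocity_sign sign convention: `-1` (default) makes tissue
#'   shortening (negative stretch rate) produce positive sliding velocity
#'   `c`, which transports bridge populations toward smaller extension.
#' @return Object of class `"coupling_parameters"`.
#' @export
coupling_parameters <- function(L_cu = 150, n_series = 1, velocity_sign = -1) {
  stopifnot(L_cu > 0, n_series >= 1, velocity_sign %in% c(-1, 1))
  structure(list(L_cu = L_cu, n_series = n_series,
                 velocity_sign = velocity_sign),
            class = "coupling_parameters")
}

#' Sinusoidal transmural pressure waveform
#'
#' `PTM(t) = PTM0 + dPTM * sin(2 * pi * t / t0)`, the tidal-breathing
#' surrogate applied in the simulated protocols (period `t0 = 5` s in the
#' replicated experiments).
#'
#' @param t time (s), vectorised.
#' @param PTM0 mean transmural pressure (cmH2O).
#' @param dPTM oscillation amplitude (cmH2O).
#' @param t0 oscillation period (s), must be positive.
#' @return Transmural pressure (cmH2O).
#' @export
pressure_waveform <- function(t, PTM0 = 7.5, dPTM = 2.5, t0 = 5) {
  if (!is.numeric(t0) || length(t0) != 1L || t0 <= 0)
    stop("oscillation period 't0' must be positive")
  PTM0 + dPTM * sin(2 * pi * t / t0)
}

#' Filament sliding velocity from fiber stretch rate
#'
#' Linear map `c = velocity_sign * (L_cu / 2) * lambda_f_rate` from the
#' tissue-scale fiber stretch rate to the sliding velocity on the
#' bond-extension grid (x-units per second). With the default sign
#' convention, wall shortening drives populations toward smaller extension.
#'
#' @param lambda_f_rate fiber stretch rate (1/s).
#' @param cp a [coupling_parameters()] object.
#' @return Sliding velocity `c` (x-units/s).
#' @export
sliding_velocity <- function(lambda_f_rate, cp = coupling_parameters()) {
  stopifnot(inherits(cp, "coupling_parameters"))
  if (!all(is.finite(lambda_f_rate)))
    stop("fiber stretch rate must be finite")
  cp$velocity_sign * (cp$L_cu / 2) * lambda_f_rate
}

#' Bundle of model components driving a dynamic simulation
#'
#' @param geom an [airway_geometry()] object.
#' @param mat a [material_parameters()] object.
#' @param rates a [rate_parameters()] object.
#' @param cp a [coupling_parameters()] object.
#' @param beta,kappa force scaling, see [active_stress()].
#' @param PTM0,dPTM,t0 waveform parameters, see [pressure_waveform()].
#' @param dt mechanics time step (s); kinetics sub-step automatically.
#' @return Object of class `"airway_model"` (plain list).
#' @export
airway_model <- function(geom = airway_geometry(),
                         mat = material_parameters(),
                         rates = rate_parameters(),
                         cp = coupling_parameters(),
                         beta = 100, kappa = default_kappa(),
                         PTM0 = 7.5, dPTM = 2.5, t0 = 5, dt = 0.01) {
  stopifnot(dt > 0)
  structure(list(geom = geom, mat = mat, rates = rates, cp = cp,
                 beta = beta, kappa = kappa,
                 PTM0 = PTM0, dPTM = dPTM, t0 = t0, dt = dt),
            class = "airway_model")
}

# isometric-scale active stress from a population snapshot; the mid-wall
# force-length overlap factor is applied inside the wall balance
.model_active <- function(model, pop) {
  active_stress(pop, beta = model$beta, kappa = model$kappa)$A
}

#' Initial (prestressed, unactivated) dynamic state
#'
#' Solves the passive equilibrium at `PTM0` with fully detached populations
#' and zero sliding velocity: the baseline state `B` of the simulated
#' protocols.
#'
#' @param model an [airway_model()] object.
#' @return Object of class `"dynamic_state"`: list with `t`, `airway`
#'   (an `airway_state`), `populations`, `c`, `lambda_f`.
#' @export
initial_state <- function(model) {
  pop <- xb_populations(model$rates)
  st <- equilibrium_radius(model$PTM0, model$geom, model$mat, A = 0)
  structure(list(t = 0, airway = st, populations = pop, c = 0,
                 lambda_f = st$lambda_mid),
            class = "dynamic_state")
}

#' Advance the coupled airway model by one time step
#'
#' Operator-splitting update: (1) evaluate the pressure waveform at
#' `t + dt`; (2) advance the cross-bridge populations with the sliding
#' velocity of the step; (3) recompute the active stress; (4) re-solve the
#' quasistatic wall equilibrium; (5) set the sliding velocity from the
#' change of the mid-wall fiber stretch over the step.
#'
#' In smooth regimes the populations are advanced with the velocity carried
#' over from the previous step (explicit coupling). When that produces a
#' large velocity change - as when the elastic wall would otherwise snap
#' instantaneously between equilibrium branches - the step is re-solved
#' implicitly: the new radius is found such that the wall equilibrium holds
#' with the active stress produced by the populations advected at the very
#' sliding velocity implied by that radius change. This restores the
#' force-velocity feedback that limits how fast the muscle can actually
#' shorten or yield, which an inertialess elastic wall cannot provide.
#' Deterministic.
#'
#' @param state a `"dynamic_state"` (see [initial_state()]).
#' @param model an [airway_model()] object.
#' @param dt time step (s); defaults to `model$dt`.
#' @param PTM_fun optional override `function(t)` for the pressure waveform.
#' @param c_tol velocity change (x-units/s) above which the implicit
#'   coupling is used.
#' @return The advanced `"dynamic_state"`.
#' @export
step_dynamics <- function(state, model, dt = model$dt, PTM_fun = NULL,
                          c_tol = 0.02) {
  if (dt <= 0) stop("'dt' must be positive")
  t_new <- state$t + dt
  PTM <- if (is.null(PTM_fun))
    pressure_waveform(t_new, model$PTM0, model$dPTM, model$t0)
  else PTM_fun(t_new)
  geom <- model$geom; mat <- model$mat
  lam_old <- state$lambda_f
  c_of_ra <- function(ra)
    sliding_velocity((.lambda_mid(ra, geom) - lam_old) / dt, model$cp)

  # explicit attempt with the carried-over velocity
  pop <- advance_populations(state$populations, model$rates, state$c, dt)
  A <- .model_active(model, pop)
  st <- tryCatch(
    equilibrium_radius(PTM, geom, mat, A = A, ra_guess = state$airway$ra),
    error = function(e)
      stop("equilibrium solve failed at t = ", signif(t_new, 6), " s: ",
           conditionMessage(e)))
  c_new <- c_of_ra(st$ra)

  if (abs(c_new - state$c) > c_tol) {
    # implicit velocity-consistent step: residual of the wall balance with
    # the active stress generated at the sliding velocity implied by ra
    quad <- .wall_quad(geom)
    g <- function(ra) {
      cc <- c_of_ra(ra)
      pp <- advance_populations(state$populations, model$rates, cc, dt)
      AA <- .model_active(model, pp)
      .eq_resid(ra, PTM, geom, mat, AA, 0, quad)
    }
    gs <- function(ra) tryCatch(g(ra), error = function(e) NA_real_)
    ra0 <- state$airway$ra
    f0 <- gs(ra0)
    if (!is.na(f0) && f0 != 0) {
      dir <- if (f0 > 0) -1 else 1
      w <- 0.002 * geom$Ra
      prev <- ra0; fprev <- f0; hit <- FALSE
      repeat {
        cand <- ra0 + dir * w
        if (cand <= 0.02 * geom$Ra || cand >= 4 * geom$Ra) break
        fc <- gs(cand)
        if (!is.na(fc) && fprev * fc <= 0) { hit <- TRUE; break }
        if (!is.na(fc)) { prev <- cand; fprev <- fc }
        w <- 1.6 * w
      }
      if (hit) {
        root <- stats::uniroot(g, lower = min(prev, cand),
                               upper = max(prev, cand),
                               tol = 1e-10 * geom$Ra)$root
        c_new <- c_of_ra(root)
        pop <- advance_populations(state$populations, model$rates, c_new, dt)
        A <- .model_active(model, pop)
        st <- .make_airway_state(root, PTM, geom, mat, A, 0, g(root))
      }
    }
  }
  structure(list(t = t_new, airway = st, populations = pop, c = c_new,
                 lambda_f = st$lambda_mid),
            class = "dynamic_state")
}

#' Integrate one protocol segment until the oscillatory state is stable
#'
#' Runs the coupled model under fixed `(k1, dPTM)` until the end-of-cycle
#' lumen radius changes by less than `tol` (relative) between successive
#' periods, or until `duration` is reached. For static segments
#' (`dPTM = 0`) the same cycle-to-cycle criterion applies to the creeping
#' radius. If the cycle-to-cycle change is still growing when `duration` is
#' reached the series is flagged unstable but returned.
#'
#' @param state starting `"dynamic_state"`.
#' @param model an [airway_model()] object.
#' @param k1 MLCK rate for this segment (1/s).
#' @param dPTM oscillation amplitude for this segment (cmH2O).
#' @param duration maximum segment length (s); should cover at least three
#'   periods.
#' @param tol relative end-of-cycle radius change declaring stability.
#' @param min_cycles minimum number of periods before stability may be
#'   declared.
#' @param sample_every store every n-th step in the returned series.
#' @return List with `series` (a `data.frame`: `t`, `PTM`, `ra`, `ra_norm`,
#'   `thickness`, `A`, `F_unit`, `c`, `lambda_f`), `state` (final
#'   `dynamic_state`), `stable` (logical), `cycles` (periods run).
#' @export
run_until_stable <- function(state, model, k1, dPTM,
                             duration = 720, tol = 1e-5,
                             min_cycles = 3, sample_every = 1L) {
  stopifnot(duration >= 3 * model$t0)
  m <- model
  m$rates$k1 <- k1
  m$dPTM <- dPTM
  dt <- m$dt
  steps_per_cycle <- round(m$t0 / dt)
  if (abs(steps_per_cycle * dt - m$t0) > 1e-9 * m$t0)
    dt <- m$t0 / steps_per_cycle   # commensurate step so cycles close exactly
  n_cycles_max <- ceiling(duration / m$t0)
  t_offset <- state$t

  n_max <- n_cycles_max * (steps_per_cycle %/% sample_every)
  rec <- matrix(NA_real_, nrow = n_max, ncol = 8)
  colnames(rec) <- c("t", "PTM", "ra", "thickness", "A", "F_unit", "c",
                     "lambda_f")
  filled <- 0L
  PTM_fun <- function(t) pressure_waveform(t - t_offset, m$PTM0, m$dPTM, m$t0)

  ra_end_prev <- state$airway$ra
  change_prev <- Inf
  stable <- FALSE
  grew <- FALSE
  cyc <- 0
  for (cyc in seq_len(n_cycles_max)) {
    for (s in seq_len(steps_per_cycle)) {
      state <- step_dynamics(state, m, dt = dt, PTM_fun = PTM_fun)
      if ((s %% sample_every) == 0L) {
        filled <- filled + 1L
        rec[filled, ] <- c(state$t, state$airway$PTM, state$airway$ra,
                           state$airway$thickness, state$airway$A,
                           state$airway$A / m$beta, state$c, state$lambda_f)
      }
    }
    change <- abs(state$airway$ra - ra_end_prev) / m$geom$Ra
    ra_end_prev <- state$airway$ra
    if (cyc >= min_cycles && change < tol) { stable <- TRUE; break }
    grew <- cyc > min_cycles && change > 2 * change_prev && change > 10 * tol
    change_prev <- change
  }
  if (!stable && grew)
    warning("run_until_stable: oscillation amplitude still growing at the ",
            "end of the segment")
  rec <- rec[seq_len(filled), , drop = FALSE]
  series <- data.frame(t = rec[, "t"], PTM = rec[, "PTM"], ra = rec[, "ra"],
                       ra_norm = rec[, "ra"] / m$geom$Ra,
                       thickness = rec[, "thickness"],
                       A = rec[, "A"], F_unit = rec[, "F_unit"],
                       c = rec[, "c"], lambda_f = rec[, "lambda_f"])
  class(series) <- c("airway_ts", "data.frame")
  list(series = series, state = state, stable = stable, cycles = cyc)
}

#' Extract the final full cycle of a time series as a pressure-radius loop
#'
#' @param series an `"airway_ts"` data frame from [run_until_stable()].
#' @param t0 oscillation period (s).
#' @return `data.frame` with the samples of the last complete period.
#' @export
final_cycle <- function(series, t0 = 5) {
  t_end <- series$t[nrow(series)]
  sel <- series$t > t_end - t0 + 1e-9
  out <- series[sel, , drop = FALSE]
  if (nrow(out) < 3) stop("insufficient samples for a full cycle")
  out
}
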