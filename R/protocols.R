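# The two experimental protocols replicated by the model, the remodeling
# (wall-thickening) variant, and the summary metrics: end-of-oscillation
# radius and thickness (percent of baseline), strain amplitude, and
# pressure-radius loop statistics.

#' Protocol specification
#'
#' A staged schedule of `(k1, dPTM, duration)` applied about a fixed mean
#' transmural pressure. Use [protocol1_spec()] and [protocol2_spec()] for
#' the built-in protocols.
#'
#' @param name protocol label.
#' @param PTM0 mean transmural pressure (cmH2O).
#' @param stages `data.frame` with columns `k1` (1/s), `dPTM` (cmH2O),
#'   `duration` (s).
#' @param g1 latch-bridge detachment coefficient (1/s).
#' @param chi undeformed wall thickness (length units of `Ra`).
#' @param beta filament-scaling parameter.
#' @return Object of class `"protocol_spec"`.
#' @export
protocol_spec <- function(name, PTM0, stages, g1 = 0.1, chi = 0.3,
                          beta = 100) {
  stopifnot(is.data.frame(stages),
            all(c("k1", "dPTM", "duration") %in% names(stages)),
            all(stages$duration > 0), all(stages$k1 >= 0),
            all(stages$dPTM >= 0))
  structure(list(name = name, PTM0 = PTM0, stages = stages, g1 = g1,
                 chi = chi, beta = beta),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("%s: PTM0 = %g cmH2O, g1 = %g /s, chi = %g Ra, beta = %g\n",
              x$name, x$PTM0, x$g1, x$chi, x$beta))
  print(x$stages)
  invisible(x)
}

#' Protocol 1: increasing agonist at fixed oscillation amplitude
#'
#' Mean pressure 7.5 cmH2O; three stages of increasing MLCK rate
#' `k1 = 0.005, 0.025, 0.05` per second, nominally 12 minutes each, with
#' either static pressure (`dPTM = 0`) or tidal oscillations
#' (`dPTM = 2.5` cmH2O).
#'
#' @param dPTM oscillation amplitude (cmH2O): 0 (static arm) or 2.5.
#' @param stage_duration stage length (s); the nominal 720 s can be
#'   shortened for desk-scale runs because [run_until_stable()] stops once
#'   the oscillatory state is stable.
#' @param remodeled use the thickened wall (`chi = 0.45`) instead of 0.3.
#' @param g1 latch detachment coefficient (1/s).
#' @return A `"protocol_spec"`.
#' @export
protocol1_spec <- function(dPTM = 2.5, stage_duration = 720,
                           remodeled = FALSE, g1 = 0.1) {
  protocol_spec("Protocol 1", PTM0 = 7.5,
                stages = data.frame(k1 = c(0.005, 0.025, 0.05),
                                    dPTM = dPTM,
                                    duration = stage_duration),
                g1 = g1, chi = if (remodeled) 0.45 else 0.3)
}

#' Protocol 2: increasing oscillation amplitude at fixed agonist
#'
#' Mean pressure 5 cmH2O; an initial static contraction stage
#' (`k1 = 0.025`, nominally 15 min), then oscillation stages of amplitude
#' 1.25, 2.5 and 5 cmH2O (15 min each) at the same agonist level.
#'
#' @param g1 latch detachment coefficient (1/s): 0.1 (easily detaching
#'   latch bridges) or 0.01.
#' @param stage_duration stage length (s); nominal 900 s.
#' @param remodeled use the thickened wall (`chi = 0.45`).
#' @return A `"protocol_spec"`.
#' @export
protocol2_spec <- function(g1 = 0.1, stage_duration = 900,
                           remodeled = FALSE) {
  protocol_spec("Protocol 2", PTM0 = 5,
                stages = data.frame(k1 = 0.025,
                                    dPTM = c(0, 1.25, 2.5, 5),
                                    duration = stage_duration),
                g1 = g1, chi = if (remodeled) 0.45 else 0.3)
}

#' Strain amplitude of an oscillation cycle
#'
#' `Delta_r = (ra_max - ra_min) / (2 * Ra_base)` over the selected cycles,
#' where `Ra_base` is the baseline radius (unactivated lumen radius at the
#' protocol's mean pressure).
#'
#' @param series an `"airway_ts"` data frame covering at least one full
#'   cycle.
#' @param Ra_base baseline lumen radius (same length unit as `series$ra`).
#' @param t0 oscillation period (s).
#' @param cycles `"final"` (default) for the last full cycle, or `"first2"`
#'   for the first two cycles (used for the baseline and contracted probe
#'   states).
#' @return Strain amplitude (dimensionless; multiply by 100 for percent).
#' @export
strain_amplitude <- function(series, Ra_base, t0 = 5, cycles = "final") {
  stopifnot(nrow(series) > 2)
  t_start <- series$t[1]; t_end <- series$t[nrow(series)]
  if (t_end - t_start < t0 - 1e-9)
    stop("insufficient data: series shorter than one oscillation period")
  sel <- if (identical(cycles, "final"))
    series$t > t_end - t0 + 1e-9
  else if (identical(cycles, "first2"))
    series$t <= t_start + 2 * t0 + 1e-9
  else stop("cycles must be 'final' or 'first2'")
  ra <- series$ra[sel]
  (max(ra) - min(ra)) / (2 * Ra_base)
}

#' Metrics of a pressure-radius loop
#'
#' @param loop `data.frame` with columns `PTM` and `ra` (or `ra_norm`)
#'   sampling one closed cycle.
#' @param closure_tol relative gap between first and last sample above
#'   which the loop is flagged open (warning; metrics still computed).
#' @return List with `mean_radius`, `area` (absolute enclosed area by the
#'   shoelace rule, cmH2O x radius units), and `dynamic_compliance`
#'   (radius range / pressure range; `NA` for a degenerate static loop).
#' @export
loop_metrics <- function(loop, closure_tol = 0.02) {
  r <- if ("ra" %in% names(loop)) loop$ra else loop$ra_norm
  P <- loop$PTM
  stopifnot(length(r) >= 3)
  gap <- abs(r[1] - r[length(r)]) / max(abs(r))
  if (gap > closure_tol)
    warning("loop_metrics: loop not closed (relative gap ",
            signif(gap, 3), "); metrics computed on raw samples")
  n <- length(r)
  i2 <- c(2:n, 1)
  area <- abs(sum(P * r[i2] - P[i2] * r) / 2)
  dP <- diff(range(P))
  list(mean_radius = mean(r), area = area,
       dynamic_compliance = if (dP > 0) diff(range(r)) / dP else NA_real_)
}

#' Radially outward wall thickening (remodeling)
#'
#' Returns the geometry of a remodeled airway with increased undeformed
#' wall thickness, keeping the lumen radius and the ASM/collagen fiber
#' densities unchanged, so total contractile and collagen content scale
#' with wall volume.
#'
#' @param geom an [airway_geometry()] object.
#' @param chi_new new undeformed thickness, `>= geom$chi`.
#' @return A new `"airway_geometry"`.
#' @export
apply_remodeling <- function(geom, chi_new) {
  stopifnot(inherits(geom, "airway_geometry"))
  if (chi_new < geom$chi)
    stop("remodeling must not decrease wall thickness (chi_new < chi)")
  airway_geometry(Ra = geom$Ra, chi = chi_new, Rp = geom$Rp)
}

#' Run a staged protocol
#'
#' Initialises the prestressed baseline state at `spec$PTM0`, then chains
#' [run_until_stable()] across the protocol stages, carrying the dynamic
#' state over. Records per-stage summary metrics in the style of the
#' replicated experiments: end-of-stage radius and wall thickness as
#' percent of baseline (sampled at the completion of the final oscillation,
#' when `PTM = PTM0`), and the strain amplitude of the final cycle. For
#' Protocol-2-style runs the contracted state `C` is the end of the first
#' (static) stage, and the strain-amplitude probes for states `B` and `C`
#' use two cycles of `dPTM = 1.25` cmH2O oscillation.
#'
#' @param spec a [protocol_spec()].
#' @param model an [airway_model()]; geometry/`g1`/`beta`/`PTM0` are
#'   overridden from the spec.
#' @param tol,dt stability tolerance and time step passed to the integrator.
#' @param stages optional subset of stage indices to run (in order).
#' @param probe_amplitudes compute `B`/`C` strain-amplitude probes when the
#'   first stage is static (Protocol-2 style).
#' @param sample_every store every n-th step of the trajectories.
#' @return Object of class `"protocol_result"`: list with `spec`, `summary`
#'   (per-stage `data.frame`), `series` (list of per-stage `airway_ts`),
#'   `loops` (list of final-cycle loops), `baseline` (radius and thickness),
#'   `B`, `C` (probe metrics or `NULL`), `model`.
#' @export
run_protocol <- function(spec, model = airway_model(), tol = 1e-5,
                         dt = model$dt, stages = NULL,
                         probe_amplitudes = TRUE, sample_every = 1L) {
  stopifnot(inherits(spec, "protocol_spec"))
  m <- model
  m$geom <- airway_geometry(Ra = m$geom$Ra, chi = spec$chi * m$geom$Ra,
                            Rp = m$geom$Rp)
  m$rates$g1 <- spec$g1
  m$rates$g_neg <- 20 * spec$g1
  m$beta <- spec$beta
  m$PTM0 <- spec$PTM0
  m$dt <- dt

  state <- initial_state(m)
  Ra_base <- state$airway$ra
  th_base <- state$airway$thickness

  B <- NULL
  if (probe_amplitudes) {
    pb <- run_until_stable(state, m, k1 = 0, dPTM = 1.25,
                           duration = 3 * m$t0, tol = 0, min_cycles = 2,
                           sample_every = sample_every)
    B <- list(strain_amplitude = strain_amplitude(pb$series, Ra_base,
                                                  t0 = m$t0,
                                                  cycles = "first2"),
              radius_pct = 100, thickness_pct = 100)
  }

  idx <- if (is.null(stages)) seq_len(nrow(spec$stages)) else stages
  n_st <- length(idx)
  summary <- data.frame(stage = integer(n_st), k1 = numeric(n_st),
                        dPTM = numeric(n_st),
                        radius_pct = numeric(n_st),
                        thickness_pct = numeric(n_st),
                        strain_amplitude_pct = numeric(n_st),
                        stable = logical(n_st))
  series <- vector("list", n_st); loops <- vector("list", n_st)
  C <- NULL
  for (j in seq_along(idx)) {
    sg <- spec$stages[idx[j], ]
    res <- tryCatch(
      run_until_stable(state, m, k1 = sg$k1, dPTM = sg$dPTM,
                       duration = sg$duration, tol = tol,
                       sample_every = sample_every),
      error = function(e) {
        stop("protocol stage ", idx[j], " (k1 = ", sg$k1, ", dPTM = ",
             sg$dPTM, ") failed: ", conditionMessage(e))
      })
    state <- res$state
    summary$stage[j] <- idx[j]
    summary$k1[j] <- sg$k1
    summary$dPTM[j] <- sg$dPTM
    summary$radius_pct[j] <- 100 * state$airway$ra / Ra_base
    summary$thickness_pct[j] <- 100 * state$airway$thickness / th_base
    summary$strain_amplitude_pct[j] <-
      if (sg$dPTM > 0)
        100 * strain_amplitude(res$series, Ra_base, t0 = m$t0)
      else 0
    summary$stable[j] <- res$stable
    series[[j]] <- res$series
    loops[[j]] <- if (sg$dPTM > 0) {
      fc <- final_cycle(res$series, t0 = m$t0)
      fc[, c("t", "PTM", "ra", "ra_norm")]
    } else NULL

    if (probe_amplitudes && j == 1L && sg$dPTM == 0) {
      pc <- run_until_stable(state, m, k1 = sg$k1, dPTM = 1.25,
                             duration = 3 * m$t0, tol = 0, min_cycles = 2,
                             sample_every = sample_every)
      C <- list(strain_amplitude = strain_amplitude(pc$series, Ra_base,
                                                    t0 = m$t0,
                                                    cycles = "first2"),
                radius_pct = 100 * state$airway$ra / Ra_base,
                thickness_pct = 100 * state$airway$thickness / th_base)
      # probe is diagnostic only: protocol continues from the pre-probe state
    }
  }
  structure(list(spec = spec, summary = summary, series = series,
                 loops = loops,
                 baseline = list(ra = Ra_base, thickness = th_base),
                 B = B, C = C, model = m),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(x$spec$name, "-", nrow(x$summary), "stage(s); baseline ra =",
      signif(x$baseline$ra, 5), "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write protocol summary and loops as CSV files
#'
#' Writes `<prefix>_summary.csv` (one row per stage, mirroring the
#' end-of-stage radius, thickness and strain-amplitude panels) and
#' `<prefix>_loop_stage<j>.csv` for each oscillatory stage.
#'
#' @param result a `"protocol_result"` from [run_protocol()].
#' @param prefix output path prefix.
#' @return Paths written, invisibly.
#' @export
write_protocol_result <- function(result, prefix) {
  paths <- paste0(prefix, "_summary.csv")
  utils::write.csv(result$summary, paths[1], row.names = FALSE)
  for (j in seq_along(result$loops)) {
    if (is.null(result$loops[[j]])) next
    p <- paste0(prefix, "_loop_stage", result$summary$stage[j], ".csv")
    utils::write.csv(result$loops[[j]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
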