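# Seeded generators of synthetic datasets with the structure the fitting
# and metrics code consumes, so the whole pipeline is testable without any
# external data.

# run expr with a local, restorable RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate a synthetic pressure-radius dataset
#'
#' Evaluates the model's static pressure-radius curve at the requested
#' activation level and adds multiplicative Gaussian noise to the radii,
#' emulating the measured quasistatic curves of isolated intact airways.
#' Fixing the seed makes the output bit-reproducible.
#'
#' @param geom,mat,rates model components (defaults as in [static_curve()]).
#' @param ptm pressure grid (cmH2O).
#' @param k1 activation level (1/s); 0 (default) gives a passive dataset.
#' @param noise_sd relative (multiplicative) radius noise, default 0.02.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param beta,kappa force scaling, see [active_stress()].
#' @return A [pr_dataset()] with the generating parameters attached as
#'   attribute `"truth"`.
#' @export
generate_pr_dataset <- function(geom = airway_geometry(),
                                mat = material_parameters(),
                                rates = rate_parameters(),
                                ptm = seq(-15, 30, by = 2.5),
                                k1 = 0, noise_sd = 0.02, seed = 1,
                                beta = 100, kappa = default_kappa()) {
  stopifnot(noise_sd >= 0)
  cv <- static_curve(levels = k1, geom = geom, mat = mat, rates = rates,
                     ptm = ptm, beta = beta, kappa = kappa)
  r <- cv$ra_norm
  noisy <- .with_seed(seed, r * (1 + stats::rnorm(length(r), 0, noise_sd)))
  d <- pr_dataset(cv$PTM, noisy,
                  label = if (k1 > 0) "activated" else "passive",
                  source = sprintf("synthetic (seed %s)", seed))
  attr(d, "truth") <- list(mu = mat$mu, C1 = mat$C1, C2 = mat$C2, k1 = k1,
                           noise_sd = noise_sd, seed = seed)
  d
}

#' Generate a short coupled-oscillation fixture
#'
#' Runs the fully coupled model for a fixed small number of pressure
#' cycles and returns the sampled trajectory: a deterministic fixture for
#' the metrics code (strain amplitude, loop area).
#'
#' @param model an [airway_model()] object.
#' @param k1 activation level (1/s).
#' @param dPTM oscillation amplitude (cmH2O).
#' @param n_cycles number of pressure cycles (default 3).
#' @param sample_every store every n-th step.
#' @return An `"airway_ts"` data frame (see [run_until_stable()]).
#' @export
generate_oscillation_fixture <- function(model = airway_model(), k1 = 0,
                                         dPTM = 2.5, n_cycles = 3,
                                         sample_every = 1L) {
  st <- initial_state(model)
  res <- run_until_stable(st, model, k1 = k1, dPTM = dPTM,
                          duration = n_cycles * model$t0, tol = 0,
                          min_cycles = n_cycles,
                          sample_every = sample_every)
  res$series
}
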