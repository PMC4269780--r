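# Fitting passive constitutive parameters to pressure-radius data, and
# logistic smoothing of experimental-style curves with stiffness extraction.

#' Pressure-radius dataset
#'
#' @param PTM transmural pressures (cmH2O).
#' @param ra_norm lumen radii normalized by the undeformed radius.
#' @param label `"passive"` or `"activated"`.
#' @param source free-text provenance tag.
#' @return Object of class `"pr_dataset"` (a `data.frame` with attributes).
#' @export
pr_dataset <- function(PTM, ra_norm, label = "passive", source = "unknown") {
  stopifnot(length(PTM) == length(ra_norm), all(is.finite(PTM)),
            all(is.finite(ra_norm)), all(ra_norm > 0))
  label <- match.arg(label, c("passive", "activated"))
  d <- data.frame(PTM = PTM, ra_norm = ra_norm)
  attr(d, "label") <- label
  attr(d, "source") <- source
  class(d) <- c("pr_dataset", "data.frame")
  d
}

#' Read a pressure-radius dataset from CSV
#'
#' Expects columns `PTM`, `ra_norm` and optionally `label`.
#'
#' @param path CSV file path.
#' @return A [pr_dataset()].
#' @export
read_pr_dataset <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("PTM", "ra_norm") %in% names(d)))
    stop("CSV must contain columns 'PTM' and 'ra_norm'")
  lab <- if ("label" %in% names(d)) as.character(d$label[1]) else "passive"
  pr_dataset(d$PTM, d$ra_norm, label = lab, source = path)
}

# model-predicted normalized radii on the data's pressure grid for candidate
# passive parameters; warm-started sweep in pressure order
.passive_curve_at <- function(PTM, mu, C1, C2, geom, base_mat) {
  mat <- base_mat
  mat$mu <- mu; mat$C1 <- C1; mat$C2 <- C2
  ord <- order(PTM)
  out <- numeric(length(PTM))
  guess <- NULL
  for (i in ord) {
    st <- equilibrium_radius(PTM[i], geom, mat, A = 0, ra_guess = guess)
    out[i] <- st$ra / geom$Ra
    guess <- st$ra
  }
  out
}

#' Fit passive wall constitutive parameters to pressure-radius data
#'
#' Nonlinear least squares of the model's passive (zero-activation) static
#' pressure-radius curve against measured data, over `(mu, C1, C2)`.
#' Residuals are taken on the normalized radius (the measured quantity),
#' with uniform weights. A deterministic multi-start strategy is used: the
#' residual norm is evaluated on a 3 x 3 x 3 log-spaced grid of starting
#' values around `start`, and Levenberg-Marquardt refinement
#' ([minpack.lm::nls.lm]) is run from the most promising starts.
#' `mu` and `C1` are optimised on the log scale (positivity); `C2` is
#' bounded below by zero, so a non-stiffening truth (`C2 = 0`) is
#' recoverable at the boundary.
#'
#' @param data a [pr_dataset()] with passive data spanning negative and
#'   positive pressures; at least 5 records.
#' @param geom an [airway_geometry()] object.
#' @param start named list/vector of starting values (`mu`, `C1`, `C2`).
#' @param base_mat template [material_parameters()] supplying the fixed
#'   parameters (slack stretch, overlap window, ...).
#' @param n_refine number of grid starts refined with full optimisation.
#' @return Object of class `"material_fit"`: list with `mat` (fitted
#'   [material_parameters()]), `estimates`, `residual_norm`, `converged`,
#'   `n_starts_tried`, `data`.
#' @export
fit_passive_materials <- function(data, geom = airway_geometry(),
                                  start = list(mu = 20, C1 = 2, C2 = 6),
                                  base_mat = material_parameters(),
                                  n_refine = 3) {
  stopifnot(inherits(data, "pr_dataset"))
  if (nrow(data) < 5)
    stop("need at least 5 records to fit passive materials")
  if (min(data$PTM) >= 0 || max(data$PTM) <= 0)
    warning("passive data should span both negative and positive PTM; ",
            "the fit may be poorly constrained")

  resid_fn <- function(par) {
    mu <- exp(par[1]); C1 <- exp(par[2]); C2 <- par[3]
    pred <- tryCatch(
      .passive_curve_at(data$PTM, mu, C1, C2, geom, base_mat),
      error = function(e) rep(NA_real_, nrow(data)))
    r <- pred - data$ra_norm
    r[!is.finite(r)] <- 10
    r
  }

  # deterministic 3x3x3 multi-start grid, log-spaced around `start`
  f <- c(0.4, 1, 2.5)
  grid <- expand.grid(mu = start$mu * f, C1 = start$C1 * f,
                      C2 = pmax(start$C2 * f, 1e-3))
  grid_par <- cbind(log(grid$mu), log(grid$C1), grid$C2)
  norms <- apply(grid_par, 1, function(p) sum(resid_fn(p)^2))
  best_idx <- order(norms)[seq_len(min(n_refine, nrow(grid)))]

  best <- NULL
  for (i in best_idx) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = grid_par[i, ], fn = resid_fn,
                         lower = c(-10, -10, 0), upper = c(10, 10, 200),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sum(fit$fvec^2)
    if (is.null(best) || rn < best$rn)
      best <- list(fit = fit, rn = rn)
  }
  if (is.null(best))
    stop("fit failure: no start converged; best grid residual norm ",
         signif(min(norms), 4))

  par <- best$fit$par
  est <- c(mu = exp(par[1]), C1 = exp(par[2]), C2 = par[3])
  mat <- base_mat
  mat$mu <- est[["mu"]]; mat$C1 <- est[["C1"]]; mat$C2 <- est[["C2"]]
  structure(list(mat = mat, estimates = est,
                 residual_norm = best$rn,
                 converged = best$fit$info %in% 1:4,
                 n_starts_tried = length(best_idx), data = data),
            class = "material_fit")
}

#' @export
print.material_fit <- function(x, ...) {
  cat(sprintf("passive material fit: mu = %.4g, C1 = %.4g, C2 = %.4g\n",
              x$estimates[["mu"]], x$estimates[["C1"]], x$estimates[["C2"]]))
  cat(sprintf("  residual norm %.3g on %d points; converged: %s\n",
              x$residual_norm, nrow(x$data), x$converged))
  invisible(x)
}

#' Write a material fit as a JSON config fragment
#'
#' @param fit a `"material_fit"`.
#' @param path output path.
#' @return The list written, invisibly.
#' @export
write_material_fit <- function(fit, path) {
  out <- list(mu = unname(fit$estimates[["mu"]]),
              C1 = unname(fit$estimates[["C1"]]),
              C2 = unname(fit$estimates[["C2"]]),
              residual_norm = fit$residual_norm,
              converged = fit$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Fit a logistic curve to pressure-radius data
#'
#' Least-squares fit of
#' `r(P) = r_min + (r_max - r_min) / (1 + exp(-(P - P_half)/slope_scale))`,
#' the smooth sigmoid used to summarise experimental pressure-radius
#' relationships before extracting stiffness.
#'
#' @param data a [pr_dataset()] with at least 5 records.
#' @return Object of class `"logistic_fit"`: list with `r_min`, `r_max`,
#'   `P_half`, `slope_scale`, `residual_norm`, `converged`.
#' @export
fit_logistic <- function(data) {
  stopifnot(inherits(data, "pr_dataset"))
  if (nrow(data) < 5) stop("need at least 5 records for a logistic fit")
  d <- data[order(data$PTM), ]
  if (stats::cor(d$PTM, d$ra_norm) < 0)
    stop("data are decreasing in pressure; a logistic radius-pressure fit ",
         "expects inflation with increasing PTM (r_max > r_min)")
  r_rng <- range(d$ra_norm)
  start <- c(r_min = r_rng[1], r_max = r_rng[2],
             P_half = stats::median(d$PTM),
             slope_scale = max(diff(range(d$PTM)) / 8, 0.5))
  fn <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + exp(-(d$PTM - p[3]) / p[4]))
    pred - d$ra_norm
  }
  fit <- minpack.lm::nls.lm(par = start, fn = fn,
                            lower = c(0, 0, -100, 1e-3),
                            upper = c(10, 10, 100, 100),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  if (p[["r_max"]] < p[["r_min"]])
    warning("fitted r_max < r_min: curve orientation inverted")
  structure(list(r_min = p[["r_min"]], r_max = p[["r_max"]],
                 P_half = p[["P_half"]], slope_scale = p[["slope_scale"]],
                 residual_norm = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: r in [%.4g, %.4g], P_half = %.4g cmH2O, slope scale = %.4g cmH2O\n",
              x$r_min, x$r_max, x$P_half, x$slope_scale))
  invisible(x)
}

#' Evaluate a fitted logistic curve
#'
#' @param fit a `"logistic_fit"`.
#' @param PTM pressures (cmH2O), vectorised.
#' @return Normalized radii.
#' @export
predict_logistic <- function(fit, PTM) {
  fit$r_min + (fit$r_max - fit$r_min) /
    (1 + exp(-(PTM - fit$P_half) / fit$slope_scale))
}

#' Effective stiffness from a fitted logistic curve
#'
#' The analytic derivative of the logistic is inverted pointwise:
#' `stiffness(P) = 1 / r'(P)`. By the symmetry of the logistic the
#' stiffness is minimal exactly at `P_half` and diverges in both
#' saturating tails.
#'
#' @param fit a `"logistic_fit"`.
#' @param ptm pressure grid (cmH2O).
#' @return A `"stiffness_curve"` data frame with `k1 = NA` marker column.
#' @export
stiffness_from_fit <- function(fit, ptm = seq(-15, 30, by = 0.25)) {
  z <- exp(-(ptm - fit$P_half) / fit$slope_scale)
  dr <- (fit$r_max - fit$r_min) * z / (fit$slope_scale * (1 + z)^2)
  res <- data.frame(k1 = NA_real_, PTM = ptm, stiffness = 1 / dr)
  class(res) <- c("stiffness_curve", "data.frame")
  res
}
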