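# Huxley-Hai-Murphy (HHM) cross-bridge kinetics: four myosin states resolved
# over the bond-extension coordinate x, transported by filament sliding.
#
# States: M   unattached, unphosphorylated
#         Mp  unattached, phosphorylated (via MLCK at rate k1)
#         AMp attached, phosphorylated ("cycling cross-bridge")
#         AM  attached, dephosphorylated ("latch bridge", slow detachment g)
#
# x is measured in multiples of the powerstroke reach h; forces come out in
# kappa*h^2 units, with kappa carrying the single stress-scale calibration.

#' Rate parameters of the HHM cross-bridge scheme
#'
#' Bundles the kinetic constants of the four-state Hai-Murphy scheme together
#' with the coefficients of the strain-dependent Huxley attachment/detachment
#' rate functions. `k1` (MLCK, the agonist surrogate) and `g1` (latch-bridge
#' detachment coefficient) are the two rates varied in the simulated
#' protocols; the remaining constants default to the standard HHM
#' parameterisation used for airway smooth muscle and are all overridable.
#'
#' @param k1 phosphorylation rate via MLCK (1/s); surrogate for agonist
#'   concentration.
#' @param k2 dephosphorylation rate via MLCP (1/s); also converts cycling
#'   cross-bridges AMp into latch bridges AM.
#' @param fp1 peak attachment rate coefficient (1/s); attachment is
#'   `fp1*x/h` on `0 <= x <= h` and zero elsewhere.
#' @param gp_neg detachment rate of cycling bridges for `x < 0` (1/s).
#' @param gp1 detachment slope coefficient of cycling bridges for `x >= 0`
#'   (1/s); detachment is `gp1*x/h`.
#' @param g1 latch-bridge detachment slope coefficient for `x >= 0` (1/s).
#' @param g_neg latch-bridge detachment rate for `x < 0` (1/s); defaults to
#'   `20*g1`, preserving the ratio used for the cycling bridges.
#' @param h powerstroke reach, the natural unit of the bond extension x.
#' @return An object of class `"rate_parameters"`.
#' @export
#' @examples
#' p <- rate_parameters(k1 = 0.025)
#' rate_functions(c(-0.5, 0.5, 1), p)
rate_parameters <- function(k1 = 0.025, k2 = 0.04, fp1 = 0.88, gp_neg = 4.4,
                            gp1 = 0.22, g1 = 0.1, g_neg = 20 * g1, h = 1) {
  p <- list(k1 = k1, k2 = k2, fp1 = fp1, gp_neg = gp_neg, gp1 = gp1,
            g1 = g1, g_neg = g_neg, h = h)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate parameter '", nm, "' must be a finite numeric scalar")
    if (v < 0) stop("rate parameter '", nm, "' must be non-negative")
  }
  if (p$h <= 0) stop("powerstroke reach 'h' must be positive")
  structure(p, class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("HHM rate parameters (1/s):\n")
  cat(sprintf("  k1 = %g  k2 = %g  (phosphorylation cycle)\n", x$k1, x$k2))
  cat(sprintf("  fp1 = %g  gp1 = %g  gp_neg = %g  (cycling bridges)\n",
              x$fp1, x$gp1, x$gp_neg))
  cat(sprintf("  g1 = %g  g_neg = %g  (latch bridges); h = %g\n",
              x$g1, x$g_neg, x$h))
  invisible(x)
}

#' Strain-dependent attachment and detachment rates
#'
#' Piecewise-linear Huxley-type rate functions. Attachment `fp` is nonzero
#' only on the powerstroke range `0 <= x <= h`; the detachment rates `gp`
#' (cycling bridges) and `g` (latch bridges) grow linearly with `x` for
#' `x >= 0` and take constant (fast) values for compressed bridges `x < 0`.
#' Cycling bridges dragged beyond the powerstroke (`x > h`) release
#' rapidly, with slope `fp1 + gp1` - the yield branch of the HHM scheme
#' that lets imposed stretch prune actively cycling cross-bridges; latch
#' bridges keep their slow slope `g1` on all of `x >= 0`, which is what
#' lets contracted, latch-dominated states resist pressure fluctuations.
#'
#' @param x bond extensions (same length unit as `p$h`); vectorised.
#' @param p a [rate_parameters()] object.
#' @return A list with numeric vectors `fp`, `gp`, `g` (1/s).
#' @export
rate_functions <- function(x, p) {
  stopifnot(inherits(p, "rate_parameters"))
  xr <- x / p$h
  fp <- ifelse(xr >= 0 & xr <= 1, p$fp1 * xr, 0)
  gp <- ifelse(xr < 0, p$gp_neg,
               ifelse(xr > 1, (p$fp1 + p$gp1) * xr, p$gp1 * xr))
  g  <- ifelse(xr < 0, p$g_neg, p$g1 * xr)
  list(fp = fp, gp = gp, g = g)
}

#' Construct a cross-bridge population field
#'
#' Creates the four population fractions on a uniform bond-extension grid,
#' initialised to the fully detached, unphosphorylated state (`nM = 1`).
#'
#' @param p a [rate_parameters()] object (supplies the length unit `h`).
#' @param n_x number of grid points (default 241).
#' @param x_range grid extent in multiples of `h` (default `c(-2, 3)`); must
#'   contain the attachment window `[0, h]` with margin.
#' @return An object of class `"xb_populations"`: list with `x` (grid),
#'   `dx`, and fraction vectors `nM`, `nMp`, `nAMp`, `nAM`.
#' @export
xb_populations <- function(p = rate_parameters(), n_x = 241,
                           x_range = c(-2, 3)) {
  stopifnot(n_x >= 11, length(x_range) == 2L, x_range[1] < 0, x_range[2] > 1)
  x <- seq(x_range[1] * p$h, x_range[2] * p$h, length.out = n_x)
  z <- numeric(n_x)
  structure(list(x = x, dx = x[2] - x[1],
                 nM = rep(1, n_x), nMp = z, nAMp = z, nAM = z),
            class = "xb_populations")
}

#' @export
print.xb_populations <- function(x, ...) {
  att <- xb_attached_fraction(x)
  cat(sprintf("cross-bridge populations on %d-point grid [%g, %g]\n",
              length(x$x), min(x$x), max(x$x)))
  cat(sprintf("  attached fraction (integral over x, per h): %.4f\n", att))
  invisible(x)
}

#' Integrated attached fraction over the bond-extension grid
#'
#' @param pop an [xb_populations()] object.
#' @return `integral of (nAMp + nAM) dx` by the trapezoidal rule.
#' @export
xb_attached_fraction <- function(pop) {
  .trapz(pop$x, pop$nAMp + pop$nAM)
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Isometric steady-state cross-bridge populations
#'
#' Solves, independently at each grid point, the four-state kinetic balance
#' with zero sliding velocity. Where the balance is singular (all
#' strain-dependent rates vanish, e.g. exactly at `x = 0`) the attached pool
#' is conserved at its initial value (zero for the default initial
#' composition) and the detached pool is split by the `k1/k2` equilibrium;
#' such points are flagged in the `"singular_x"` attribute and reported via
#' a message.
#'
#' @param p a [rate_parameters()] object.
#' @param pop optional [xb_populations()] template supplying the grid
#'   (default grid otherwise).
#' @param quiet suppress the singular-point message.
#' @return An `xb_populations` object at kinetic steady state.
#' @export
steady_state_populations <- function(p, pop = xb_populations(p),
                                     quiet = FALSE) {
  stopifnot(inherits(p, "rate_parameters"), inherits(pop, "xb_populations"))
  rt <- rate_functions(pop$x, p)
  n <- length(pop$x)
  nM <- numeric(n); nMp <- numeric(n); nAMp <- numeric(n); nAM <- numeric(n)
  singular <- logical(n)

  k1 <- p$k1; k2 <- p$k2
  for (i in seq_len(n)) {
    fp <- rt$fp[i]; gp <- rt$gp[i]; g <- rt$g[i]
    if (k1 == 0 && k2 == 0 && fp == 0) {
      # no reactions at all: initial composition persists
      nM[i] <- pop$nM[i]; nMp[i] <- pop$nMp[i]
      nAMp[i] <- pop$nAMp[i]; nAM[i] <- pop$nAM[i]
      singular[i] <- TRUE
      next
    }
    if (k1 == 0) {
      # no phosphorylation: everything drains to M (detachment via gp, g;
      # if attached rates are zero the attached pool is conserved instead)
      if (gp == 0 && g == 0) {
        att <- pop$nAMp[i] + pop$nAM[i]
        nAMp[i] <- 0; nAM[i] <- att     # k2 converts AMp -> AM
        nM[i] <- 1 - att
        singular[i] <- att > 0 || (fp == 0 && gp == 0 && g == 0)
      } else {
        nM[i] <- 1
      }
      next
    }
    # k1 > 0 from here
    D1 <- (gp + k2) * (k1 + g) - k1 * k2   # = gp*k1 + gp*g + k2*g
    if (fp == 0) {
      if (gp == 0 && g == 0) {
        # singular: attached pool conserved (x = 0 grid point)
        att <- pop$nAMp[i] + pop$nAM[i]
        det <- 1 - att
        nMp[i] <- det * k1 / (k1 + k2); nM[i] <- det - nMp[i]
        nAM[i] <- att * k2 / (k1 + k2); nAMp[i] <- att - nAM[i]
        singular[i] <- TRUE
      } else {
        nMp[i] <- k1 / (k1 + k2); nM[i] <- 1 - nMp[i]
      }
      next
    }
    if (D1 <= 0) {
      # fp > 0 with no attached escape: all mass ends attached
      nAMp[i] <- k1 / (k1 + k2); nAM[i] <- 1 - nAMp[i]
      next
    }
    mp <- 1
    amp <- fp * mp / D1 * (k1 + g)          # from AMp/AM balance pair
    am <- k2 * amp / (k1 + g)
    m <- (k2 * mp + g * am) / k1
    tot <- m + mp + amp + am
    nM[i] <- m / tot; nMp[i] <- mp / tot
    nAMp[i] <- amp / tot; nAM[i] <- am / tot
  }
  if (any(singular) && !quiet)
    message("steady_state_populations: singular kinetic balance at ",
            sum(singular), " grid point(s); conserved composition used there")
  out <- pop
  out$nM <- nM; out$nMp <- nMp; out$nAMp <- nAMp; out$nAM <- nAM
  attr(out, "singular_x") <- pop$x[singular]
  out
}

#' Advance cross-bridge populations under sliding and reaction
#'
#' Integrates the transport-reaction system
#' `dn/dt - c dn/dx = reactions` for all four populations over a time
#' interval `dt`, using first-order upwind finite differences with automatic
#' sub-stepping so that the Courant number is at most one and the fastest
#' reaction loses at most a quarter of a state per sub-step. Populations
#' advected off the grid are absorbed as detached (`nM`), so the pointwise
#' conservation `nM + nMp + nAMp + nAM = 1` is preserved to round-off.
#'
#' @param pop an [xb_populations()] object.
#' @param p a [rate_parameters()] object.
#' @param c sliding velocity in x-units per second; positive values shift
#'   populations toward smaller extension (tissue shortening).
#' @param dt time interval (s), must be positive.
#' @return The advanced `xb_populations` object.
#' @export
advance_populations <- function(pop, p, c, dt) {
  stopifnot(inherits(pop, "xb_populations"), inherits(p, "rate_parameters"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive finite scalar")
  if (!is.finite(c)) stop("sliding velocity 'c' must be finite")

  # the strain-dependent rates depend only on the grid and the parameter
  # set; cache them on the population object across repeated steps
  sig <- c(p$k1, p$k2, p$fp1, p$gp_neg, p$gp1, p$g1, p$g_neg, p$h,
           pop$x[1], pop$dx, length(pop$x))
  rc <- attr(pop, "rate_cache")
  if (is.null(rc) || !identical(rc$sig, sig)) {
    rt <- rate_functions(pop$x, p)
    rc <- list(sig = sig, fp = rt$fp, gp = rt$gp, g = rt$g,
               max_rate = max(p$k1, p$k2 + rt$fp, rt$gp + p$k2,
                              p$k1 + rt$g))
  }
  rt <- rc
  max_rate <- rc$max_rate
  m_adv <- ceiling(abs(c) * dt / pop$dx - 1e-12)
  m_rea <- ceiling(dt * max_rate / 0.25)
  m <- max(1, m_adv, m_rea)
  if (max_rate > 0) {
    # combined positivity bound: Courant number plus reaction loss per
    # sub-step must stay below one (nu = 1 exactly is allowed only in the
    # pure-advection case, where upwind transport is exact)
    m <- max(m, ceiling((abs(c) * dt / pop$dx + dt * max_rate) / 0.9))
  }
  dts <- dt / m
  nu <- c * dts / pop$dx   # Courant number, |nu| <= 1 by construction

  nM <- pop$nM; nMp <- pop$nMp; nAMp <- pop$nAMp; nAM <- pop$nAM
  n <- length(nM)
  k1 <- p$k1; k2 <- p$k2
  fp <- rt$fp; gp <- rt$gp; g <- rt$g
  for (s in seq_len(m)) {
    dM   <- -k1 * nM + k2 * nMp + g * nAM
    dMp  <-  k1 * nM - (k2 + fp) * nMp + gp * nAMp
    dAMp <-  fp * nMp - (gp + k2) * nAMp + k1 * nAM
    dAM  <-  k2 * nAMp - (k1 + g) * nAM
    if (nu > 0) {
      # dn/dt = c dn/dx, information enters from the right; ghost = detached
      nM   <- nM   + nu * (c(nM[-1], 1)   - nM)   + dts * dM
      nMp  <- nMp  + nu * (c(nMp[-1], 0)  - nMp)  + dts * dMp
      nAMp <- nAMp + nu * (c(nAMp[-1], 0) - nAMp) + dts * dAMp
      nAM  <- nAM  + nu * (c(nAM[-1], 0)  - nAM)  + dts * dAM
    } else if (nu < 0) {
      nM   <- nM   + nu * (nM   - c(1, nM[-n]))   + dts * dM
      nMp  <- nMp  + nu * (nMp  - c(0, nMp[-n]))  + dts * dMp
      nAMp <- nAMp + nu * (nAMp - c(0, nAMp[-n])) + dts * dAMp
      nAM  <- nAM  + nu * (nAM  - c(0, nAM[-n]))  + dts * dAM
    } else {
      nM   <- nM   + dts * dM
      nMp  <- nMp  + dts * dMp
      nAMp <- nAMp + dts * dAMp
      nAM  <- nAM  + dts * dAM
    }
  }

  tol <- 1e-6
  lo <- min(nM, nMp, nAMp, nAM); hi <- max(nM, nMp, nAMp, nAM)
  if (lo < -tol || hi > 1 + tol)
    stop("advance_populations: population fractions left [0, 1] beyond ",
         "tolerance; reduce dt or check parameters")
  out <- pop
  if (lo < 0 || hi > 1) {
    out$nM <- pmin(pmax(nM, 0), 1); out$nMp <- pmin(pmax(nMp, 0), 1)
    out$nAMp <- pmin(pmax(nAMp, 0), 1); out$nAM <- pmin(pmax(nAM, 0), 1)
  } else {
    out$nM <- nM; out$nMp <- nMp; out$nAMp <- nAMp; out$nAM <- nAM
  }
  attr(out, "rate_cache") <- rc
  out
}

#' Contractile force and active stress from attached bridges
#'
#' The force of a single contractile unit is the first moment of the
#' attached populations over bond extension,
#' `F_unit = kappa * integral of x * (nAMp + nAM) dx`, and the active stress
#' available to the tissue is `A = beta * F_unit`, where `beta` counts
#' filaments per unit area (volume fraction times parallel myosin filaments
#' per fiber). `kappa` is the cross-bridge stiffness and carries the single
#' stress-scale calibration of the model, so `A` is in cmH2O.
#'
#' @param pop an [xb_populations()] object.
#' @param beta filament-scaling parameter (dimensionless), default 100.
#' @param kappa cross-bridge stiffness (stress per contractile unit per
#'   x-unit); default [default_kappa()].
#' @return An object of class `"contractile_force"`: list with `F_unit`,
#'   `A` (cmH2O), and `beta`. Negative values are reported as-is
#'   (net-compressed bridge distribution).
#' @export
active_stress <- function(pop, beta = 100, kappa = default_kappa()) {
  stopifnot(inherits(pop, "xb_populations"))
  if (length(pop$x) < 2) stop("active_stress: empty or degenerate grid")
  F_unit <- kappa * .trapz(pop$x, pop$x * (pop$nAMp + pop$nAM))
  structure(list(F_unit = F_unit, A = beta * F_unit, beta = beta,
                 kappa = kappa),
            class = "contractile_force")
}

#' @export
print.contractile_force <- function(x, ...) {
  cat(sprintf("contractile unit force %.5g (kappa*h^2), active stress A = %.4g cmH2O (beta = %g)\n",
              x$F_unit / x$kappa, x$A, x$beta))
  invisible(x)
}

#' Stress-scale calibration constant
#'
#' The cross-bridge stiffness `kappa` converting the contractile-unit force
#' integral (in h^2 units) into tissue stress (cmH2O) once multiplied by
#' `beta`. Calibrated once so that isometric activation over the protocol
#' range of `k1` produces the contracted radii and the rightward shifts of
#' the static pressure-radius and stiffness-pressure curves characteristic
#' of intact bovine airways; see the methods vignette.
#'
#' @return A numeric scalar (cmH2O per kappa*h^2 force unit, per beta unit).
#' @export
default_kappa <- function() 1.8

#' Export a population snapshot as a data frame
#'
#' @param x an [xb_populations()] object.
#' @param ... unused.
#' @return `data.frame` with columns `x`, `nM`, `nMp`, `nAMp`, `nAM`.
#' @export
as.data.frame.xb_populations <- function(x, ...) {
  data.frame(x = x$x, nM = x$nM, nMp = x$nMp, nAMp = x$nAMp, nAM = x$nAM)
}
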