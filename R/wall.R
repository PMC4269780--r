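# Quasistatic nonlinear mechanics of the two-layer axisymmetric airway:
# incompressible fiber-reinforced wall in plane strain, optional compressible
# linear-elastic parenchyma, equilibrium lumen radius under transmural
# pressure, and static pressure-radius / effective-stiffness curves.
#
# Sign convention: PTM = tau_a - tau_p (lumen minus external pressure); a
# compressive luminal pressure enters the wall as tau_rr(ra) = -tau_a, so
# positive PTM inflates the airway.

#' Undeformed airway geometry
#'
#' @param Ra undeformed lumen radius (length unit of the model; default 1).
#' @param chi undeformed wall thickness (default `0.3 * Ra`, the thickness of
#'   the intact bovine airways at zero transmural pressure; `0.45 * Ra` for
#'   the remodeled, thickened wall).
#' @param Rp undeformed outer radius of the parenchymal annulus, or `NULL`
#'   (default) for an isolated airway without parenchyma.
#' @return Object of class `"airway_geometry"` with fields `Ra`, `chi`,
#'   `Rb = Ra + chi`, `Rp`, `parenchyma_present`.
#' @export
airway_geometry <- function(Ra = 1, chi = 0.3 * Ra, Rp = NULL) {
  stopifnot(is.numeric(Ra), Ra > 0, is.numeric(chi), chi > 0)
  Rb <- Ra + chi
  if (!is.null(Rp) && Rp <= Rb)
    stop("parenchyma outer radius Rp must exceed Rb = Ra + chi")
  structure(list(Ra = Ra, chi = chi, Rb = Rb, Rp = Rp,
                 parenchyma_present = !is.null(Rp)),
            class = "airway_geometry")
}

#' @export
print.airway_geometry <- function(x, ...) {
  cat(sprintf("airway geometry: Ra = %g, wall thickness chi = %g (Rb = %g)",
              x$Ra, x$chi, x$Rb))
  if (x$parenchyma_present) cat(sprintf(", parenchyma to Rp = %g", x$Rp))
  cat("\n")
  invisible(x)
}

#' Constitutive parameters of wall and parenchyma
#'
#' The wall is an incompressible neo-Hookean matrix (modulus `mu`) reinforced
#' by fiber rings with exponential strain-stiffening energy
#' `Phi(lf) = C1/(2*C2) * (exp(C2*(lf^2-1)^2) - 1)`, mimicking progressive
#' collagen recruitment; `C1` scales fiber density/stiffness and `C2` the
#' nonlinear stiffening. The surrounding parenchyma, when present, is a
#' compressible linear elastic annulus with Young's modulus
#' `E_par_ratio * 3 * mu` and Poisson ratio `nu`.
#'
#' Defaults are the package's standard passive parameter set for an intact
#' bovine airway (see the methods vignette and [fit_passive_materials()]).
#'
#' @param mu base-matrix shear modulus (cmH2O).
#' @param C1 fiber stiffness/density parameter (cmH2O).
#' @param C2 fiber strain-stiffening exponent (dimensionless, >= 0).
#' @param lambda_slack recruitment stretch of the collagen fibers: wavy
#'   fibers carry tensile load only once stretched beyond this value
#'   (squared-stretch measure `e = max(lf^2 - lambda_slack^2, 0)` on the
#'   tensile side), producing the compliant toe region of the passive
#'   pressure-radius curve; in compression the fiber network engages
#'   immediately (`e = lf^2 - 1` for `lf < 1`).
#' @param lambda_buckle fiber stretch below which the compressed fiber
#'   network buckles: for `lf < lambda_buckle` the compressive strain
#'   measure plateaus at `lambda_buckle^2 - 1`, so strongly constricted
#'   states are held by the matrix rather than an ever-stiffening fiber
#'   bed.
#' @param E_par_ratio parenchyma-to-matrix Young's modulus ratio.
#' @param nu parenchyma Poisson ratio, in `[0, 0.5)`.
#' @param fiber_angle helix angle of the fiber family measured from the hoop
#'   direction (radians); 0 (default) gives pure rings.
#' @param tension_only if `TRUE`, fibers bear load only when stretched
#'   (`lf > 1`); by default they also resist compression.
#' @param fl_on,fl_off fiber stretches bounding the taper of the active
#'   force-length (filament-overlap) factor: the contractile stress carries
#'   its full weight for fiber stretch below `fl_on`, falls smoothly
#'   (cubic smoothstep) to zero at `fl_off`, and vanishes beyond, reflecting
#'   loss of actin-myosin overlap in strongly stretched contractile units.
#'   No penalty is applied on the shortening side.
#' @return Object of class `"material_parameters"`.
#' @export
material_parameters <- function(mu = 22, C1 = 2, C2 = 8,
                                lambda_slack = 1.08, lambda_buckle = 0.94,
                                E_par_ratio = 0.1, nu = 0.3,
                                fiber_angle = 0, tension_only = FALSE,
                                fl_on = 1.25, fl_off = 1.30) {
  stopifnot(mu > 0, C1 > 0, C2 >= 0, E_par_ratio >= 0, nu >= 0, nu < 0.5,
            fl_off > fl_on, fl_on >= 1, lambda_slack >= 1,
            lambda_buckle > 0, lambda_buckle <= 1)
  structure(list(mu = mu, C1 = C1, C2 = C2, lambda_slack = lambda_slack,
                 lambda_buckle = lambda_buckle,
                 E_par_ratio = E_par_ratio,
                 nu = nu, fiber_angle = fiber_angle,
                 tension_only = isTRUE(tension_only),
                 fl_on = fl_on, fl_off = fl_off),
            class = "material_parameters")
}

#' Active force-length (filament-overlap) factor
#'
#' Fraction of the isometric contractile stress available at fiber stretch
#' `lf`: 1 for `lf <= fl_on`, a cubic smoothstep taper on
#' `(fl_on, fl_off)`, and 0 beyond `fl_off` where actin-myosin overlap is
#' lost.
#'
#' @param lf fiber stretch (vectorised).
#' @param mat a [material_parameters()] object (supplies `fl_on`, `fl_off`).
#' @return Numeric vector in `[0, 1]`.
#' @export
overlap_factor <- function(lf, mat) {
  s <- pmin(pmax((lf - mat$fl_on) / (mat$fl_off - mat$fl_on), 0), 1)
  1 - s^2 * (3 - 2 * s)
}

#' @export
print.material_parameters <- function(x, ...) {
  cat(sprintf("wall materials: mu = %g, C1 = %g, C2 = %g (cmH2O)\n",
              x$mu, x$C1, x$C2))
  cat(sprintf("  parenchyma E ratio = %g, nu = %g; fiber angle = %g rad%s\n",
              x$E_par_ratio, x$nu, x$fiber_angle,
              if (x$tension_only) " (tension-only fibers)" else ""))
  invisible(x)
}

#' Incompressible plane-strain deformation map
#'
#' Maps an undeformed radius `R` in the wall to its deformed position given
#' the deformed lumen radius `ra`: `r = sqrt(ra^2 + R^2 - Ra^2)`, which
#' conserves the annular cross-section area exactly.
#'
#' @param ra deformed lumen radius.
#' @param geom an [airway_geometry()] object.
#' @param R undeformed radius (vectorised), `Ra <= R <= Rb`.
#' @return Deformed radii `r`.
#' @export
deformation_map <- function(ra, geom, R) {
  stopifnot(inherits(geom, "airway_geometry"))
  arg <- ra^2 + R^2 - geom$Ra^2
  if (any(arg <= 0))
    stop("airway collapse: deformation map undefined (ra too small)")
  sqrt(arg)
}

# hoop Cauchy stress carried by the fiber family (passive + active), at
# hoop stretch lt (vectorised). Exponent clamped to avoid overflow in the
# far-from-equilibrium region probed by root bracketing.
# A_eff is the overlap-weighted active stress (see .effective_active): the
# force-length state of the contractile machinery is evaluated once at the
# mid-wall fiber, matching the velocity coupling.
.fiber_hoop_stress <- function(lt, mat, A_eff) {
  ca2 <- cos(mat$fiber_angle)^2
  lf2 <- lt^2 * ca2 + (1 - ca2)   # axial stretch is 1 in plane strain
  # recruitment: tensile load only beyond the slack stretch; in compression
  # the network engages immediately but buckles (stress plateau) beyond
  # lambda_buckle
  e <- pmax(lf2 - mat$lambda_slack^2, 0)
  comp <- lf2 < 1
  if (any(comp))
    e[comp] <- pmax(lf2[comp] - 1, mat$lambda_buckle^2 - 1)
  z <- mat$C2 * e^2
  if (any(z > 690))
    stop("fiber stiffening overflow: exp(", signif(max(z), 3),
         ") at hoop stretch ", signif(max(lt), 4))
  passive <- 2 * mat$C1 * ca2 * lt^2 * e * exp(z)
  if (mat$tension_only) passive[lf2 < 1] <- 0
  active <- if (A_eff == 0) 0 else {
    lf <- sqrt(lf2)
    A_eff * lt^2 * ca2 / lf
  }
  passive + active
}

# mid-wall fiber stretch for a given lumen radius
.lambda_mid <- function(ra, geom) {
  R_mid <- (geom$Ra + geom$Rb) / 2
  sqrt(ra^2 + R_mid^2 - geom$Ra^2) / R_mid
}

# overlap-weighted active stress: the isometric active stress A is scaled by
# the filament-overlap factor of the mid-wall fiber
.effective_active <- function(ra, geom, mat, A) {
  if (A == 0) return(0)
  A * overlap_factor(.lambda_mid(ra, geom), mat)
}

# integrand of the radial momentum balance: (tau_tt - tau_rr) / r, written
# in the undeformed variable R (dr = R dR / r):
#   integral (tau_tt - tau_rr) / r dr = integral dev(R) * R / r^2 dR
.wall_balance_integral <- function(ra, geom, mat, A, quad) {
  r2 <- ra^2 + quad$R^2 - geom$Ra^2
  lt2 <- r2 / quad$R^2
  A_eff <- .effective_active(ra, geom, mat, A)
  dev <- mat$mu * (lt2 - 1 / lt2) + .fiber_hoop_stress(sqrt(lt2), mat, A_eff)
  sum(quad$w * dev * quad$R / r2)
}

.quad_cache <- new.env(parent = emptyenv())

.wall_quad <- function(geom, n = 64) {
  key <- paste(format(geom$Ra, digits = 17), format(geom$Rb, digits = 17), n)
  hit <- .quad_cache[[key]]
  if (!is.null(hit)) return(hit)
  gl <- pracma::gaussLegendre(n, geom$Ra, geom$Rb)
  out <- list(R = gl$x, w = gl$w)
  .quad_cache[[key]] <- out
  out
}

#' Cauchy stress profiles across the airway wall
#'
#' Integrates the radial momentum balance `d tau_rr / dr = (tau_tt -
#' tau_rr) / r` outward from the lumen boundary condition
#' `tau_rr(ra) = -tau_a` and reports the radial, hoop and axial Cauchy
#' stress components across the wall.
#'
#' @param ra deformed lumen radius.
#' @param geom an [airway_geometry()] object.
#' @param mat a [material_parameters()] object.
#' @param A active stress delivered by the fibers (cmH2O).
#' @param tau_a applied normal stress at the lumen boundary (cmH2O).
#' @param n number of radial sample points.
#' @return `data.frame` with columns `R`, `r`, `lambda_theta`, `tau_rr`,
#'   `tau_tt`, `tau_zz` (all stresses in cmH2O).
#' @export
wall_stress <- function(ra, geom, mat, A = 0, tau_a = 0, n = 201) {
  stopifnot(inherits(geom, "airway_geometry"),
            inherits(mat, "material_parameters"))
  R <- seq(geom$Ra, geom$Rb, length.out = n)
  r <- deformation_map(ra, geom, R)
  lt <- r / R
  A_eff <- .effective_active(ra, geom, mat, A)
  dev <- mat$mu * (lt^2 - 1 / lt^2) + .fiber_hoop_stress(lt, mat, A_eff)
  # cumulative trapezoid of dev / r dr = dev * R / r^2 dR
  f <- dev * R / r^2
  dR <- R[2] - R[1]
  cumint <- c(0, cumsum((f[-1] + f[-n]) / 2 * dR))
  tau_rr <- -tau_a + cumint
  tau_tt <- tau_rr + dev
  # plane-strain axial reaction: tau_zz = tau_rr + mu (1 - lambda_r^2) + axial
  # fiber component (zero for hoop rings)
  sa2 <- sin(mat$fiber_angle)^2
  lf2 <- lt^2 * cos(mat$fiber_angle)^2 + sa2
  e <- pmax(lf2 - mat$lambda_slack^2, 0)
  comp <- lf2 < 1
  if (any(comp))
    e[comp] <- pmax(lf2[comp] - 1, mat$lambda_buckle^2 - 1)
  z <- pmin(mat$C2 * e^2, 690)
  fib_zz <- 2 * mat$C1 * sa2 * e * exp(z) +
    if (A_eff == 0) 0 else A_eff * sa2 / sqrt(lf2)
  tau_zz <- tau_rr + mat$mu * (1 - 1 / lt^2) + fib_zz
  data.frame(R = R, r = r, lambda_theta = lt,
             tau_rr = tau_rr, tau_tt = tau_tt, tau_zz = tau_zz)
}

#' Radial stress at the wall-parenchyma interface
#'
#' Solves the classical compressible linear-elastic annulus (Lame) problem
#' for the parenchyma, with prescribed radial displacement `rb - Rb` at the
#' inner boundary and applied normal stress `tau_p` at the outer boundary,
#' and returns the normal stress the parenchyma exerts on the airway wall at
#' the interface (same sign convention as `tau_p`: the value that replaces
#' the external stress in the wall equilibrium). Without parenchyma the
#' external stress is returned unchanged.
#'
#' @param rb deformed outer wall radius.
#' @param geom an [airway_geometry()] object.
#' @param mat a [material_parameters()] object.
#' @param tau_p applied normal stress at the outer parenchyma boundary
#'   (cmH2O).
#' @return Interface normal stress (cmH2O).
#' @export
parenchyma_interface_stress <- function(rb, geom, mat, tau_p = 0) {
  stopifnot(inherits(geom, "airway_geometry"),
            inherits(mat, "material_parameters"))
  if (!geom$parenchyma_present) return(tau_p)
  if (geom$Rp <= geom$Rb) stop("invalid geometry: Rp <= Rb")
  E_par <- mat$E_par_ratio * 3 * mat$mu   # matrix is incompressible: E = 3 mu
  if (E_par == 0) return(tau_p)
  nu <- mat$nu
  G <- E_par / (2 * (1 + nu))
  lam <- E_par * nu / ((1 + nu) * (1 - 2 * nu))
  # u(R) = a R + b / R; sig_rr = 2 (lam + G) a - 2 G b / R^2
  # conditions: u(Rb) = rb - Rb; sig_rr(Rp) = -tau_p
  M <- rbind(c(geom$Rb, 1 / geom$Rb),
             c(2 * (lam + G), -2 * G / geom$Rp^2))
  rhs <- c(rb - geom$Rb, -tau_p)
  ab <- solve(M, rhs)
  sig_rr_b <- 2 * (lam + G) * ab[1] - 2 * G * ab[2] / geom$Rb^2
  -sig_rr_b
}

# deformed parenchyma outer radius for a given rb (NULL without parenchyma)
.parenchyma_outer_radius <- function(rb, geom, mat, tau_p = 0) {
  if (!geom$parenchyma_present) return(NULL)
  E_par <- mat$E_par_ratio * 3 * mat$mu
  if (E_par == 0) return(geom$Rp + (rb - geom$Rb) * geom$Rb / geom$Rp)
  nu <- mat$nu
  G <- E_par / (2 * (1 + nu))
  lam <- E_par * nu / ((1 + nu) * (1 - 2 * nu))
  M <- rbind(c(geom$Rb, 1 / geom$Rb),
             c(2 * (lam + G), -2 * G / geom$Rp^2))
  ab <- solve(M, c(rb - geom$Rb, -tau_p))
  geom$Rp + ab[1] * geom$Rp + ab[2] / geom$Rp
}

#' Equilibrium lumen radius under transmural pressure
#'
#' Finds the deformed lumen radius `ra` at which the integrated radial
#' momentum balance across the wall matches the applied boundary stresses,
#' `tau_a = PTM + tau_p` at the lumen and the parenchyma interface stress
#' (equal to `tau_p` for an isolated airway) outside. The root is located by
#' a bracketed scalar solve and polished until the residual is below
#' `1e-9 * mu`.
#'
#' @param PTM transmural pressure (cmH2O).
#' @param geom an [airway_geometry()] object.
#' @param mat a [material_parameters()] object.
#' @param A active fiber stress (cmH2O).
#' @param tau_p external normal stress at the outer boundary (cmH2O),
#'   zero in all replicated protocols.
#' @param bracket search interval for `ra` (default `c(0.05, 4) * Ra`).
#' @param ra_guess optional warm start (previous solution) used to tighten
#'   the bracket.
#' @param quad_n number of Gauss-Legendre nodes for the wall integral.
#' @return Object of class `"airway_state"`: list with `ra`, `rb`, `rp`,
#'   `thickness`, `PTM`, `tau_a`, `tau_p`, `A`, `lambda_mid` (hoop stretch
#'   at the wall midpoint) and `residual`.
#' @export
equilibrium_radius <- function(PTM, geom, mat, A = 0, tau_p = 0,
                               bracket = c(0.05, 4) * geom$Ra,
                               ra_guess = NULL, quad_n = 64) {
  stopifnot(inherits(geom, "airway_geometry"),
            inherits(mat, "material_parameters"))
  quad <- .wall_quad(geom, quad_n)
  resid <- function(ra) .eq_resid(ra, PTM, geom, mat, A, tau_p, quad)
  safe <- function(ra) tryCatch(resid(ra), error = function(e) NA_real_)

  lo <- bracket[1]; hi <- bracket[2]
  bracketed <- FALSE
  if (!is.null(ra_guess) && is.finite(ra_guess)) {
    # march from the previous radius in the direction of the net force
    # imbalance (f > 0: wall stress exceeds the applied load, the lumen
    # shrinks); the first sign change encountered this way brackets the
    # stable equilibrium the quasistatic dynamics actually reach, not an
    # unstable middle branch of a folded pressure-radius relation
    f0 <- safe(ra_guess)
    if (!is.na(f0) && f0 != 0) {
      dir <- if (f0 > 0) -1 else 1
      w <- 0.005 * geom$Ra
      prev <- ra_guess; fprev <- f0
      repeat {
        cand <- ra_guess + dir * w
        if (cand <= bracket[1] || cand >= bracket[2]) break
        fc <- safe(cand)
        if (!is.na(fc) && fprev * fc <= 0) {
          if (prev < cand) { lo <- prev; hi <- cand; flo <- fprev; fhi <- fc }
          else { lo <- cand; hi <- prev; flo <- fc; fhi <- fprev }
          bracketed <- TRUE
          break
        }
        if (!is.na(fc)) { prev <- cand; fprev <- fc }
        w <- 1.6 * w
        if (w > (bracket[2] - bracket[1])) break
      }
    } else if (!is.na(f0) && f0 == 0) {
      lo <- hi <- ra_guess
    }
  }
  if (lo == hi)
    return(.make_airway_state(lo, PTM, geom, mat, A, tau_p, 0))
  if (!bracketed) { flo <- safe(lo); fhi <- safe(hi) }
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    # scan for a sign change on a coarse grid before giving up
    grid <- seq(bracket[1], bracket[2], length.out = 81)
    fg <- vapply(grid, safe, numeric(1))
    ok <- which(!is.na(fg))
    sgn <- which(diff(sign(fg[ok])) != 0)
    if (length(sgn) == 0)
      stop("no equilibrium: residual has no sign change in bracket [",
           signif(bracket[1], 4), ", ", signif(bracket[2], 4), "]")
    lo <- grid[ok[sgn[1]]]; hi <- grid[ok[sgn[1] + 1]]
    flo <- fg[ok[sgn[1]]]; fhi <- fg[ok[sgn[1] + 1]]
  }
  root <- stats::uniroot(resid, lower = lo, upper = hi,
                         f.lower = flo, f.upper = fhi,
                         tol = 1e-12 * geom$Ra)$root
  # secant polish to meet the residual tolerance
  tol <- 1e-9 * mat$mu
  f0 <- resid(root)
  if (abs(f0) > tol) {
    dr <- 1e-7 * geom$Ra
    for (i in 1:8) {
      f1 <- resid(root + dr)
      slope <- (f1 - f0) / dr
      if (!is.finite(slope) || slope == 0) break
      root <- root - f0 / slope
      f0 <- resid(root)
      if (abs(f0) <= tol) break
    }
  }
  .make_airway_state(root, PTM, geom, mat, A, tau_p, f0)
}

# residual of the integrated radial momentum balance at lumen radius ra
.eq_resid <- function(ra, PTM, geom, mat, A, tau_p = 0,
                      quad = .wall_quad(geom)) {
  rb <- sqrt(ra^2 + geom$Rb^2 - geom$Ra^2)
  tau_b <- parenchyma_interface_stress(rb, geom, mat, tau_p)
  .wall_balance_integral(ra, geom, mat, A, quad) - (PTM + tau_p - tau_b)
}

.make_airway_state <- function(ra, PTM, geom, mat, A, tau_p, residual) {
  rb <- sqrt(ra^2 + geom$Rb^2 - geom$Ra^2)
  structure(list(ra = ra, rb = rb,
                 rp = .parenchyma_outer_radius(rb, geom, mat, tau_p),
                 thickness = rb - ra, PTM = PTM,
                 tau_a = PTM + tau_p, tau_p = tau_p, A = A,
                 lambda_mid = .lambda_mid(ra, geom),
                 residual = residual),
            class = "airway_state")
}

#' @export
print.airway_state <- function(x, ...) {
  cat(sprintf("airway state: PTM = %.3g cmH2O, A = %.3g cmH2O\n", x$PTM, x$A))
  cat(sprintf("  ra = %.5g, rb = %.5g, thickness = %.5g\n",
              x$ra, x$rb, x$thickness))
  invisible(x)
}

#' Static pressure-radius curves per activation level
#'
#' For each MLCK rate `k1`, computes the isometric steady-state cross-bridge
#' populations and the resulting active stress, then sweeps the transmural
#' pressure grid solving the wall equilibrium at every point. Because the
#' isometric kinetic steady state is independent of stretch, the
#' self-consistency iteration between active stress and equilibrium radius
#' converges immediately; the loop is retained for stretch-dependent force
#' models.
#'
#' @param levels numeric vector of `k1` values (1/s); 0 gives the passive
#'   curve.
#' @param geom an [airway_geometry()] object.
#' @param mat a [material_parameters()] object.
#' @param rates a [rate_parameters()] template; `k1` is overridden per level.
#' @param ptm transmural pressure grid (cmH2O), default `-15` to `30`.
#' @param beta,kappa force-scaling parameters, see [active_stress()].
#' @param tau_p external normal stress (cmH2O).
#' @return Object of class `"pr_curve"`: a `data.frame` with columns `k1`,
#'   `PTM`, `ra`, `ra_norm` (`= ra / Ra`), `thickness`, `A`.
#' @export
static_curve <- function(levels = c(0, 0.005, 0.025, 0.05),
                         geom = airway_geometry(),
                         mat = material_parameters(),
                         rates = rate_parameters(),
                         ptm = seq(-15, 30, by = 0.25),
                         beta = 100, kappa = default_kappa(), tau_p = 0) {
  stopifnot(length(levels) >= 1)
  out <- vector("list", length(levels))
  for (j in seq_along(levels)) {
    k1 <- levels[j]
    A <- if (k1 == 0) 0 else {
      pj <- rates; pj$k1 <- k1
      pop <- steady_state_populations(pj, quiet = TRUE)
      active_stress(pop, beta = beta, kappa = kappa)$A
    }
    ra <- numeric(length(ptm)); th <- numeric(length(ptm))
    guess <- NULL
    ord <- order(ptm)
    for (i in ord) {
      st <- equilibrium_radius(ptm[i], geom, mat, A = A, tau_p = tau_p,
                               ra_guess = guess)
      ra[i] <- st$ra; th[i] <- st$thickness
      guess <- st$ra
    }
    out[[j]] <- data.frame(k1 = k1, PTM = ptm, ra = ra,
                           ra_norm = ra / geom$Ra, thickness = th, A = A)
  }
  res <- do.call(rbind, out)
  attr(res, "geom") <- geom
  class(res) <- c("pr_curve", "data.frame")
  res
}

#' Effective stiffness from a pressure-radius curve
#'
#' The effective airway stiffness is the reciprocal of the slope of the
#' static pressure-radius relationship,
#' `stiffness(PTM) = 1 / d(ra/Ra)/dPTM`, evaluated by central finite
#' differences (one-sided at the endpoints). Points with zero slope are
#' flagged as infinitely stiff and masked to `NA`.
#'
#' @param curve a `"pr_curve"` from [static_curve()], or any `data.frame`
#'   with columns `k1`, `PTM`, `ra_norm`.
#' @return Object of class `"stiffness_curve"`: `data.frame` with columns
#'   `k1`, `PTM`, `stiffness` (cmH2O per unit normalized radius).
#' @export
effective_stiffness <- function(curve) {
  stopifnot(all(c("k1", "PTM", "ra_norm") %in% names(curve)))
  parts <- lapply(split(curve, curve$k1), function(d) {
    d <- d[order(d$PTM), ]
    n <- nrow(d)
    if (n < 3) stop("effective_stiffness: need at least 3 points per level")
    dP <- c(d$PTM[2] - d$PTM[1],
            d$PTM[3:n] - d$PTM[1:(n - 2)],
            d$PTM[n] - d$PTM[n - 1])
    dr <- c(d$ra_norm[2] - d$ra_norm[1],
            d$ra_norm[3:n] - d$ra_norm[1:(n - 2)],
            d$ra_norm[n] - d$ra_norm[n - 1])
    s <- ifelse(dr == 0, NA_real_, dP / dr)
    data.frame(k1 = d$k1, PTM = d$PTM, stiffness = s)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  class(res) <- c("stiffness_curve", "data.frame")
  res
}

#' Location of the interior stiffness minimum
#'
#' Finds the transmural pressure at which the effective stiffness attains
#' its interior minimum for one activation level, refining the grid argmin
#' by a local quadratic (three-point parabolic) interpolation.
#'
#' @param stiff a `"stiffness_curve"` from [effective_stiffness()].
#' @param k1 activation level to examine (must match a level in `stiff`).
#' @return PTM of the stiffness minimum (cmH2O).
#' @export
stiffness_minimum <- function(stiff, k1) {
  d <- stiff[stiff$k1 == k1 & is.finite(stiff$stiffness), ]
  if (nrow(d) < 3) stop("no such activation level or too few points")
  d <- d[order(d$PTM), ]
  i <- which.min(d$stiffness)
  if (i == 1 || i == nrow(d)) return(d$PTM[i])   # boundary minimum
  # parabolic refinement through the three bracketing points
  p <- d$PTM[(i - 1):(i + 1)]; s <- d$stiffness[(i - 1):(i + 1)]
  denom <- (p[1] - p[2]) * (p[1] - p[3]) * (p[2] - p[3])
  aa <- (p[3] * (s[2] - s[1]) + p[2] * (s[1] - s[3]) + p[1] * (s[3] - s[2])) / denom
  bb <- (p[3]^2 * (s[1] - s[2]) + p[2]^2 * (s[3] - s[1]) + p[1]^2 * (s[2] - s[3])) / denom
  if (aa <= 0) return(d$PTM[i])
  -bb / (2 * aa)
}

#' Pressure range over which activation re-orders the stiffness curves
#'
#' At each grid pressure, checks whether effective stiffness is strictly
#' increasing across the activation levels (sorted by `k1`). Returns the
#' interval of transmural pressures over which that ordering fails - the
#' band in which a more activated airway can be the more compliant one -
#' together with the crossover pressures bounding it.
#'
#' @param stiff a `"stiffness_curve"` with at least two activation levels.
#' @param rel_tol relative tolerance below which two stiffness values are
#'   treated as equal (and hence as not violating the ordering); absorbs
#'   finite-difference noise where activated and passive curves have merged.
#' @return List with `lower` and `upper` (cmH2O): the first and last grid
#'   pressures at which the monotone-in-activation ordering fails, or `NULL`
#'   if the ordering holds everywhere.
#' @export
stiffness_ordering_range <- function(stiff, rel_tol = 1e-6) {
  lv <- sort(unique(stiff$k1))
  if (length(lv) < 2) stop("need at least two activation levels")
  wide <- lapply(lv, function(k) {
    d <- stiff[stiff$k1 == k, ]
    d[order(d$PTM), "stiffness"]
  })
  ptm <- sort(unique(stiff$PTM))
  mono <- rep(TRUE, length(ptm))
  for (j in seq_len(length(lv) - 1)) {
    a <- wide[[j]]; b <- wide[[j + 1]]
    viol <- (a - b) > rel_tol * pmax(abs(a), abs(b))
    mono <- mono & !is.na(a) & !is.na(b) & !viol
  }
  bad <- which(!mono)
  if (length(bad) == 0) return(NULL)
  list(lower = ptm[min(bad)], upper = ptm[max(bad)])
}

#' Export a pressure-radius curve (with stiffness) as CSV
#'
#' Writes one block per activation level with columns
#' `k1, PTM, ra_norm, thickness_norm, stiffness`.
#'
#' @param curve a `"pr_curve"` from [static_curve()].
#' @param path output file path.
#' @return The written `data.frame`, invisibly.
#' @export
write_pr_curve <- function(curve, path) {
  stiff <- effective_stiffness(curve)
  parts <- lapply(split(as.data.frame(curve), curve$k1), function(d) {
    d <- d[order(d$PTM), ]
    t0 <- d$thickness[which.min(abs(d$PTM))]
    data.frame(k1 = d$k1, PTM = d$PTM, ra_norm = d$ra_norm,
               thickness_norm = d$thickness / t0)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- merge(out, as.data.frame(stiff), by = c("k1", "PTM"), sort = FALSE)
  out <- out[order(out$k1, out$PTM), ]
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
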