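# Run configuration (YAML), validation against the built-in defaults, and
# the orchestration entry point used by the command-line script.

#' Default run configuration
#'
#' All model parameters with their protocol defaults (mean pressure
#' 7.5 cmH2O, tidal amplitude 2.5 cmH2O, beta = 100, wall thickness
#' 0.3 Ra, g1 = 0.1), the fitted passive material set, and the standard
#' kinetic constants.
#'
#' @return Nested named list; see [load_config()].
#' @export
default_config <- function() {
  mat <- material_parameters()
  rates <- rate_parameters()
  cp <- coupling_parameters()
  list(
    command = "protocol1",
    geometry = list(Ra = 1, chi = 0.3, Rp = NULL),
    materials = list(mu = mat$mu, C1 = mat$C1, C2 = mat$C2,
                     lambda_slack = mat$lambda_slack,
                     E_par_ratio = mat$E_par_ratio, nu = mat$nu,
                     fiber_angle = mat$fiber_angle,
                     tension_only = mat$tension_only,
                     fl_on = mat$fl_on, fl_off = mat$fl_off),
    rates = list(k1 = rates$k1, k2 = rates$k2, fp1 = rates$fp1,
                 gp_neg = rates$gp_neg, gp1 = rates$gp1, g1 = rates$g1,
                 g_neg = rates$g_neg, h = rates$h),
    coupling = list(L_cu = cp$L_cu, n_series = cp$n_series,
                    velocity_sign = cp$velocity_sign),
    forcing = list(PTM0 = 7.5, dPTM = 2.5, t0 = 5),
    force_scale = list(beta = 100, kappa = default_kappa()),
    protocol = list(g1 = 0.1, remodeled = FALSE, stage_duration = 720,
                    scaled_durations = TRUE, tol = 1e-5),
    curves = list(levels = c(0, 0.005, 0.025, 0.05),
                  ptm_min = -15, ptm_max = 30, ptm_step = 0.25),
    synth = list(noise_sd = 0.02, seed = 1, k1 = 0, ptm_step = 2.5),
    fit = list(input = NULL),
    numerics = list(dt = 0.01),
    output_dir = "airwaymech_out",
    verbose = TRUE
  )
}

# recursively merge user values over defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: '", key, "'")
    if (is.list(defaults[[nm]]) && !is.null(defaults[[nm]]) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  if (cfg$forcing$t0 <= 0) stop("config error at forcing.t0: must be > 0")
  if (cfg$numerics$dt <= 0) stop("config error at numerics.dt: must be > 0")
  if (cfg$geometry$Ra <= 0) stop("config error at geometry.Ra: must be > 0")
  if (cfg$geometry$chi <= 0) stop("config error at geometry.chi: must be > 0")
  if (cfg$forcing$dPTM < 0) stop("config error at forcing.dPTM: must be >= 0")
  if (!cfg$command %in% c("curves", "protocol1", "protocol2", "fit", "synth"))
    stop("config error at command: unknown command '", cfg$command, "'")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()], rejects unknown
#' keys (with the offending key path), and validates the result. An empty
#' file yields the Protocol-1 defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("config file must be a YAML mapping")
      cfg <- .merge_config(cfg, user)
    }
  }
  .validate_config(cfg)
  cfg
}

# assemble model objects from a configuration
.config_model <- function(cfg) {
  geom <- airway_geometry(Ra = cfg$geometry$Ra,
                          chi = cfg$geometry$chi * cfg$geometry$Ra,
                          Rp = cfg$geometry$Rp)
  mat <- do.call(material_parameters, cfg$materials)
  rates <- do.call(rate_parameters, cfg$rates)
  cp <- do.call(coupling_parameters, cfg$coupling)
  airway_model(geom = geom, mat = mat, rates = rates, cp = cp,
               beta = cfg$force_scale$beta, kappa = cfg$force_scale$kappa,
               PTM0 = cfg$forcing$PTM0, dPTM = cfg$forcing$dPTM,
               t0 = cfg$forcing$t0, dt = cfg$numerics$dt)
}

#' Execute a configured run and write its artifacts
#'
#' Orchestrates the experiment selected by `config$command`:
#' \describe{
#'   \item{`curves`}{static pressure-radius and stiffness curves over the
#'     configured activation levels, written as one CSV.}
#'   \item{`protocol1` / `protocol2`}{the staged protocols (oscillatory and
#'     static companion for Protocol 1), summary and loop CSVs.}
#'   \item{`fit`}{passive material fit to the CSV in `config$fit$input`,
#'     report written as JSON.}
#'   \item{`synth`}{a synthetic pressure-radius dataset CSV.}
#' }
#' A machine-readable manifest (`manifest.json`: effective parameters,
#' package version, seed) is always written, making each run reproducible
#' from its output directory alone.
#'
#' @param config configuration list from [load_config()].
#' @return Invisibly, a character vector of files written.
#' @export
run_command <- function(config) {
  cfg <- .validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  files <- character(0)
  out <- function(name) file.path(cfg$output_dir, name)
  model <- .config_model(cfg)

  if (cfg$command == "curves") {
    say("computing static curves for k1 = ",
        paste(cfg$curves$levels, collapse = ", "))
    cv <- static_curve(levels = cfg$curves$levels, geom = model$geom,
                       mat = model$mat, rates = model$rates,
                       ptm = seq(cfg$curves$ptm_min, cfg$curves$ptm_max,
                                 by = cfg$curves$ptm_step),
                       beta = model$beta, kappa = model$kappa)
    write_pr_curve(cv, out("static_curves.csv"))
    files <- c(files, out("static_curves.csv"))
  } else if (cfg$command %in% c("protocol1", "protocol2")) {
    dur <- cfg$protocol$stage_duration
    spec <- if (cfg$command == "protocol1")
      protocol1_spec(dPTM = cfg$forcing$dPTM, stage_duration = dur,
                     remodeled = cfg$protocol$remodeled,
                     g1 = cfg$protocol$g1)
    else
      protocol2_spec(g1 = cfg$protocol$g1, stage_duration = dur,
                     remodeled = cfg$protocol$remodeled)
    say("running ", spec$name, " (", nrow(spec$stages), " stages)")
    tol <- if (isTRUE(cfg$protocol$scaled_durations)) cfg$protocol$tol else 0
    res <- run_protocol(spec, model, tol = tol, sample_every = 5L)
    prefix <- out(sub(" ", "", tolower(spec$name)))
    files <- c(files, write_protocol_result(res, prefix))
  } else if (cfg$command == "fit") {
    if (is.null(cfg$fit$input))
      stop("config error at fit.input: a CSV path is required")
    d <- read_pr_dataset(cfg$fit$input)
    say("fitting passive materials to ", nrow(d), " records")
    fit <- fit_passive_materials(d, geom = model$geom,
                                 base_mat = model$mat)
    write_material_fit(fit, out("material_fit.json"))
    files <- c(files, out("material_fit.json"))
  } else if (cfg$command == "synth") {
    say("generating synthetic pressure-radius dataset (seed ",
        cfg$synth$seed, ")")
    d <- generate_pr_dataset(geom = model$geom, mat = model$mat,
                             rates = model$rates,
                             ptm = seq(cfg$curves$ptm_min,
                                       cfg$curves$ptm_max,
                                       by = cfg$synth$ptm_step),
                             k1 = cfg$synth$k1,
                             noise_sd = cfg$synth$noise_sd,
                             seed = cfg$synth$seed,
                             beta = model$beta, kappa = model$kappa)
    utils::write.csv(cbind(as.data.frame(d), label = attr(d, "label")),
                     out("synthetic_pr.csv"), row.names = FALSE)
    files <- c(files, out("synthetic_pr.csv"))
  }

  manifest <- list(
    package = "airwaymech",
    version = as.character(utils::packageVersion("airwaymech")),
    command = cfg$command,
    parameters = cfg[setdiff(names(cfg), c("verbose", "output_dir"))],
    files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, out("manifest.json"))
  invisible(files)
}
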