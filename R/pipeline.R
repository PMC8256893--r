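#' Configuration for an end-to-end run
#'
#' Collects every knob of the pipeline with defaults mirroring the standard
#' acquisition: a 26-node mesh (1,300 resistors), 8 needle electrodes under
#' the adjacent method, 15 mA injection, 3 Modified Newton-Raphson
#' iterations.
#'
#' @param s Grid side.
#' @param electrodes Template points (data frame / matrix with columns a, b)
#'   in ring order.
#' @param amplitude_A Injection amplitude in amperes.
#' @param frequency_khz Frequency label for the simulated acquisition.
#' @param phantom A [phantom_spec()], or a scenario name understood by
#'   [scenario_phantom()].
#' @param snr_db Measurement SNR in dB; `Inf` (default) for noiseless.
#' @param seed Integer seed for the noise generator.
#' @param z0 Initial uniform resistance; `NULL` uses the phantom background
#'   (or the scenario's recommended value).
#' @param lambda,max_iter,delta_tol Reconstruction settings, see
#'   [eit_reconstruct()].
#' @return A `run_config` list.
#' @export
run_config <- function(s = 26L, electrodes = default_electrodes(),
                       amplitude_A = 0.015, frequency_khz = 1,
                       phantom = "saline_large_disc", snr_db = Inf,
                       seed = 1L, z0 = NULL, lambda = 1e-8, max_iter = 3L,
                       delta_tol = 0) {
  if (is.character(phantom)) {
    sc <- scenario_phantom(phantom)
    phantom <- sc$spec
    if (is.null(z0)) z0 <- sc$z0
  }
  stopifnot(inherits(phantom, "phantom_spec"))
  if (is.null(z0)) z0 <- phantom$background_ohms
  structure(list(s = check_grid_side(s), electrodes = electrodes,
                 amplitude_A = amplitude_A, frequency_khz = frequency_khz,
                 phantom = phantom, snr_db = snr_db, seed = as.integer(seed),
                 z0 = z0, lambda = lambda, max_iter = as.integer(max_iter),
                 delta_tol = delta_tol),
            class = "run_config")
}

#' Run the full pipeline: phantom, simulate, reconstruct, render
#'
#' Generates the phantom mesh, simulates the adjacent-protocol measurements
#' (optionally adding seeded noise), reconstructs the resistance
#' distribution and renders the normalized tomogram. All artifacts are
#' written under `out_dir` together with a machine-readable manifest; the
#' run is fully reproducible from (config, seed).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the `eit_recon` fit, the true grid, the
#'   measurement frame, the tomogram, and the manifest (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  paths <- list(true_grid = file.path(out_dir, "true_grid.csv"),
                measurements = file.path(out_dir, "measurements.csv"),
                recon_grid = file.path(out_dir, "recon_grid.csv"),
                trace = file.path(out_dir, "trace.json"),
                image_csv = file.path(out_dir, "tomogram.csv"),
                image_png = file.path(out_dir, "tomogram.png"),
                manifest = file.path(out_dir, "manifest.json"))

  truth <- stage("phantom", generate_phantom(config$phantom))
  write_grid_csv(truth, paths$true_grid)

  prot <- adjacent_protocol(map_template_to_node(config$electrodes$a,
                                                 config$electrodes$b, config$s),
                            config$s, config$amplitude_A)
  ground <- default_ground(config$s)
  frame <- stage("simulate", {
    f <- simulate_measurements(truth, prot, ground, config$frequency_khz)
    if (is.finite(config$snr_db)) f <- add_noise(f, config$snr_db, config$seed)
    f
  })
  write_frame_csv(frame, paths$measurements)

  fit <- stage("reconstruct",
               eit_reconstruct(frame, prot, z0 = config$z0,
                               lambda = config$lambda,
                               max_iter = config$max_iter,
                               delta_tol = config$delta_tol,
                               ground = ground))
  write_grid_csv(fit$grid, paths$recon_grid)
  jsonlite::write_json(fit$trace, paths$trace, digits = NA, auto_unbox = TRUE)

  tomo <- stage("render", tomogram(fit))
  write_tomogram(tomo, paths$image_csv, paths$image_png)

  manifest <- list(
    artifacts = lapply(paths[setdiff(names(paths), "manifest")], normalizePath),
    settings = list(s = config$s, electrodes = nrow(config$electrodes),
                    amplitude_A = config$amplitude_A,
                    frequency_khz = config$frequency_khz,
                    snr_db = config$snr_db, seed = config$seed,
                    z0 = config$z0, lambda = config$lambda,
                    max_iter = config$max_iter),
    n_measurements = nrow(frame),
    trace = fit$trace,
    converged_by = fit$converged_by)
  jsonlite::write_json(manifest, paths$manifest, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, truth = truth, frame = frame, tomogram = tomo,
                 manifest = manifest, paths = paths))
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value file mirroring the arguments of [run_config()]; the
#' phantom is given either as `scenario: <name>` or as explicit
#' `background_ohms` plus an `inclusions` list of maps with keys `shape`
#' (circle/rectangle), `center`, `radius` or `half_extents`, and `ohms`.
#' Electrode template points go under `electrodes` as a list of `[a, b]`
#' pairs (defaulting to [default_electrodes()]).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  s <- if (is.null(y[["s"]])) 26L else y[["s"]]
  phantom <- if (!is.null(y[["scenario"]])) {
    y[["scenario"]]
  } else {
    incs <- lapply(y[["inclusions"]], function(i) {
      if (identical(i$shape, "rectangle")) {
        rect_inclusion(unlist(i$center), unlist(i$half_extents), i$ohms)
      } else {
        circle_inclusion(unlist(i$center), i$radius, i$ohms)
      }
    })
    phantom_spec(s, y[["background_ohms"]], incs,
                 if (is.null(y[["extent_mm"]])) 130 else y[["extent_mm"]])
  }
  electrodes <- if (is.null(y[["electrodes"]])) {
    default_electrodes()
  } else {
    m <- do.call(rbind, y[["electrodes"]])
    data.frame(a = m[, 1], b = m[, 2])
  }
  args <- list(s = s, electrodes = electrodes, phantom = phantom)
  for (nm in c("amplitude_A", "frequency_khz", "snr_db", "seed", "z0",
               "lambda", "max_iter", "delta_tol")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(run_config, args)
}
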