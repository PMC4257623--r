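# Plain-text interchange formats and the end-to-end pipeline.
#
# Spot lists are CSV with header image_id,x_mm,y_mm,intensity,h,k,l and
# optional extension columns delta_psi_rad,d_angstrom; coordinates are
# detector millimetres relative to the beam centre, h,k,l blank when
# unassigned. Geometry configs and crystal models are YAML.

SPOT_COLUMNS <- c("image_id", "x_mm", "y_mm", "intensity", "h", "k", "l")

#' Read and write spot lists
#'
#' Lossless CSV round trip of spot tables, including unassigned indices
#' (blank h,k,l) and any extension columns.
#'
#' @param path File path.
#' @param spots Spot data frame.
#' @param det Optional [detector()]; when given, positions further than ten
#'   panel widths from the centre trigger a unit-mismatch warning.
#' @return `read_spot_list()` returns the spot data frame.
#' @export
read_spot_list <- function(path, det = NULL) {
  spots <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed spot list '", path, "': ",
                             conditionMessage(e)))
  missing <- setdiff(SPOT_COLUMNS, names(spots))
  if (length(missing)) {
    stop("spot list '", path, "' lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  for (cn in c("x_mm", "y_mm", "intensity", "h", "k", "l")) {
    v <- spots[[cn]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop("malformed value in column ", cn, " at line ", bad[1L] + 1L,
             " of '", path, "'")
      }
      spots[[cn]] <- as.numeric(v)
    }
    if (all(is.na(v))) spots[[cn]] <- as.numeric(v)
  }
  if (!is.null(det)) {
    lim <- 10 * max(det$n_fast, det$n_slow) * det$pixel_size
    if (any(abs(spots$x_mm) > lim | abs(spots$y_mm) > lim, na.rm = TRUE)) {
      warning("spot positions far outside the detector: check units (mm expected)")
    }
  }
  spots
}

#' @rdname read_spot_list
#' @export
write_spot_list <- function(spots, path) {
  extra <- setdiff(names(spots), SPOT_COLUMNS)
  spots <- spots[, c(SPOT_COLUMNS, extra), drop = FALSE]
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write geometry configurations
#'
#' YAML schema: `wavelength_angstrom`, `s0_hat` (unit 3-vector),
#' `distance_mm`, `pixel_size_mm`, `n_fast`, `n_slow`, `beam_center_mm`
#' (position of the direct-beam intersection on the panel, mm from the panel
#' corner; detector x,y parallel to lab x,y, right-handed frame with the
#' beam along -z).
#'
#' @param path File path.
#' @param beam A [beam()].
#' @param det A [detector()].
#' @return `read_geometry()` returns `list(beam = , det = )`.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  g <- yaml::read_yaml(path)
  need <- c("wavelength_angstrom", "distance_mm", "pixel_size_mm",
            "n_fast", "n_slow")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("geometry config lacks fields: ",
                         paste(miss, collapse = ", "))
  b <- beam(g$wavelength_angstrom,
            if (is.null(g$s0_hat)) c(0, 0, -1) else as.numeric(g$s0_hat))
  d <- if (is.null(g$beam_center_mm)) {
    detector(g$distance_mm, g$pixel_size_mm, g$n_fast, g$n_slow)
  } else {
    detector(g$distance_mm, g$pixel_size_mm, g$n_fast, g$n_slow,
             as.numeric(g$beam_center_mm))
  }
  list(beam = b, det = d)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(beam, det, path) {
  yaml::write_yaml(list(wavelength_angstrom = beam$wavelength,
                        s0_hat = beam$s0_hat,
                        distance_mm = det$distance,
                        pixel_size_mm = det$pixel_size,
                        n_fast = det$n_fast, n_slow = det$n_slow,
                        beam_center_mm = det$beam_center),
                   path)
  invisible(path)
}

#' Read and write crystal models
#'
#' YAML record of the cell (Angstrom/degrees), orientation matrix and
#' symmetry tag.
#'
#' @param model A [crystal_model()].
#' @param path File path.
#' @return `read_crystal_model()` returns a [crystal_model()].
#' @export
write_crystal_model <- function(model, path) {
  cl <- as.numeric(model$cell)
  yaml::write_yaml(list(cell = list(a = cl[1L], b = cl[2L], c = cl[3L],
                                    alpha = cl[4L], beta = cl[5L],
                                    gamma = cl[6L]),
                        orientation = lapply(1:3, function(i)
                          as.numeric(model$U[i, ])),
                        symmetry = model$symmetry),
                   path, precision = 12L)
  invisible(path)
}

#' @rdname write_crystal_model
#' @export
read_crystal_model <- function(path) {
  m <- yaml::read_yaml(path)
  U <- do.call(rbind, lapply(m$orientation, as.numeric))
  crystal_model(do.call(unit_cell, m$cell), nearest_rotation(U), m$symmetry)
}

#' Run the still-shot modelling pipeline
#'
#' Executes, per image: simulation (or spot-list input), index assignment
#' (optional when true indices are present), two-stage refinement, mosaic
#' envelope fitting, spot prediction and scoring against the reference set.
#' Failures are recorded per image and the pipeline continues.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{n_images}{number of simulated stills (simulation mode).}
#'     \item{seed}{base seed; image i uses `seed + i`.}
#'     \item{noise_sigma_mm}{centroid jitter (default 0.03).}
#'     \item{max_rot_deg, max_cell_rel}{start perturbation bounds
#'       (defaults 0.5 deg, 0.005).}
#'     \item{stage1_target, stage2_target}{refinement targets
#'       (default both `"hybrid"`).}
#'     \item{fit_method, epsilon}{mosaic fit settings (defaults `"ml"`, 10).}
#'     \item{reassign}{re-run index assignment from the perturbed start
#'       instead of using true indices (default FALSE).}
#'     \item{output_dir}{optional directory; per-image spot CSVs, models and
#'       the resolved config are written there.}
#'   }
#' @return An object of class `still_pipeline`: per-image results and
#'   aggregate statistics (rms/median misorientation, mean fitted mosaicity
#'   and block size, pooled false-prediction and unmodeled fractions).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cf <- utils::modifyList(list(n_images = 10L, seed = 1L,
                               noise_sigma_mm = 0.03, max_rot_deg = 0.5,
                               max_cell_rel = 0.005,
                               stage1_target = "hybrid",
                               stage2_target = "hybrid",
                               fit_method = "ml", epsilon = 10,
                               reassign = FALSE, output_dir = NULL),
                          config)
  pc <- psi_conditions()
  out_dir <- cf$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cf[setdiff(names(cf), "output_dir")],
                     file.path(out_dir, "config.yaml"))
    write_geometry(pc$beam, pc$det, file.path(out_dir, "geometry.yaml"))
  }
  images <- vector("list", cf$n_images)
  for (i in seq_len(cf$n_images)) {
    images[[i]] <- tryCatch({
      scene <- simulate_still(noise_sigma_mm = cf$noise_sigma_mm,
                              seed = cf$seed + i)
      start <- random_start(scene$model, cf$max_rot_deg, cf$max_cell_rel,
                            seed = cf$seed + i + 500000L)
      spots <- scene$spots
      if (isTRUE(cf$reassign)) {
        spots <- assign_indices(spots, start, scene$beam, scene$det)
        spots <- spots[!is.na(spots$h), , drop = FALSE]
      }
      fit <- run_protocol(spots, start, scene$beam, scene$det,
                          stage1_target = cf$stage1_target,
                          stage2_target = cf$stage2_target)
      mis <- misorientation_angle(fit$model, scene$model)
      rec <- fit$per_spot[fit$per_spot$ok, ]
      mf <- if (nrow(rec) >= 10L) {
        fit_mosaic(rec, method = cf$fit_method, epsilon = cf$epsilon)
      } else NULL
      sc <- if (!is.null(mf)) {
        pred <- predict_spots(fit$model, scene$beam, scene$det, mf$envelope,
                              min(scene$d_range), max(scene$d_range))
        score_prediction(pred, scene$spots)
      } else NULL
      if (!is.null(out_dir)) {
        write_spot_list(scene$spots,
                        file.path(out_dir, sprintf("image_%03d_spots.csv", i)))
        write_crystal_model(fit$model,
                            file.path(out_dir, sprintf("image_%03d_model.yaml", i)))
      }
      list(ok = TRUE, seed = scene$seed, n_spots = nrow(spots),
           misorientation = mis$angle, components = mis$components,
           eta_half_deg = if (!is.null(mf)) coef(mf)[["eta_halfwidth_deg"]]
             else NA_real_,
           d_eff = if (!is.null(mf)) coef(mf)[["d_eff_angstrom"]] else NA_real_,
           false_fraction = if (!is.null(sc)) sc$totals$false_fraction
             else NA_real_,
           unmodeled_fraction = if (!is.null(sc)) sc$totals$unmodeled_fraction
             else NA_real_,
           converged = fit$converged)
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  }
  okimg <- Filter(function(x) isTRUE(x$ok), images)
  mis <- vapply(okimg, `[[`, 0, "misorientation")
  aggregate <- list(
    n_images = cf$n_images, n_ok = length(okimg),
    rms_misorientation_deg = sqrt(mean(mis^2)),
    median_misorientation_deg = stats::median(mis),
    frac_within_0.1_deg = mean(mis < 0.1),
    mean_eta_half_deg = mean(vapply(okimg, `[[`, 0, "eta_half_deg"),
                             na.rm = TRUE),
    mean_d_eff = 1 / mean(1 / vapply(okimg, `[[`, 0, "d_eff"), na.rm = TRUE),
    mean_false_fraction = mean(vapply(okimg, `[[`, 0, "false_fraction"),
                               na.rm = TRUE),
    mean_unmodeled_fraction = mean(vapply(okimg, `[[`, 0, "unmodeled_fraction"),
                                   na.rm = TRUE))
  res <- structure(list(config = cf, images = images, aggregate = aggregate),
                   class = "still_pipeline")
  if (!is.null(out_dir)) {
    yaml::write_yaml(aggregate, file.path(out_dir, "report.yaml"))
  }
  res
}

#' @export
print.still_pipeline <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Still pipeline: %d/%d images processed (targets %s/%s, fit %s)\n",
              a$n_ok, a$n_images, x$config$stage1_target,
              x$config$stage2_target, x$config$fit_method))
  cat(sprintf("  misorientation rms %.4f deg, median %.4f deg, %.1f%% within 0.1 deg\n",
              a$rms_misorientation_deg, a$median_misorientation_deg,
              100 * a$frac_within_0.1_deg))
  cat(sprintf("  mean half-width mosaicity %.4f deg, block size %.0f A\n",
              a$mean_eta_half_deg, a$mean_d_eff))
  cat(sprintf("  false predictions %.1f%%, unmodeled spots %.1f%%\n",
              100 * a$mean_false_fraction, 100 * a$mean_unmodeled_fraction))
  invisible(x)
}
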