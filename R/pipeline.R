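## tiny FNV-1a hash for stamping reports with their configuration
fnv1a <- function(x) {
  b <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 216613626
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Re-express a linkage in a new ground frame
#'
#' Rigidly transforms the linkage (ground pivots and drive map) by a
#' planar pose: the new ground frame is such that `pose` maps old ground
#' coordinates into the new ones.
#'
#' @param linkage a [fourbar_linkage()].
#' @param pose an [se2_pose()] applied to the linkage geometry.
#' @return the transformed [fourbar_linkage()].
#' @export
transform_linkage <- function(linkage, pose) {
  drv <- linkage$drive
  new_drive <-
    if (is.null(drv)) NULL
    else if (is.function(drv)) {
      force(drv)
      local({
        dth <- pose$theta
        function(f) drv(f) + dth
      })
    } else c(drv[1] + pose$theta, drv[2])
  fourbar_linkage(ground_a = se2_apply(pose, linkage$ground_a),
                  ground_b = se2_apply(pose, linkage$ground_b),
                  len_input = linkage$len_input,
                  len_coupler = linkage$len_coupler,
                  len_follower = linkage$len_follower,
                  coupler_offset = linkage$coupler_offset,
                  branch = linkage$branch,
                  angle_range = if (is.null(linkage$angle_range)) NULL
                                else linkage$angle_range + pose$theta,
                  drive = new_drive)
}

## project a 3D bone-frame registration into the fitted plane as a planar
## pose (error if the projected frame is left-handed, i.e. the plane
## normal opposes the bone frame's out-of-plane axis)
project_registration <- function(registration, plane) {
  o <- project_trajectory(rbind(registration$origin), plane)$uv[1, ]
  exv <- project_trajectory(rbind(registration$origin + registration$ex),
                            plane)$uv[1, ] - o
  eyv <- project_trajectory(rbind(registration$origin + registration$ey),
                            plane)$uv[1, ] - o
  if (exv[1] * eyv[2] - exv[2] * eyv[1] <= 0)
    stop("bone frame projects left-handed onto the fitted plane; ",
         "check the lateral direction hint")
  se2_pose(rad2deg(atan2(exv[2], exv[1])), o)
}

#' Fit the four-bar knee model from a marker stream
#'
#' The model-identification half of the pipeline: marker streams are
#' turned into flexion samples and a main plane ([analyze_motion()]), the
#' tracker-centre path is interpolated over flexion
#' ([interpolate_flexion_path()]), a four-bar is synthesised to the path
#' ([synthesize_fourbar()]), its drive map refined
#' ([refine_drive_map()]), the tibia attachment estimated
#' ([fit_tibia_attachment()]), and everything is re-expressed in the
#' femur bone (sagittal) frame using the CT-to-tracker registration.
#'
#' @param frames marker stream data.frame (see [read_marker_csv()]).
#' @param registration 3D pose of the femur sagittal frame in camera
#'   coordinates at the reference frame: list with `origin`, `ex`, `ey`,
#'   `ez` (the synthetic stand-in for CT registration).
#' @param synthesis a [synthesis_config()].
#' @param n_path number of interpolated path samples used as synthesis
#'   targets.
#' @param reference_frame extension-reference frame id (default 0).
#' @param path_smoothing smoothing passed to [interpolate_flexion_path()].
#' @return list of class `knee_fit`: `motion`, `path`, `synthesis`
#'   (report), `linkage` (in the femur sagittal frame, refined drive),
#'   `attachment` (tibia sagittal frame on the coupler), `K` (femur frame
#'   in plane coordinates), `attachment_rms_mm`.
#' @export
fit_knee_model <- function(frames, registration,
                           synthesis = synthesis_config(),
                           n_path = 41L, reference_frame = 0L,
                           path_smoothing = NULL) {
  mo <- analyze_motion(frames, reference_frame = reference_frame,
                       lateral_hint = registration$ez,
                       ap_hint = registration$ex)
  sm <- mo$samples
  path <- interpolate_flexion_path(cbind(sm$u_mm, sm$v_mm), sm$flexion_deg,
                                   n_out = n_path,
                                   smoothing = path_smoothing)
  ## measured planar body poses along the pooled path: the tibia rotates
  ## by the flexion angle about the plane normal
  poses <- lapply(seq_along(path$angle), function(i)
    se2_pose(path$angle[i], path$points[i, ]))
  syn <- synthesize_fourbar_poses(poses, path$angle, synthesis)
  lk <- syn$linkage
  ## registration chain: coupler -> measured tibia frame -> (via the
  ## extension reference and the CT frames) -> tibia sagittal frame
  K <- project_registration(registration, mo$plane)
  B0r <- registration$tibia_extension_pose2d
  B0 <- se2_pose(B0r$theta, as.numeric(B0r$t))
  P0 <- poses[[which.min(path$angle)]]
  lk_knee <- transform_linkage(lk, se2_inverse(K))
  att_knee <- se2_compose(syn$attachment,
                          se2_compose(se2_inverse(P0),
                                      se2_compose(K, B0)))
  structure(list(motion = mo, path = path, synthesis = syn,
                 linkage = lk_knee, attachment = att_knee, K = K,
                 attachment_rms_mm = syn$rms_mm),
            class = "knee_fit")
}

#' Run the full synthetic demo experiment
#'
#' Generates the frozen synthetic knee, simulates noise-free tracker
#' streams over repeated flexion-extension cycles, fits the planar
#' four-bar knee model from the streams, applies the measured-resection
#' plan to the synthetic femur solid, and computes the normalised
#' femoral rollback curve with the natural two-arc condyle (pre-op) and
#' with the single-arc implant condyle (post-op) over the flexion grid --
#' everything the pre/post comparison needs, from one seed.
#'
#' @param seed integer seed controlling synthesis multi-starts (and any
#'   noise, if enabled).
#' @param grid flexion grid for the rollback curves (degrees).
#' @param extension_angle extension reference of the model (degrees,
#'   default 20: the model's extended position).
#' @param params generator parameters (frozen defaults).
#' @param noise a [noise_model()]; the demo default is noise-free.
#' @param n_starts synthesis multi-starts.
#' @param n_cycles flexion-extension cycles simulated.
#' @param resect also run the measured-resection stage on the synthetic
#'   femur mesh (default TRUE).
#' @return list of class `knee_demo_report`; notable elements:
#'   `rollback_pre`, `rollback_post` ([rollback_curve()]s),
#'   `comparison` (see [compare_rollback()]), `fit` (the `knee_fit`),
#'   `truth` (ground-truth curves from the generator linkage),
#'   `resection` (removed volumes, mm^3), `config_hash`, `seed`.
#' @export
run_demo <- function(seed = 1L, grid = seq(20, 90, by = 1),
                     extension_angle = 20,
                     params = synthetic_knee_params(seed = seed),
                     noise = noise_model(marker_sd = 0, shell_drift_amp = 0,
                                         seed = seed),
                     n_starts = 40L, n_cycles = 3L, resect = TRUE) {
  knee <- make_ground_truth_knee(params)
  up <- seq(0, params$flexion_max, by = 2)
  cycle <- c(up, rev(up)[-1][-length(up) + 1])
  profile <- c(rep(cycle, n_cycles), 0)
  sim <- simulate_tracker_stream(knee, c(0, profile[-1]), noise)
  cfg <- synthesis_config(n_starts = n_starts, seed = seed,
                          tolerance = 0.01, lock_orientation = TRUE)
  fit <- fit_knee_model(sim$frames, sim$registration, synthesis = cfg)
  pre <- rollback_curve(fit$linkage, knee$natural_profile, knee$plateau,
                        fit$attachment, grid, extension_angle)
  post <- rollback_curve(fit$linkage, knee$implant_profile, knee$plateau,
                         fit$attachment, grid, extension_angle)
  cmp <- compare_rollback(pre, post)
  truth_pre <- rollback_curve(knee$linkage, knee$natural_profile,
                              knee$plateau, knee$tibia_attachment, grid,
                              extension_angle)
  truth_post <- rollback_curve(knee$linkage, knee$implant_profile,
                               knee$plateau, knee$tibia_attachment, grid,
                               extension_angle)
  res <- NULL
  if (resect) {
    femur <- make_synthetic_femur_mesh(params)
    axes <- anatomical_axes(mechanical_axis = c(0, 1, 0), tea = c(0, 0, 1),
                            ap_axis = c(-1, 0, 0), pca = c(0, 0, 1),
                            origin = c(10, -20, 0))
    planes <- build_resection_planes(axes, resection_plan())
    rr <- apply_resection(femur, planes[1:5])
    res <- list(removed_mm3 = rr$removed,
                femur_volume_mm3 = mesh_volume(femur),
                resected_volume_mm3 = mesh_volume(rr$mesh))
  }
  cfg_stamp <- list(seed = seed, grid = range(grid),
                    extension_angle = extension_angle,
                    params = unclass(params), n_starts = n_starts,
                    n_cycles = n_cycles,
                    noise = unclass(noise))
  structure(list(rollback_pre = pre, rollback_post = post,
                 comparison = cmp, fit = fit, truth = list(
                   pre = truth_pre, post = truth_post, knee = knee),
                 resection = res, seed = seed,
                 config_hash = fnv1a(cfg_stamp)),
            class = "knee_demo_report")
}

#' @export
print.knee_demo_report <- function(x, ...) {
  cmp <- x$comparison
  cat("<knee_demo_report>\n")
  cat(sprintf("  synthesis rms %.4g mm (path), attachment rms %.4g mm\n",
              x$fit$synthesis$rms_mm, x$fit$attachment_rms_mm))
  cat(sprintf("  pre-op  max rollback %.2f mm at %.0f deg\n",
              cmp$max_pre, cmp$angle_at_max_pre))
  cat(sprintf("  post-op max rollback %.2f mm at %.0f deg\n",
              cmp$max_post, cmp$angle_at_max_post))
  cat(sprintf("  post/pre ratio %.3f\n", cmp$ratio))
  if (!is.null(x$resection))
    cat(sprintf("  femoral resection removed %.0f mm^3 in %d cuts\n",
                sum(x$resection$removed_mm3),
                length(x$resection$removed_mm3)))
  cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  invisible(x)
}

#' Write a demo/pipeline report to JSON
#' @param report a `knee_demo_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  cmp <- report$comparison
  x <- list(seed = report$seed, config_hash = report$config_hash,
            synthesis_rms_mm = report$fit$synthesis$rms_mm,
            attachment_rms_mm = report$fit$attachment_rms_mm,
            max_pre_mm = cmp$max_pre,
            angle_at_max_pre_deg = cmp$angle_at_max_pre,
            max_post_mm = cmp$max_post,
            angle_at_max_post_deg = cmp$angle_at_max_post,
            ratio = cmp$ratio,
            rollback_pre = list(flexion_deg = report$rollback_pre$flexion,
                                displacement_mm =
                                  report$rollback_pre$displacement),
            rollback_post = list(flexion_deg = report$rollback_post$flexion,
                                 displacement_mm =
                                   report$rollback_post$displacement),
            resection_removed_mm3 =
              as.list(report$resection$removed_mm3))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot pre- and post-operative rollback curves
#'
#' Flexion angle against normalised contact-point displacement for both
#' models, the standard pre-versus-post rollback figure.
#'
#' @param pre,post [rollback_curve()] objects.
#' @param main plot title.
#' @export
plot_rollback <- function(pre, post, main = "Femoral rollback") {
  yl <- range(0, pre$displacement, post$displacement)
  graphics::plot(pre$flexion, pre$displacement, type = "l", lwd = 2,
                 col = "firebrick", ylim = yl,
                 xlab = "flexion angle (deg)",
                 ylab = "contact AP displacement (mm)", main = main)
  graphics::lines(post$flexion, post$displacement, lwd = 2,
                  col = "steelblue")
  graphics::abline(h = 0, col = "grey60", lty = 3)
  graphics::legend("topright", c("pre-op (natural)", "post-op (implant)"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(NULL)
}

#' Run the pipeline from a config file
#'
#' File-driven front end: reads a JSON config, runs the synthetic
#' generator and/or the fitting pipeline, and writes all artifacts
#' (marker CSV, plane JSON, linkage JSON, rollback CSV, comparison JSON,
#' rollback plot) to the output directory.
#'
#' @param config path to a JSON config or an equivalent named list.
#'   Recognised fields: `seed`, `out_dir`, `grid` (min, max, step),
#'   `extension_angle`, `n_starts`, `n_cycles`, `noise`
#'   (marker_sd, shell_drift_amp), `params` (overrides for
#'   [synthetic_knee_params()]), `plot` (logical).
#' @return the `knee_demo_report`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- if (is.null(config$grid)) seq(20, 90, 1)
          else seq(config$grid[1], config$grid[2], by = config$grid[3])
  ext <- if (is.null(config$extension_angle)) 20 else config$extension_angle
  prm <- synthetic_knee_params(seed = seed)
  if (!is.null(config$params))
    prm <- do.call(synthetic_knee_params,
                   utils::modifyList(c(unclass(prm)), config$params))
  nz <- if (is.null(config$noise)) noise_model(0, 0, seed = seed)
        else noise_model(config$noise$marker_sd,
                         config$noise$shell_drift_amp, seed = seed)
  ns <- if (is.null(config$n_starts)) 40L else as.integer(config$n_starts)
  nc <- if (is.null(config$n_cycles)) 3L else as.integer(config$n_cycles)
  rep <- run_demo(seed = seed, grid = grid, extension_angle = ext,
                  params = prm, noise = nz, n_starts = ns, n_cycles = nc)
  write_report_json(rep, file.path(out, "report.json"))
  write_plane_json(rep$fit$motion$plane, file.path(out, "plane.json"))
  write_linkage_json(rep$fit$linkage, file.path(out, "linkage.json"))
  write_rollback_csv(list(pre = rep$rollback_pre, post = rep$rollback_post),
                     file.path(out, "rollback.csv"))
  utils::write.csv(rep$fit$motion$samples,
                   file.path(out, "flexion_samples.csv"), row.names = FALSE)
  if (isTRUE(config$plot)) {
    grDevices::png(file.path(out, "rollback.png"), 800, 600)
    plot_rollback(rep$rollback_pre, rep$rollback_post)
    grDevices::dev.off()
  }
  invisible(rep)
}
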