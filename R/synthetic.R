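# Synthetic forearm-image generator: paired pre/post visible+thermal bundles
# with exact ground truth (marker centres, inter-series rigid transform,
# per-site labels).  The scene is an analytic function of continuous scene
# coordinates; the post series is rendered through the inverse pose transform,
# so ground-truth marker centres and the true transform are exact by
# construction rather than quantized by warping a raster.

#' Scene configuration for the synthetic generator
#'
#' Defaults describe a half-resolution forearm (512 x 385, width x height,
#' half of the native 1024 x 770 acquisition size) with a 2 x 4 grid of eight
#' highlighter markers: seven circles plus one square histamine-control mark.
#' Marker radii are drawn so that detected bounding boxes average about
#' 85 native-scale pixels (sd ~6), matching the segment-size statistics the
#' contour filter is built on.  Length-valued defaults scale proportionally
#' with `image_size`.
#'
#' @param image_size `(height, width)` in pixels.
#' @param grid `(n_lines, n_per_line)`; the reading protocol uses `c(2, 4)`.
#' @param marker_radius_range Range of marker ring radii, pixels.
#' @param inter_marker_spacing Column spacing between neighbouring sites, pixels.
#' @param line_spacing Row spacing between the two lines, pixels.
#' @param position_jitter Maximum per-marker positional jitter, pixels.
#' @param pose_max_rotation Maximum forearm rotation between series, degrees.
#' @param pose_max_translation Maximum translation between series, pixels.
#' @param hotspot_amplitude Peak temperature rise of a reaction, degC.
#' @param hotspot_sigma Gaussian spread of a reaction hot spot, pixels.
#' @param baseline_temp Baseline skin temperature, degC.
#' @param noise_sd Thermal pixel noise standard deviation, degC.
#' @param visible_noise_sd Visible-channel pixel noise standard deviation.
#' @param hair_density Number of hair streaks (dark in visible, cool in thermal).
#' @param vessel_count Number of subdermal vessels (warm ridges in thermal).
#' @param prevalence Probability that a non-control site is positive.
#' @param marker_dropout Probability a marker is drawn too faintly to detect.
#' @param hive_contrast Visible-channel amplitude of the wheal at positive
#'   sites (post series only); low by default, reflecting how subtle wheals
#'   are against skin.
#' @param hive_sigma Spatial spread of the wheal, pixels.
#' @param seed Integer generator seed.
#' @return An object of class `"scene_config"`.
#' @export
scene_config <- function(image_size = c(385, 512),
                         grid = c(2, 4),
                         marker_radius_range = NULL,
                         inter_marker_spacing = NULL,
                         line_spacing = NULL,
                         position_jitter = NULL,
                         pose_max_rotation = 5,
                         pose_max_translation = NULL,
                         hotspot_amplitude = 1.5,
                         hotspot_sigma = NULL,
                         baseline_temp = 33,
                         noise_sd = 0.05,
                         visible_noise_sd = 0.01,
                         hair_density = 12,
                         vessel_count = 3,
                         prevalence = 0.3,
                         marker_dropout = 0.1,
                         hive_contrast = 0.08,
                         hive_sigma = NULL,
                         seed = 1) {
  s <- image_size[2] / 512  # length scale relative to the half-size default
  if (is.null(marker_radius_range)) marker_radius_range <- c(19, 24) * s
  if (is.null(inter_marker_spacing)) inter_marker_spacing <- 110 * s
  if (is.null(line_spacing)) line_spacing <- 0.36 * image_size[1]
  if (is.null(position_jitter)) position_jitter <- 5 * s
  if (is.null(pose_max_translation)) pose_max_translation <- 15 * s
  if (is.null(hotspot_sigma)) hotspot_sigma <- 12 * s
  if (is.null(hive_sigma)) hive_sigma <- 9 * s
  cfg <- list(image_size = as.integer(image_size), grid = as.integer(grid),
              marker_radius_range = marker_radius_range,
              inter_marker_spacing = inter_marker_spacing,
              line_spacing = line_spacing, position_jitter = position_jitter,
              pose_max_rotation = pose_max_rotation,
              pose_max_translation = pose_max_translation,
              hotspot_amplitude = hotspot_amplitude, hotspot_sigma = hotspot_sigma,
              baseline_temp = baseline_temp, noise_sd = noise_sd,
              visible_noise_sd = visible_noise_sd,
              hair_density = as.integer(hair_density),
              vessel_count = as.integer(vessel_count),
              prevalence = prevalence, marker_dropout = marker_dropout,
              hive_contrast = hive_contrast, hive_sigma = hive_sigma,
              ring_width = 4 * s, seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  if (cfg$prevalence < 0 || cfg$prevalence > 1) stop_thermoprick("prevalence must be in [0, 1]")
  if (cfg$marker_dropout < 0 || cfg$marker_dropout >= 1)
    stop_thermoprick("marker_dropout must be in [0, 1)")
  if (cfg$hotspot_amplitude <= 0) stop_thermoprick("hotspot_amplitude must be positive")
  if (cfg$hair_density < 0 || cfg$vessel_count < 0) stop_thermoprick("counts must be >= 0")
  margin <- max(cfg$marker_radius_range) + cfg$position_jitter + cfg$ring_width + 2
  span_c <- (cfg$grid[2] - 1) * cfg$inter_marker_spacing
  span_r <- (cfg$grid[1] - 1) * cfg$line_spacing
  if (span_c + 2 * margin > w || span_r + 2 * margin > h)
    stop_thermoprick("configuration error: ", cfg$grid[1], "x", cfg$grid[2],
                     " marker grid does not fit in a ", h, "x", w,
                     " image with spacing ", round(cfg$inter_marker_spacing),
                     " and margin ", round(margin))
  invisible(cfg)
}

# nominal (un-jittered) grid centres: rows = lines, ordered left to right
grid_centres <- function(cfg) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  lines <- h / 2 + (seq_len(cfg$grid[1]) - (cfg$grid[1] + 1) / 2) * cfg$line_spacing
  cols <- w / 2 + (seq_len(cfg$grid[2]) - (cfg$grid[2] + 1) / 2) * cfg$inter_marker_spacing
  list(rows = lines, cols = cols)
}

random_patient <- function(id, seed) {
  with_seed(seed, {
    patient_record(
      patient_id = id,
      sex = sample(c("M", "F"), 1),
      age = round(runif(1, 18, 70)),
      weight = round(runif(1, 50, 110), 1),
      height = round(runif(1, 150, 200)),
      body_temperature = round(min(38, max(35.5, rnorm(1, 36.6, 0.25))), 2))
  })
}

random_polyline <- function(start, angle, length, n = 6, drift = 0.3) {
  step <- length / (n - 1)
  pts <- matrix(0, n, 2)
  pts[1, ] <- start
  for (i in 2:n) {
    angle <- angle + rnorm(1, 0, drift)
    pts[i, ] <- pts[i - 1, ] + step * c(sin(angle), cos(angle))
  }
  pts
}

marker_palette <- rbind(c(0.10, 0.35, 0.15),   # green highlighter
                        c(0.10, 0.20, 0.55),   # blue
                        c(0.35, 0.12, 0.45))   # purple

#' Generate one synthetic forearm case
#'
#' Renders the pre- and post-application visible/thermal bundles of a single
#' forearm with full ground truth.  Positive sites (always including the
#' histamine control, never the negative control) receive a truncated
#' isotropic Gaussian temperature bump in the post-series thermal image and a
#' faint wheal in the post-series visible image.  The post series is the same
#' analytic scene observed through a random rigid pose change, so applying
#' `true_transform` to pre-series marker centres reproduces post-series
#' centres exactly.  Deterministic given `(config$seed, patient_seed, forearm)`.
#'
#' @param config A [scene_config()].
#' @param patient_seed Integer distinguishing patients.
#' @param patient Optional [patient_record()]; generated randomly if `NULL`.
#' @param forearm `"L"` or `"R"`.
#' @param labels Optional length-8 0/1 override of site labels (ordered line
#'   by line, left to right), e.g. to force an all-negative forearm.
#' @param dropped Optional integer override of which marker indices are
#'   rendered at dropout (unreadable) contrast.
#' @param render If `FALSE`, skip image rendering and return ground truth only
#'   (used for large label-statistics checks).
#' @return An object of class `"synthetic_case"`: `patient`, `pre`, `post`
#'   ([image_bundle()]s), `annotations` (pre frame), `annotations_post`,
#'   `true_transform` ([planar_transform()], pre to post), `labels`,
#'   `dropped_markers`, `site_meta`, `forearm`, `case_id`.
#' @export
generate_case <- function(config, patient_seed, patient = NULL, forearm = "L",
                          labels = NULL, dropped = NULL, render = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  seed <- derive_seed(config$seed, patient_seed, 7L + (forearm == "R"))
  if (is.null(patient))
    patient <- random_patient(paste0("P", patient_seed), derive_seed(config$seed, patient_seed, 999L))
  with_seed(seed, {
    h <- config$image_size[1]; w <- config$image_size[2]
    g <- grid_centres(config)
    n_sites <- config$grid[1] * config$grid[2]
    meta <- expand.grid(pos = seq_len(config$grid[2]), line = seq_len(config$grid[1]))
    meta <- meta[, c("line", "pos")]
    meta$row <- g$rows[meta$line] + runif(n_sites, -1, 1) * config$position_jitter
    meta$col <- g$cols[meta$pos] + runif(n_sites, -1, 1) * config$position_jitter
    meta$radius <- runif(n_sites, config$marker_radius_range[1], config$marker_radius_range[2])

    hist_idx <- sample.int(n_sites, 1)
    neg_idx <- sample(setdiff(seq_len(n_sites), hist_idx), 1)
    meta$role <- "allergen"
    meta$role[hist_idx] <- "histamine"
    meta$role[neg_idx] <- "negative_control"
    meta$shape <- ifelse(meta$role == "histamine", "square", "circle")
    allergen_offset <- if (forearm == "L") 0 else 6
    ids <- character(n_sites)
    ids[hist_idx] <- "histamine"
    ids[neg_idx] <- "negative_control"
    ids[meta$role == "allergen"] <-
      sprintf("allergen%02d", allergen_offset + seq_len(sum(meta$role == "allergen")))
    meta$site_id <- ids

    lab <- rbinom(n_sites, 1, config$prevalence)
    lab[hist_idx] <- 1L
    lab[neg_idx] <- 0L
    if (!is.null(labels)) {
      stopifnot(length(labels) == n_sites, all(labels %in% c(0, 1)))
      lab <- as.integer(labels)
    }
    meta$label <- lab

    drop_draw <- which(runif(n_sites) < config$marker_dropout)
    if (is.null(dropped)) dropped <- drop_draw
    dropped <- as.integer(dropped)

    # rigid pre -> post pose change about the image centre
    theta <- runif(1, -1, 1) * config$pose_max_rotation * pi / 180
    trans <- runif(2, -1, 1) * config$pose_max_translation
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    Tm <- diag(3)
    Tm[1:2, 1:2] <- R
    Tm[1:2, 3] <- ctr - R %*% ctr + trans
    true_transform <- planar_transform(Tm, "rigid")

    # annotations: injection point at the site centre, marker point on the ring
    phi <- runif(n_sites, 0, 2 * pi)
    annotations <- lapply(seq_len(n_sites), function(i)
      marker_annotation(c(meta$row[i], meta$col[i]),
                        c(meta$row[i], meta$col[i]) +
                          meta$radius[i] * c(sin(phi[i]), cos(phi[i])),
                        meta$shape[i], meta$site_id[i]))
    post_centres <- transform_points(true_transform, cbind(meta$row, meta$col))
    post_marker <- transform_points(true_transform,
                                    t(vapply(annotations, `[[`, numeric(2), "marker_point")))
    annotations_post <- lapply(seq_len(n_sites), function(i)
      marker_annotation(post_centres[i, ], post_marker[i, ],
                        meta$shape[i], meta$site_id[i]))

    # scene texture, confounders, marker ink
    tex_vis <- cbind(runif(3, 0.01, 0.04), runif(3, -1, 1) * 2 * pi / runif(3, 120, 300),
                     runif(3, -1, 1) * 2 * pi / runif(3, 120, 300), runif(3, 0, 2 * pi))
    tex_th <- cbind(runif(2, 0.08, 0.25), runif(2, -1, 1) * 2 * pi / runif(2, 200, 450),
                    runif(2, -1, 1) * 2 * pi / runif(2, 200, 450), runif(2, 0, 2 * pi))
    s <- w / 512
    n_hair <- config$hair_density
    hair_pts <- matrix(0, 0, 2); hair_breaks <- integer(0)
    if (n_hair > 0) {
      pls <- lapply(seq_len(n_hair), function(i)
        random_polyline(c(runif(1, 1, h), runif(1, 1, w)), runif(1, 0, 2 * pi),
                        runif(1, 40, 120) * s))
      hair_breaks <- c(0L, cumsum(vapply(pls, nrow, 0L)))
      hair_pts <- do.call(rbind, pls)
    }
    ves_pts <- matrix(0, 0, 2); ves_breaks <- integer(0)
    if (config$vessel_count > 0) {
      pls <- lapply(seq_len(config$vessel_count), function(i)
        random_polyline(c(runif(1, 1, h), runif(1, 1, w)),
                        runif(1, -0.4, 0.4) + pi / 2,  # roughly along the arm
                        runif(1, 200, 420) * s, n = 8, drift = 0.12))
      ves_breaks <- c(0L, cumsum(vapply(pls, nrow, 0L)))
      ves_pts <- do.call(rbind, pls)
    }
    base_rgb <- c(0.80, 0.62, 0.50) * runif(1, 0.9, 1.05)
    ink <- marker_palette[sample.int(nrow(marker_palette), 1), ]
    contrast <- rep(0.85, n_sites)
    contrast[dropped] <- 0.12
    markers <- cbind(meta$row, meta$col, meta$radius, as.numeric(meta$shape == "square"),
                     contrast)
    marker_rgb <- matrix(rep(ink, each = n_sites), n_sites, 3)

    pos_idx <- which(lab == 1L)
    hotspots <- if (length(pos_idx)) {
      cbind(meta$row[pos_idx], meta$col[pos_idx],
            config$hotspot_amplitude * runif(length(pos_idx), 0.85, 1.15),
            config$hotspot_sigma * runif(length(pos_idx), 0.9, 1.1))
    } else matrix(0, 0, 4)
    hives <- if (length(pos_idx)) {
      cbind(meta$row[pos_idx], meta$col[pos_idx],
            config$hive_contrast * runif(length(pos_idx), 0.8, 1.2),
            config$hive_sigma * runif(length(pos_idx), 0.9, 1.1))
    } else matrix(0, 0, 4)

    pre <- post <- NULL
    if (render) {
      A_pre <- cbind(diag(2), c(0, 0))
      Tinv <- solve(Tm)
      A_post <- Tinv[1:2, ]
      none <- matrix(0, 0, 4)
      sc_pre <- cpp_render_scene(h, w, A_pre, base_rgb, config$baseline_temp,
                                 tex_vis, tex_th, markers, marker_rgb, config$ring_width,
                                 hair_pts, hair_breaks, 0.5, 1.1 * s, 0.3, 1.6 * s,
                                 ves_pts, ves_breaks, 0.35, 4 * s, none)
      sc_post <- cpp_render_scene(h, w, A_post, base_rgb, config$baseline_temp,
                                  tex_vis, tex_th, markers, marker_rgb, config$ring_width,
                                  hair_pts, hair_breaks, 0.5, 1.1 * s, 0.3, 1.6 * s,
                                  ves_pts, ves_breaks, 0.35, 4 * s, hotspots)
      vis_post <- cpp_add_hives(sc_post$visible, A_post, hives)
      # independent per-series pixel noise
      vpre <- sc_pre$visible
      if (config$visible_noise_sd > 0) {
        vpre <- array(pmin(1, pmax(0, vpre + rnorm(length(vpre), 0, config$visible_noise_sd))),
                      dim(sc_pre$visible))
        vis_post <- array(pmin(1, pmax(0, vis_post + rnorm(length(vis_post), 0, config$visible_noise_sd))),
                          dim(vis_post))
      }
      tpre <- sc_pre$thermal
      tpost <- sc_post$thermal
      if (config$noise_sd > 0) {
        tpre <- tpre + rnorm(length(tpre), 0, config$noise_sd)
        tpost <- tpost + rnorm(length(tpost), 0, config$noise_sd)
      }
      pre <- image_bundle(vpre, tpre, "pre")
      post <- image_bundle(vis_post, tpost, "post")
    }

    colnames(hotspots) <- colnames(hives) <- c("row", "col", "amplitude", "sigma")
    structure(list(patient = patient, pre = pre, post = post,
                   annotations = annotations, annotations_post = annotations_post,
                   true_transform = true_transform,
                   labels = stats::setNames(lab, meta$site_id),
                   dropped_markers = dropped, site_meta = meta,
                   hotspots = hotspots, hives = hives,
                   forearm = forearm,
                   case_id = paste0(patient$patient_id, "_", forearm)),
              class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case %s: %d sites, %d positive, %d dropped markers%s>\n",
              x$case_id, length(x$labels), sum(x$labels), length(x$dropped_markers),
              if (is.null(x$pre)) ", not rendered" else ""))
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Two forearm cases per patient with randomly drawn interview attributes.
#' Deterministic given `config$seed`.
#'
#' @param config A [scene_config()].
#' @param n_patients Number of patients (>= 1).
#' @inheritParams generate_case
#' @return A list with `cases` (length `2 * n_patients`), `labels` (data
#'   frame: `patient_id`, `forearm`, `site_id`, `role`, `label`), `patients`
#'   (data frame of attributes) and `config`.
#' @export
generate_cohort <- function(config, n_patients, render = TRUE) {
  stopifnot(inherits(config, "scene_config"), is_count(n_patients), n_patients >= 1)
  cases <- vector("list", 2 * n_patients)
  lab_rows <- vector("list", 2 * n_patients)
  pats <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    patient <- random_patient(sprintf("P%03d", p), derive_seed(config$seed, p, 999L))
    pats[[p]] <- data.frame(patient_id = patient$patient_id, sex = patient$sex,
                            age = patient$age, weight = patient$weight,
                            height = patient$height,
                            body_temperature = patient$body_temperature)
    for (arm in c("L", "R")) {
      k <- 2 * (p - 1) + (arm == "R") + 1
      cs <- generate_case(config, p, patient = patient, forearm = arm, render = render)
      cases[[k]] <- cs
      lab_rows[[k]] <- data.frame(patient_id = patient$patient_id, forearm = arm,
                                  site_id = cs$site_meta$site_id,
                                  role = cs$site_meta$role,
                                  label = cs$site_meta$label)
    }
  }
  list(cases = cases, labels = do.call(rbind, lab_rows),
       patients = do.call(rbind, pats), config = config)
}

#' Write a synthetic cohort to a directory
#'
#' Produces the on-disk layout the pipeline and CLI consume: per-case PNG +
#' float TIFF pairs for both series, per-case annotation JSON (pre and post
#' frames), a labels CSV, a patients CSV and a transforms JSON.
#'
#' @param cohort Result of [generate_cohort()] (rendered).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- list()
  for (cs in cohort$cases) {
    if (is.null(cs$pre)) stop_thermoprick("cohort was generated with render = FALSE")
    stem <- file.path(dir, cs$case_id)
    write_bundle(cs$pre, paste0(stem, "_pre_vis.png"), paste0(stem, "_pre_th.tif"))
    write_bundle(cs$post, paste0(stem, "_post_vis.png"), paste0(stem, "_post_th.tif"))
    write_annotations(cs$annotations, paste0(stem, "_pre_ann.json"))
    write_annotations(cs$annotations_post, paste0(stem, "_post_ann.json"))
    tr[[cs$case_id]] <- list(matrix = cs$true_transform$matrix, kind = cs$true_transform$kind)
  }
  write_labels(cohort$labels, file.path(dir, "labels.csv"))
  write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  jsonlite::write_json(tr, file.path(dir, "transforms.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A list with `cases` (each holding `pre`, `post`, `annotations`,
#'   `annotations_post`, `case_id`, `patient_id`, `forearm`), `labels` and
#'   `patients`.
#' @export
read_cohort <- function(dir) {
  labels <- read_labels(file.path(dir, "labels.csv"))
  patients <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  stems <- sub("_pre_vis\\.png$", "",
               list.files(dir, pattern = "_pre_vis\\.png$", full.names = TRUE))
  cases <- lapply(stems, function(stem) {
    id <- basename(stem)
    list(pre = read_bundle(paste0(stem, "_pre_vis.png"), paste0(stem, "_pre_th.tif"), "pre"),
         post = read_bundle(paste0(stem, "_post_vis.png"), paste0(stem, "_post_th.tif"), "post"),
         annotations = read_annotations(paste0(stem, "_pre_ann.json")),
         annotations_post = read_annotations(paste0(stem, "_post_ann.json")),
         case_id = id,
         patient_id = sub("_[LR]$", "", id),
         forearm = sub("^.*_", "", id))
  })
  list(cases = cases, labels = labels, patients = patients)
}
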