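#' Specification of a synthetic tooth cohort
#'
#' Describes the tooth population of an in-silico dry-mandible experiment:
#' 20 loose mandibular teeth re-seated in wax to create a stable artificial
#' bone level of about 7 mm.  Tooth lengths are either an explicit list (such
#' as the caliper lengths of the physical specimens, which span roughly
#' 18.2-24.1 mm) or drawn uniformly from `length_range`.
#'
#' @param n_teeth Number of teeth (default 20).  Ignored when `lengths` is
#'   given.
#' @param lengths Optional explicit vector of tooth lengths in mm.
#' @param length_range Range (mm) for uniformly sampled lengths.
#' @param bone_level Target marginal bone level in mm, CEJ to AC (default 7).
#' @param bone_level_sd Between-tooth SD of the achieved bone level in mm
#'   (default 1; re-seating teeth in wax is only approximately uniform).
#' @param cej_offset Distance from the crown reference down to the CEJ in mm
#'   (default 2).
#' @param fraction_multirooted Probability that a tooth is modelled with
#'   separate mesial and distal roots (default 0.3).
#' @param seed Integer seed recorded in the spec and used by
#'   [generate_cohort()].
#' @return An object of class `relrbl_cohort_spec`.
#' @export
cohort_spec <- function(n_teeth = 20,
                        lengths = NULL,
                        length_range = c(18.2, 24.1),
                        bone_level = 7,
                        bone_level_sd = 1,
                        cej_offset = 2,
                        fraction_multirooted = 0.3,
                        seed = NULL) {
  if (!is.null(lengths)) {
    if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths <= 0)) {
      stop_input("explicit tooth lengths must be positive numbers (mm)")
    }
    n_teeth <- length(lengths)
  }
  if (!is_number(n_teeth) || n_teeth < 1) stop_input("n_teeth must be >= 1")
  if (!is_number(bone_level) || bone_level <= 0) stop_input("bone_level must be > 0 mm")
  if (!is_number(bone_level_sd) || bone_level_sd < 0) stop_input("bone_level_sd must be >= 0")
  min_len <- if (is.null(lengths)) min(length_range) else min(lengths)
  if (bone_level + cej_offset >= min_len) {
    stop_input("infeasible cohort: bone_level + cej_offset (%.1f mm) reaches the shortest tooth (%.1f mm)",
               bone_level + cej_offset, min_len)
  }
  if (fraction_multirooted < 0 || fraction_multirooted > 1) {
    stop_input("fraction_multirooted must be in [0, 1]")
  }
  structure(
    list(n_teeth = as.integer(n_teeth), lengths = lengths,
         length_range = length_range, bone_level = bone_level,
         bone_level_sd = bone_level_sd, cej_offset = cej_offset,
         fraction_multirooted = fraction_multirooted, seed = seed),
    class = "relrbl_cohort_spec"
  )
}

#' Reader noise model
#'
#' The human part of the measurement chain: how many examiners read the
#' blinded images, how many times, and how precisely they click.  Click
#' noise is isotropic Gaussian on the receptor plane, per landmark; an
#' optional per-examiner bias shifts each examiner's alveolar-crest
#' placement systematically (crest position is the landmark hardest to call
#' on a radiograph).
#'
#' @param n_examiners Number of examiners (default 4).
#' @param n_repeats Blinded repeat reads per examiner (default 2).
#' @param click_noise_sd SD of the landmark click error in mm (default 0.15).
#' @param examiner_bias Scalar or per-examiner vector of systematic AC
#'   placement shifts in mm (default 0).
#' @param seed Integer seed used by [simulate_readings()].
#' @return An object of class `relrbl_reader_model`.
#' @export
reader_model <- function(n_examiners = 4,
                         n_repeats = 2,
                         click_noise_sd = 0.15,
                         examiner_bias = 0,
                         seed = NULL) {
  if (!is_number(n_examiners) || n_examiners < 1) stop_input("n_examiners must be >= 1")
  if (!is_number(n_repeats) || n_repeats < 1) stop_input("n_repeats must be >= 1")
  if (!is_number(click_noise_sd) || click_noise_sd < 0) {
    stop_input("click_noise_sd must be >= 0 mm")
  }
  bias <- rep_len(examiner_bias, n_examiners)
  structure(
    list(n_examiners = as.integer(n_examiners),
         n_repeats = as.integer(n_repeats),
         click_noise_sd = click_noise_sd,
         examiner_bias = bias, seed = seed),
    class = "relrbl_reader_model"
  )
}

#' Generate a synthetic tooth cohort
#'
#' Draws tooth models from a [cohort_spec()]: length (explicit or uniform),
#' a per-tooth achieved bone level around the target, CEJ `cej_offset` mm
#' below the crown, and (for multi-rooted teeth) a distal root 0.5-1.5 mm
#' shorter than the mesial one.
#'
#' @param spec A [cohort_spec()].
#' @param seed Overrides the seed stored in the spec.
#' @return A list of [tooth_model()] objects with attributes `tooth_id` and
#'   `bone_level` on each element.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "relrbl_cohort_spec"))
  with_seed(seed, {
    n <- spec$n_teeth
    lens <- if (is.null(spec$lengths)) {
      stats::runif(n, spec$length_range[1], spec$length_range[2])
    } else {
      spec$lengths
    }
    multi <- stats::runif(n) < spec$fraction_multirooted
    bl <- stats::rnorm(n, spec$bone_level, spec$bone_level_sd)
    # keep the wax-seating variation within physical bounds
    bl <- pmin(pmax(bl, 0.5), lens - spec$cej_offset - 0.5)
    lapply(seq_len(n), function(i) {
      apex <- if (multi[i]) c(M = 0, D = stats::runif(1, 0.5, 1.5)) else c(single = 0)
      m <- tooth_model(length = lens[i],
                       h_cej = lens[i] - spec$cej_offset,
                       h_ac = lens[i] - spec$cej_offset - bl[i],
                       apex_heights = apex)
      attr(m, "tooth_id") <- sprintf("tooth%02d", i)
      attr(m, "bone_level") <- bl[i]
      m
    })
  })
}

#' Default dual-angle imaging geometries
#'
#' The control and distorted imaging conditions of the simulated experiment:
#' a paralleling-technique exposure (receptor tilt 0) and the same setup with
#' the receptor tilted by `angle_deg` (default 30 degrees, a deviation that
#' commonly occurs between two clinical exposures of the same site).
#'
#' @param angle_deg Receptor tilt of the distorted condition (default 30).
#' @param mode `"parallel"` (default; long-cone idealisation) or `"central"`.
#' @param focal_distance,standoff Source and object distances in mm, used in
#'   central mode.
#' @return A list with elements `g0` and `g1` ([projection_geometry()]s) and
#'   `angles` (numeric, degrees).
#' @export
default_geometries <- function(angle_deg = 30, mode = "parallel",
                               focal_distance = 300, standoff = 15) {
  list(g0 = projection_geometry(mode, focal_distance = focal_distance,
                                standoff = standoff, receptor_tilt_deg = 0),
       g1 = projection_geometry(mode, focal_distance = focal_distance,
                                standoff = standoff,
                                receptor_tilt_deg = angle_deg),
       angles = c(0, angle_deg))
}

# Receptor-frame (u, v) mm -> image pixels (origin upper-left, y downward).
# The frame offsets keep all coordinates non-negative for realistic inputs.
receptor_to_pixels <- function(u, v, mm_per_px, u_offset = 25, v_offset = 40) {
  list(x = (u + u_offset) / mm_per_px, y = (v_offset - v) / mm_per_px)
}

#' Simulate the blinded multi-reader reading of a cohort
#'
#' For every tooth and each of the two imaging geometries, projects the
#' landmark model onto the receptor; then for every examiner and blinded
#' repeat adds click noise, converts to pixel coordinates, and measures the
#' annotated site exactly as real annotation files would be measured.  The
#' result is the long-format reading table the reliability module consumes.
#'
#' @param cohort A list of tooth models from [generate_cohort()].
#' @param geometry_0,geometry_1 The two imaging [projection_geometry()]s.
#' @param reader A [reader_model()].
#' @param angles Numeric labels (degrees) for the two conditions.
#' @param mm_per_px Pixel calibration of the simulated images (default 0.06
#'   mm/px, a typical intraoral sensor resolution).
#' @param seed Overrides the seed stored in the reader model.
#' @param out_dir If non-`NULL`, writes one landmark CSV per simulated image
#'   plus a calibration sidecar JSON into this directory.
#' @return A data frame of class `relrbl_readings` (columns `site`,
#'   `examiner`, `repeat`, `angle`, `metric`, `value`) with attribute
#'   `truth` (per-site true length, bone level and relRBL).
#' @export
simulate_readings <- function(cohort, geometry_0, geometry_1, reader,
                              angles = c(0, geometry_1$receptor_tilt_deg),
                              mm_per_px = 0.06,
                              seed = reader$seed,
                              out_dir = NULL) {
  stopifnot(inherits(reader, "relrbl_reader_model"))
  geoms <- list(geometry_0, geometry_1)
  cal <- calibration(mm_per_px, source = "sidecar")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  truth <- list()
  landmark_files <- list()
  with_seed(seed, {
    for (ti in seq_along(cohort)) {
      model <- cohort[[ti]]
      tooth_id <- attr(model, "tooth_id") %||% sprintf("tooth%02d", ti)
      for (gi in 1:2) {
        pl <- project_tooth(model, geoms[[gi]])
        for (ex in seq_len(reader$n_examiners)) {
          for (rp in seq_len(reader$n_repeats)) {
            noisy <- pl
            npts <- nrow(noisy)
            noisy$u <- noisy$u + stats::rnorm(npts, 0, reader$click_noise_sd)
            noisy$v <- noisy$v + stats::rnorm(npts, 0, reader$click_noise_sd)
            is_ac <- noisy$label == "AC"
            noisy$v[is_ac] <- noisy$v[is_ac] + reader$examiner_bias[ex]
            px <- receptor_to_pixels(noisy$u, noisy$v, mm_per_px)
            pts <- data.frame(label = noisy$label, aspect = noisy$aspect,
                              root = noisy$root, x = px$x, y = px$y,
                              stringsAsFactors = FALSE)
            image_id <- sprintf("%s_a%02d_e%d_r%d", tooth_id, angles[gi], ex, rp)
            site <- site_annotation(image_id, tooth_id, pts, cal)
            meas <- measure_site(site, timestamp = "simulated")
            for (k in seq_len(nrow(meas))) {
              if (meas$status[k] != "ok") next
              site_id <- paste(tooth_id, meas$aspect[k], sep = "_")
              rows[[length(rows) + 1L]] <- data.frame(
                site = site_id, examiner = ex, "repeat" = rp,
                angle = angles[gi],
                metric = METRIC_LEVELS,
                value = c(meas$a_mm[k], meas$b_mm[k], meas$rel_rbl_pct[k]),
                stringsAsFactors = FALSE, check.names = FALSE)
            }
            if (!is.null(out_dir)) {
              landmark_files[[image_id]] <- cbind(
                data.frame(image_id = image_id, tooth_id = tooth_id,
                           stringsAsFactors = FALSE),
                pts)
            }
          }
        }
      }
      bl <- model$h_cej - model$h_ac
      for (aspect in names(model$aspect_offsets)) {
        root <- aspect_root(aspect, names(model$apex_heights))
        a_true <- model$length - model$apex_heights[[root]]
        truth[[length(truth) + 1L]] <- data.frame(
          site = paste(tooth_id, aspect, sep = "_"),
          length_true = a_true, rbl_true = bl,
          rel_rbl_true = 100 * bl / a_true,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "mm_per_px") <- mm_per_px
  class(out) <- c("relrbl_readings", "data.frame")
  if (!is.null(out_dir)) {
    for (image_id in names(landmark_files)) {
      write_landmarks(landmark_files[[image_id]],
                      file.path(out_dir, paste0(image_id, ".csv")))
    }
    write_calibrations(
      data.frame(image_id = names(landmark_files), mm_per_px = mm_per_px,
                 stringsAsFactors = FALSE),
      file.path(out_dir, "calibration.json"))
    write_readings(out, file.path(out_dir, "readings.csv"))
  }
  out
}

#' Run the full synthetic dual-angle experiment
#'
#' End-to-end pipeline: generate the cohort, simulate the dual-angle
#' multi-reader reading, and reduce it to a study summary (means, SDs,
#' paired t-tests, percent changes) and an examiner-reliability report.
#'
#' @param spec A [cohort_spec()] (default: the standard 20-tooth cohort).
#' @param geometries A list with `g0`, `g1`, `angles` as produced by
#'   [default_geometries()].
#' @param reader A [reader_model()].
#' @param seed Master integer seed; the cohort and the reading stage use
#'   seeds derived from it.
#' @param out_dir Optional directory for landmark/reading CSV output.
#' @return A list of class `relrbl_experiment` with elements `summary`,
#'   `reliability`, `readings`, `cohort`, `seed`.
#' @export
#' @examples
#' exp <- run_experiment(seed = 1)
#' exp$summary
run_experiment <- function(spec = cohort_spec(),
                           geometries = default_geometries(),
                           reader = reader_model(),
                           seed = 1,
                           out_dir = NULL) {
  if (!is_number(seed)) stop_input("seed must be a single integer")
  cohort <- generate_cohort(spec, seed = seed)
  readings <- simulate_readings(cohort, geometries$g0, geometries$g1, reader,
                                angles = geometries$angles, seed = seed + 1,
                                out_dir = out_dir)
  structure(
    list(summary = summarize_study(readings),
         reliability = reliability_report(readings),
         readings = readings, cohort = cohort, seed = seed),
    class = "relrbl_experiment"
  )
}

#' @export
print.relrbl_experiment <- function(x, ...) {
  cat(sprintf("Synthetic dual-angle study (seed %s, %d teeth)\n",
              format(x$seed), length(x$cohort)))
  print(x$summary)
  print(x$reliability)
  invisible(x)
}
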