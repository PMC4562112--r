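LANDMARK_LABELS <- c("INC_OCL", "APEX", "AC", "CEJ", "RM")
ASPECT_LEVELS <- c("mesial", "distal", "none")
ROOT_LEVELS <- c("M", "D", "single")

#' Image calibration
#'
#' The millimetre size of one pixel, as recovered from an image sidecar, a
#' TIFF resolution tag, or a configured default.
#'
#' @param mm_per_px Millimetres per pixel, > 0.
#' @param source Where the value came from: `"sidecar"`, `"tiff_tag"` or
#'   `"default"`.
#' @return An object of class `relrbl_calibration`.
#' @export
#' @examples
#' calibration(0.06)
calibration <- function(mm_per_px, source = c("sidecar", "tiff_tag", "default")) {
  source <- match.arg(source)
  if (!is_number(mm_per_px) || mm_per_px <= 0) {
    stop_input("mm_per_px must be a single positive number")
  }
  structure(list(mm_per_px = mm_per_px, source = source),
            class = "relrbl_calibration")
}

validate_points <- function(points) {
  need <- c("label", "aspect", "root", "x", "y")
  if (!is.data.frame(points) || !all(need %in% names(points))) {
    stop_input("points must be a data frame with columns %s",
               paste(need, collapse = ", "))
  }
  points$label <- as.character(points$label)
  points$aspect <- as.character(points$aspect)
  points$root <- as.character(points$root)
  if (!all(points$label %in% LANDMARK_LABELS)) {
    stop_input("unknown landmark label(s): %s",
               paste(setdiff(points$label, LANDMARK_LABELS), collapse = ", "))
  }
  if (!all(points$aspect %in% ASPECT_LEVELS)) {
    stop_input("aspect must be one of %s", paste(ASPECT_LEVELS, collapse = ", "))
  }
  if (!all(points$root %in% ROOT_LEVELS)) {
    stop_input("root must be one of %s", paste(ROOT_LEVELS, collapse = ", "))
  }
  if (!is.numeric(points$x) || !is.numeric(points$y) ||
      any(!is.finite(points$x)) || any(!is.finite(points$y)) ||
      any(points$x < 0) || any(points$y < 0)) {
    stop_input("pixel coordinates must be finite and >= 0 (image origin is the upper-left corner)")
  }
  key <- paste(points$label, points$aspect, points$root)
  if (anyDuplicated(key)) {
    stop_input("duplicate landmark (label, aspect, root): %s",
               paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  points
}

#' Landmark annotation of one tooth site
#'
#' Bundles the clicked landmark points of one imaged tooth (both aspects)
#' with its pixel calibration.  Landmarks follow the clinical protocol:
#' exactly one crown reference (`INC_OCL`, the incisal edge or most elevated
#' cusp), at least one root apex (`APEX`, per root on multi-rooted teeth),
#' and per measured aspect one alveolar crest (`AC`) and one cemento-enamel
#' junction (`CEJ`).  Restoration margins (`RM`) may be stored but are not
#' used in any measurement.
#'
#' @param image_id,tooth_id Identifiers (character scalars).
#' @param points Data frame with columns `label`, `aspect`, `root`, `x`, `y`
#'   (pixel coordinates, origin at the upper-left corner, y increasing
#'   downward).
#' @param calibration A [calibration()].
#' @return An object of class `relrbl_site`.
#' @export
site_annotation <- function(image_id, tooth_id, points, calibration) {
  if (!inherits(calibration, "relrbl_calibration")) {
    stop_input("'calibration' must be created with calibration()")
  }
  points <- validate_points(points)
  if (sum(points$label == "INC_OCL") != 1L) {
    stop_input("site %s/%s must have exactly one INC_OCL landmark", image_id, tooth_id)
  }
  if (sum(points$label == "APEX") < 1L) {
    stop_input("site %s/%s must have at least one APEX landmark", image_id, tooth_id)
  }
  structure(
    list(image_id = as.character(image_id), tooth_id = as.character(tooth_id),
         points = points, calibration = calibration),
    class = "relrbl_site"
  )
}

#' @export
print.relrbl_site <- function(x, ...) {
  cat(sprintf("<site %s/%s: %d landmarks, %.4g mm/px (%s)>\n",
              x$image_id, x$tooth_id, nrow(x$points),
              x$calibration$mm_per_px, x$calibration$source))
  invisible(x)
}

#' Vertical-axis coordinate of a landmark
#'
#' Projects a clicked point onto the imaginary vertical axis parallel to the
#' vertical edge of the receptor: the horizontal pixel coordinate is
#' discarded and the vertical one converted to mm.  All distances in this
#' package are differences of such axis coordinates, never 2D Euclidean
#' distances — this is what makes the technique robust to mesial/distal
#' landmark placement.
#'
#' @param point A one-row landmark data frame (with a `y` column) or a
#'   numeric vector of y pixel coordinates.
#' @param calibration A [calibration()].
#' @return Axis coordinate(s) in mm.
#' @export
#' @examples
#' axis_coordinate(100, calibration(0.06))  # 6 mm
axis_coordinate <- function(point, calibration) {
  if (!inherits(calibration, "relrbl_calibration")) {
    stop_input("'calibration' must be created with calibration()")
  }
  y <- if (is.data.frame(point)) point$y else point
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop_input("y pixel coordinates must be finite numbers")
  }
  y * calibration$mm_per_px
}

site_axis <- function(site, label, aspect = NULL, root = NULL) {
  p <- site$points
  sel <- p$label == label
  if (!is.null(aspect)) sel <- sel & p$aspect == aspect
  if (!is.null(root)) sel <- sel & p$root == root
  axis_coordinate(p[sel, , drop = FALSE], site$calibration)
}

#' Tooth length from an annotated site
#'
#' Distance on the vertical axis from the crown reference (INC/OCL) to each
#' apex, in mm.  Multi-rooted teeth yield one length per apex, named by root.
#'
#' @param site A [site_annotation()].
#' @return Named numeric vector of lengths `a` in mm, one per root.
#' @export
tooth_length <- function(site) {
  stopifnot(inherits(site, "relrbl_site"))
  crown <- site_axis(site, "INC_OCL")
  apexes <- site$points[site$points$label == "APEX", , drop = FALSE]
  a <- abs(crown - axis_coordinate(apexes, site$calibration))
  names(a) <- apexes$root
  if (any(a == 0)) {
    stop_degenerate("INC_OCL and APEX coincide on the vertical axis (zero tooth length)")
  }
  a
}

#' Direct radiographic bone level (RBL)
#'
#' Distance on the vertical axis from the alveolar crest (AC) to the
#' cemento-enamel junction (CEJ) of one aspect, in mm — the conventional
#' direct measurement of bone level.
#'
#' @param site A [site_annotation()].
#' @param aspect `"mesial"`, `"distal"` or `"none"`.
#' @return Bone level `b` in mm (>= 0).
#' @export
rbl <- function(site, aspect) {
  stopifnot(inherits(site, "relrbl_site"))
  aspect <- match.arg(aspect, ASPECT_LEVELS)
  ac <- site_axis(site, "AC", aspect = aspect)
  cej <- site_axis(site, "CEJ", aspect = aspect)
  if (length(ac) != 1L || length(cej) != 1L) {
    stop_input("site %s/%s: aspect '%s' needs exactly one AC and one CEJ (found %d/%d)",
               site$image_id, site$tooth_id, aspect, length(ac), length(cej))
  }
  abs(ac - cej)
}

#' Length-adjusted radiographic bone level (relRBL)
#'
#' The ratio of bone level to tooth length, expressed as a percentage:
#' `100 * b / a`.  Because any uniform projection scaling multiplies `a` and
#' `b` by the same factor, this ratio is invariant to elongation,
#' foreshortening and magnification — the core of the indirect technique.
#'
#' @param b Bone level(s) in mm (>= 0).
#' @param a Tooth length(s) in mm (> 0).
#' @return relRBL in percent.  A value above 100 % (b > a) is anatomically
#'   implausible and triggers a warning but is still returned, so annotation
#'   noise is visible rather than silently clamped.
#' @export
#' @examples
#' rel_rbl(7, 22.1)
rel_rbl <- function(b, a) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop_input("a and b must be finite numbers (mm)")
  }
  if (any(a == 0)) stop_degenerate("tooth length a = 0: relRBL undefined")
  if (any(b < 0)) stop_input("bone level b must be >= 0")
  if (any(b > a)) {
    warn_relrbl("bone level exceeds tooth length (b > a): relRBL > 100 %%")
  }
  100 * b / a
}

# Which root's length does an aspect use?  Mesial pairs with the mesial
# root, distal with the distal; single-rooted teeth use their one root.
aspect_root <- function(aspect, roots) {
  pref <- switch(aspect,
                 mesial = c("M", "single"),
                 distal = c("D", "single"),
                 none = c("single", "M", "D"))
  hit <- pref[pref %in% roots]
  if (length(hit) == 0L) roots[1] else hit[1]
}

#' Measure a complete annotated site
#'
#' Composes [tooth_length()], [rbl()] and [rel_rbl()] for every annotated
#' aspect of the site.  On multi-rooted teeth the mesial aspect is adjusted
#' by the mesial-root length and the distal aspect by the distal-root
#' length.  Aspects missing an AC or CEJ are reported with status
#' `"incomplete"` and `NA` values instead of failing the whole site.
#'
#' @param site A [site_annotation()].
#' @param timestamp Character timestamp recorded with the measurement;
#'   defaults to the current time (ISO 8601).
#' @return A data frame of class `relrbl_measurement` with one row per
#'   aspect: `image_id`, `tooth_id`, `aspect`, `root`, `a_mm`, `b_mm`,
#'   `rel_rbl_pct`, `status`, `unit`, `timestamp`.
#' @export
measure_site <- function(site,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(inherits(site, "relrbl_site"))
  a <- tooth_length(site)
  p <- site$points
  aspects <- intersect(ASPECT_LEVELS, unique(p$aspect[p$label %in% c("AC", "CEJ")]))
  if (length(aspects) == 0L) {
    stop_input("site %s/%s has no AC/CEJ landmarks to measure", site$image_id, site$tooth_id)
  }
  rows <- lapply(aspects, function(aspect) {
    root <- aspect_root(aspect, names(a))
    ai <- a[[root]]
    has_ac <- any(p$label == "AC" & p$aspect == aspect)
    has_cej <- any(p$label == "CEJ" & p$aspect == aspect)
    if (has_ac && has_cej) {
      bi <- rbl(site, aspect)
      data.frame(image_id = site$image_id, tooth_id = site$tooth_id,
                 aspect = aspect, root = root, a_mm = ai, b_mm = bi,
                 rel_rbl_pct = rel_rbl(bi, ai), status = "ok",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(image_id = site$image_id, tooth_id = site$tooth_id,
                 aspect = aspect, root = root, a_mm = ai, b_mm = NA_real_,
                 rel_rbl_pct = NA_real_, status = "incomplete",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$unit <- "mm"
  out$timestamp <- timestamp
  class(out) <- c("relrbl_measurement", "data.frame")
  out
}
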