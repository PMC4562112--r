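#' Projection geometry of an intraoral radiograph
#'
#' Describes the spatial configuration of X-ray source, receptor and tooth
#' used to form a periapical image.  The receptor plane passes through the
#' origin; the central beam runs along the negative z axis, so in `central`
#' mode the point source sits at `(0, 0, focal_distance)`.  The receptor may
#' be tilted by `receptor_tilt_deg` about the horizontal x axis (the
#' modified-holder situation that produces image *elongation*), and the tooth
#' axis may be tilted by `tooth_tilt_deg` away from the receptor vertical
#' (producing *foreshortening*).  With both tilts zero and a parallel beam
#' the geometry is the ideal paralleling technique.
#'
#' @param mode `"parallel"` (beam rays parallel to the central beam; an
#'   idealisation of the long-cone technique) or `"central"` (divergent beam
#'   from a point source at finite `focal_distance`, which adds magnification
#'   `f / (f - d)` for an object standing `d` mm off the receptor).
#' @param focal_distance Source-to-receptor distance f in mm; ignored (and
#'   may be `Inf`) in parallel mode.
#' @param standoff Distance d >= 0 in mm from the tooth axis to the receptor
#'   plane.
#' @param receptor_tilt_deg Receptor tilt angle (alpha) in degrees,
#'   `|alpha| < 90`.
#' @param tooth_tilt_deg Tooth-axis tilt in degrees away from the receptor
#'   vertical, `|alpha| < 90`.
#'
#' @return An object of class `relrbl_geometry`.
#' @seealso [project_point()], [project_tooth()], [scale_factor()]
#' @export
#' @examples
#' projection_geometry("parallel", receptor_tilt_deg = 30)
#' projection_geometry("central", focal_distance = 300, standoff = 15)
projection_geometry <- function(mode = c("parallel", "central"),
                                focal_distance = Inf,
                                standoff = 0,
                                receptor_tilt_deg = 0,
                                tooth_tilt_deg = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(standoff) || length(standoff) != 1L || is.na(standoff) ||
      standoff < 0) {
    stop_input("'standoff' must be a single non-negative number (mm)")
  }
  for (ang in c(receptor_tilt_deg, tooth_tilt_deg)) {
    if (!is_number(ang) || abs(ang) >= 90) {
      stop_input("tilt angles must be finite and strictly inside (-90, 90) degrees")
    }
  }
  if (mode == "central") {
    if (!is_number(focal_distance) || focal_distance <= 0) {
      stop_input("'focal_distance' must be a finite positive number (mm) in central mode")
    }
    if (focal_distance <= standoff) {
      stop_degenerate("focal distance (%.3g mm) must exceed the standoff (%.3g mm)",
                      focal_distance, standoff)
    }
  }
  structure(
    list(mode = mode,
         focal_distance = if (mode == "parallel") Inf else focal_distance,
         standoff = standoff,
         receptor_tilt_deg = receptor_tilt_deg,
         tooth_tilt_deg = tooth_tilt_deg),
    class = "relrbl_geometry"
  )
}

#' @export
print.relrbl_geometry <- function(x, ...) {
  cat(sprintf(
    "<projection geometry: %s mode, f = %s mm, standoff = %g mm, receptor tilt = %g deg, tooth tilt = %g deg>\n",
    x$mode,
    if (is.finite(x$focal_distance)) format(x$focal_distance) else "Inf",
    x$standoff, x$receptor_tilt_deg, x$tooth_tilt_deg))
  invisible(x)
}

# Receptor in-plane basis and unit normal for a tilt about the x axis.
# The in-plane vertical is (0, cos a, sin a); the normal is (0, -sin a, cos a).
receptor_frame <- function(geometry) {
  a <- deg2rad(geometry$receptor_tilt_deg)
  list(e_u = c(1, 0, 0),
       e_v = c(0, cos(a), sin(a)),
       n   = c(0, -sin(a), cos(a)))
}

#' Project 3D points onto the receptor plane
#'
#' Maps world points (mm) to receptor-frame coordinates `(u, v)` in mm.
#' In `central` mode each point is carried along the ray from the source at
#' `(0, 0, f)` to its intersection with the (possibly tilted) receptor plane;
#' in `parallel` mode all points travel along the central-beam direction
#' `(0, 0, -1)`.  `u` is the receptor's horizontal in-plane coordinate and
#' `v` its in-plane vertical — the axis all bone-level measurements use.
#'
#' @param point A length-3 numeric `(x, y, z)` or an n x 3 matrix of points,
#'   in mm.  Positive z is towards the source.
#' @param geometry A [projection_geometry()].
#'
#' @return A length-2 numeric `(u, v)` for a single point, or an n x 2 matrix.
#' @export
#' @examples
#' g <- projection_geometry("central", focal_distance = 300)
#' project_point(c(0, 10, 20), g)  # magnified by 300/280
project_point <- function(point, geometry) {
  stopifnot(inherits(geometry, "relrbl_geometry"))
  single <- is.null(dim(point))
  p <- if (single) matrix(as.numeric(point), nrow = 1L) else as.matrix(point)
  if (ncol(p) != 3L || anyNA(p) || any(!is.finite(p))) {
    stop_input("points must be finite (x, y, z) triples in mm")
  }
  fr <- receptor_frame(geometry)

  if (geometry$mode == "parallel") {
    dir <- c(0, 0, -1)
    denom <- sum(dir * fr$n)            # -cos(alpha), never 0 for |alpha| < 90
    tt <- -(p %*% fr$n) / denom
    x <- p + tt %*% rbind(dir)
  } else {
    f <- geometry$focal_distance
    s <- c(0, 0, f)
    if (any(p[, 3] >= f)) {
      stop_degenerate("point at or behind the X-ray source (z >= focal distance)")
    }
    d <- sweep(p, 2, s)                 # rays source -> point
    denom <- d %*% fr$n
    if (any(abs(denom) < 1e-12)) {
      stop_degenerate("ray parallel to the receptor plane")
    }
    tt <- -sum(s * fr$n) / denom
    x <- matrix(s, nrow(p), 3, byrow = TRUE) + as.vector(tt) * d
  }
  uv <- cbind(u = as.vector(x %*% fr$e_u), v = as.vector(x %*% fr$e_v))
  if (single) c(u = unname(uv[1, 1]), v = unname(uv[1, 2])) else uv
}

#' Three-dimensional tooth model
#'
#' A tooth reduced to the landmarks the measurement protocol uses: signed
#' heights along the tooth axis in mm, with the (most apical) apex at 0 and
#' the crown reference (incisal edge or most elevated cusp, INC/OCL) at the
#' tooth length `L`.  The cemento-enamel junction (CEJ) sits at `h_cej`, the
#' alveolar crest (AC) at `h_ac`; their difference `h_cej - h_ac` is the true
#' marginal bone level.  Mesial and distal CEJ/AC landmarks are displaced
#' laterally off the axis by `aspect_offsets` — displacement that the
#' vertical-axis measurement rule must ignore.
#'
#' @param length Tooth length L in mm (INC/OCL to apex), > 0.
#' @param h_cej CEJ height above the apex, mm, in (0, L].
#' @param h_ac AC height above the apex, mm, in [0, L] and not above `h_cej`.
#' @param apex_heights Named numeric of apex heights (mm above the reference
#'   apex): `c(single = 0)` for single-rooted teeth, or e.g.
#'   `c(M = 0, D = 0.8)` for a molar whose distal root is 0.8 mm shorter.
#' @param aspect_offsets Named numeric lateral offsets (mm) of the mesial and
#'   distal CEJ/AC landmarks.
#'
#' @return An object of class `relrbl_tooth`.
#' @export
#' @examples
#' tooth_model(length = 22.1, h_cej = 20.1, h_ac = 13.1)
tooth_model <- function(length,
                        h_cej,
                        h_ac,
                        apex_heights = c(single = 0),
                        aspect_offsets = c(mesial = -3, distal = 3)) {
  if (!is_number(length) || length <= 0) stop_input("tooth length must be > 0 mm")
  if (!is_number(h_cej) || h_cej <= 0 || h_cej > length) {
    stop_input("h_cej must lie in (0, L]")
  }
  if (!is_number(h_ac) || h_ac < 0 || h_ac > length) {
    stop_input("h_ac must lie in [0, L]")
  }
  if (h_ac > h_cej) {
    stop_input("the alveolar crest cannot be coronal to the CEJ (h_ac > h_cej)")
  }
  if (is.null(names(apex_heights)) || anyNA(apex_heights) ||
      any(apex_heights < 0) || any(apex_heights >= length)) {
    stop_input("apex_heights must be named, non-negative and below the tooth length")
  }
  if (is.null(names(aspect_offsets)) ||
      !all(names(aspect_offsets) %in% c("mesial", "distal"))) {
    stop_input("aspect_offsets must be named 'mesial'/'distal'")
  }
  structure(
    list(length = length, h_cej = h_cej, h_ac = h_ac,
         apex_heights = apex_heights, aspect_offsets = aspect_offsets),
    class = "relrbl_tooth"
  )
}

#' @export
print.relrbl_tooth <- function(x, ...) {
  cat(sprintf(
    "<tooth: L = %.2f mm, CEJ at %.2f, AC at %.2f (bone level %.2f mm), roots: %s>\n",
    x$length, x$h_cej, x$h_ac, x$h_cej - x$h_ac,
    paste(names(x$apex_heights), collapse = "/")))
  invisible(x)
}

# Landmark table for a tooth model: label/aspect/root plus the 3D position
# before projection.  Heights are measured from the reference apex; the tooth
# is centred vertically on the central beam so the beam strikes mid-tooth.
tooth_landmarks_3d <- function(model, geometry, center = c(0, 0)) {
  at <- deg2rad(geometry$tooth_tilt_deg)
  d <- geometry$standoff
  mk <- function(label, aspect, root, h, offset) {
    hc <- h - model$length / 2
    data.frame(label = label, aspect = aspect, root = root,
               x = offset + center[1],
               y = hc * cos(at) + center[2],
               z = d + hc * sin(at),
               stringsAsFactors = FALSE)
  }
  rows <- list(mk("INC_OCL", "none", "single", model$length, 0))
  roots <- names(model$apex_heights)
  for (i in seq_along(roots)) {
    # small lateral spread between roots; irrelevant to vertical measurements
    off <- if (length(roots) == 1L) 0 else c(-1.5, 1.5)[i]
    rows[[length(rows) + 1L]] <-
      mk("APEX", "none", roots[i], model$apex_heights[[i]], off)
  }
  for (aspect in names(model$aspect_offsets)) {
    off <- model$aspect_offsets[[aspect]]
    rows[[length(rows) + 1L]] <- mk("CEJ", aspect, "single", model$h_cej, off)
    rows[[length(rows) + 1L]] <- mk("AC",  aspect, "single", model$h_ac,  off)
  }
  do.call(rbind, rows)
}

#' Project a tooth model onto the receptor
#'
#' Places the tooth at the geometry's standoff, centred vertically on the
#' central beam, applies any tooth tilt, and projects every landmark with
#' [project_point()].
#'
#' @param model A [tooth_model()].
#' @param geometry A [projection_geometry()]; its `standoff` and
#'   `tooth_tilt_deg` position the tooth.
#' @param center Length-2 in-plane `(u, v)` offset in mm for the tooth
#'   mid-height (default centred on the beam axis).
#'
#' @return A data frame of projected landmarks with columns `label`,
#'   `aspect`, `root`, `u`, `v` (mm, receptor frame).
#' @export
project_tooth <- function(model, geometry, center = c(0, 0)) {
  stopifnot(inherits(model, "relrbl_tooth"))
  lm3 <- tooth_landmarks_3d(model, geometry, center = center)
  uv <- project_point(as.matrix(lm3[, c("x", "y", "z")]), geometry)
  out <- lm3[, c("label", "aspect", "root")]
  out$u <- uv[, "u"]
  out$v <- uv[, "v"]
  rownames(out) <- NULL
  out
}

#' Local vertical scale factor of the projection
#'
#' Ratio of projected vertical image length to true object length for a
#' small vertical object at distance `at_standoff` from the receptor:
#' magnification `f / (f - d)` from the divergent beam (1 in parallel mode),
#' elongation `1 / cos(alpha_r)` from receptor tilt, and foreshortening
#' `cos(alpha_t)` from tooth tilt.
#'
#' @param geometry A [projection_geometry()].
#' @param at_standoff Object-to-receptor distance d in mm; defaults to the
#'   geometry's own standoff.
#'
#' @return A single dimensionless ratio.
#' @export
#' @examples
#' scale_factor(projection_geometry("central", focal_distance = 300, standoff = 15))
#' scale_factor(projection_geometry("parallel", receptor_tilt_deg = 30))
scale_factor <- function(geometry, at_standoff = geometry$standoff) {
  stopifnot(inherits(geometry, "relrbl_geometry"))
  if (!is_number(at_standoff) || at_standoff < 0) {
    stop_input("'at_standoff' must be a non-negative number (mm)")
  }
  mag <- 1
  if (geometry$mode == "central") {
    f <- geometry$focal_distance
    if (f <= at_standoff) {
      stop_degenerate("object at or behind the source: f = %g <= d = %g", f, at_standoff)
    }
    mag <- f / (f - at_standoff)
  }
  mag / cos(deg2rad(geometry$receptor_tilt_deg)) *
    cos(deg2rad(geometry$tooth_tilt_deg))
}

#' Measurement bias of direct versus length-adjusted technique
#'
#' Quantifies how much an object of a given length appears to change between
#' two imaging geometries (e.g. two recall visits with different projection
#' angles).  The object is modelled as a bone-level segment ending 2 mm below
#' the crown of a tooth of length `tooth_length`; both are projected under
#' each geometry and measured on the receptor-vertical axis.
#'
#' `direct_bias` is the absolute change of the projected object length in mm
#' — the error a direct mm measurement incurs.  `ratio_bias` is the absolute
#' change of the length-adjusted ratio (object / tooth length), re-expressed
#' in mm equivalents by multiplying with the true tooth length, so the two
#' techniques are comparable on one scale.  Under parallel projection the
#' ratio is exactly invariant and `ratio_bias` is 0; the ratio technique
#' only pays off once the object is large enough that `direct_bias` exceeds
#' the reader's own precision, which is the small-object trade-off.
#'
#' @param object_length Length of the measured object in mm (e.g. the bone
#'   level), `0 < object_length <= tooth_length` (after leaving 2 mm of crown
#'   above the segment).
#' @param tooth_length True tooth length in mm.
#' @param geometry0,geometry1 The two [projection_geometry()] configurations.
#'
#' @return Named numeric `c(direct_bias, ratio_bias)` in mm.
#' @export
#' @examples
#' g0 <- projection_geometry("parallel")
#' g30 <- projection_geometry("parallel", receptor_tilt_deg = 30)
#' bias_comparison(7, 22.1, g0, g30)   # direct biased ~1.08 mm, ratio exact
#' bias_comparison(1, 22.1, g0, g30)   # small object: direct bias ~0.15 mm
bias_comparison <- function(object_length, tooth_length, geometry0, geometry1) {
  if (!is_number(object_length) || !is_number(tooth_length) ||
      object_length <= 0 || tooth_length <= 0) {
    stop_input("object and tooth lengths must be positive numbers (mm)")
  }
  crown_margin <- min(2, tooth_length - object_length)
  if (object_length + crown_margin > tooth_length || crown_margin < 0) {
    stop_input("object_length must fit within the tooth length")
  }
  model <- tooth_model(length = tooth_length,
                       h_cej = tooth_length - crown_margin,
                       h_ac = tooth_length - crown_margin - object_length)
  measure_one <- function(geom) {
    pl <- project_tooth(model, geom)
    vs <- function(lab, asp) pl$v[pl$label == lab & pl$aspect == asp][1]
    a <- abs(vs("INC_OCL", "none") - pl$v[pl$label == "APEX"][1])
    b <- abs(vs("CEJ", "mesial") - vs("AC", "mesial"))
    c(a = a, b = b)
  }
  m0 <- measure_one(geometry0)
  m1 <- measure_one(geometry1)
  c(direct_bias = abs(m1[["b"]] - m0[["b"]]),
    ratio_bias = abs(m1[["b"]] / m1[["a"]] - m0[["b"]] / m0[["a"]]) * tooth_length)
}
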