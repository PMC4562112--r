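make_site <- function(points, mm_per_px = 0.06, image_id = "img1",
                      tooth_id = "t1") {
  site_annotation(image_id, tooth_id, points, calibration(mm_per_px))
}

pt <- function(label, y, aspect = "none", root = "single", x = 100) {
  data.frame(label = label, aspect = aspect, root = root, x = x, y = y,
             stringsAsFactors = FALSE)
}

test_that("axis coordinate is the calibrated vertical pixel coordinate", {
  cal <- calibration(0.06)
  expect_equal(axis_coordinate(0, cal), 0)
  expect_equal(axis_coordinate(100, cal), 6)
  expect_equal(axis_coordinate(368.33, cal), 22.0998)
  # the horizontal coordinate is discarded entirely
  p1 <- pt("AC", 100, x = 5); p2 <- pt("AC", 100, x = 900)
  expect_equal(axis_coordinate(p1, cal), axis_coordinate(p2, cal))
})

test_that("tooth length is the INC/OCL-to-apex axis distance, per root", {
  cal_mm <- calibration(1)  # 1 mm per px: pixel y values are mm
  s <- make_site(rbind(pt("INC_OCL", 2), pt("APEX", 23.5)), mm_per_px = 1)
  expect_equal(unname(tooth_length(s)), 21.5)
  s2 <- make_site(rbind(pt("INC_OCL", 21), pt("APEX", 1, root = "M"),
                        pt("APEX", 2, root = "D")), mm_per_px = 1)
  expect_equal(tooth_length(s2), c(M = 20, D = 19))
  s3 <- make_site(rbind(pt("INC_OCL", 5), pt("APEX", 5)), mm_per_px = 1)
  expect_error(tooth_length(s3), class = "relrbl_degenerate_error")
})

test_that("caliper length times the projection scale gives the imaged length", {
  # physical 21.34 mm tooth imaged at the scale its radiograph implies
  g <- projection_geometry("central", focal_distance = 300,
                           standoff = 300 * (1 - 21.34 / 21.5))
  expect_equal(21.34 * scale_factor(g), 21.5, tolerance = 1e-9)
  tm <- tooth_model(21.34, 19.34, 12.34)
  m <- measure_projected(project_tooth(tm, g))
  expect_equal(m$a_mm[1], 21.5, tolerance = 1e-3)
})

test_that("RBL is the AC-to-CEJ axis distance", {
  s <- make_site(rbind(pt("INC_OCL", 1), pt("APEX", 24),
                       pt("CEJ", 2, aspect = "mesial"),
                       pt("AC", 3.7, aspect = "mesial"),
                       pt("CEJ", 3, aspect = "distal"),
                       pt("AC", 3, aspect = "distal")), mm_per_px = 1)
  expect_equal(rbl(s, "mesial"), 1.7)
  expect_equal(rbl(s, "distal"), 0)
  s2 <- make_site(rbind(pt("INC_OCL", 10), pt("APEX", 400),
                        pt("CEJ", 100, aspect = "mesial"),
                        pt("AC", 216.67, aspect = "mesial")), mm_per_px = 0.06)
  expect_equal(rbl(s2, "mesial"), 7.0002)
  expect_error(rbl(s2, "distal"), class = "relrbl_input_error")
})

test_that("relRBL is 100 b / a with guarded edge cases", {
  expect_equal(rel_rbl(0, 20), 0)
  expect_equal(rel_rbl(20, 20), 100)
  expect_equal(rel_rbl(7, 22.1), 100 * 7 / 22.1)
  expect_equal(round(rel_rbl(7, 22.1), 2), 31.67)
  expect_error(rel_rbl(1, 0), class = "relrbl_degenerate_error")
  expect_warning(v <- rel_rbl(25, 20), class = "relrbl_warning")
  expect_equal(v, 125)
})

test_that("measure_site composes measurements per aspect with root pairing", {
  s <- make_site(rbind(pt("INC_OCL", 1), pt("APEX", 23),
                       pt("CEJ", 3, aspect = "mesial"),
                       pt("AC", 10, aspect = "mesial"),
                       pt("CEJ", 3.5, aspect = "distal"),
                       pt("AC", 9.5, aspect = "distal")), mm_per_px = 1)
  m <- measure_site(s, timestamp = "test")
  expect_equal(nrow(m), 2L)
  expect_equal(m$a_mm, c(22, 22))
  expect_equal(m$b_mm, c(7, 6))
  expect_equal(m$rel_rbl_pct, 100 * c(7, 6) / 22)
  expect_true(all(m$status == "ok"))
  expect_equal(unique(m$unit), "mm")

  # molar: mesial aspect paired with mesial root, distal with distal
  s2 <- make_site(rbind(pt("INC_OCL", 1), pt("APEX", 23, root = "M"),
                        pt("APEX", 21.5, root = "D"),
                        pt("CEJ", 3, aspect = "mesial"),
                        pt("AC", 10, aspect = "mesial"),
                        pt("CEJ", 3, aspect = "distal"),
                        pt("AC", 10, aspect = "distal")), mm_per_px = 1)
  m2 <- measure_site(s2, timestamp = "test")
  expect_equal(m2$root[m2$aspect == "mesial"], "M")
  expect_equal(m2$root[m2$aspect == "distal"], "D")
  expect_equal(m2$a_mm[m2$aspect == "mesial"], 22)
  expect_equal(m2$a_mm[m2$aspect == "distal"], 20.5)

  # missing distal CEJ: mesial still measured, distal flagged incomplete
  s3 <- make_site(rbind(pt("INC_OCL", 1), pt("APEX", 23),
                        pt("CEJ", 3, aspect = "mesial"),
                        pt("AC", 10, aspect = "mesial"),
                        pt("AC", 9.5, aspect = "distal")), mm_per_px = 1)
  m3 <- measure_site(s3, timestamp = "test")
  expect_equal(m3$status[m3$aspect == "mesial"], "ok")
  expect_equal(m3$status[m3$aspect == "distal"], "incomplete")
  expect_true(is.na(m3$b_mm[m3$aspect == "distal"]))
})

test_that("site invariants are enforced", {
  expect_error(make_site(pt("APEX", 10)), class = "relrbl_input_error")
  expect_error(make_site(rbind(pt("INC_OCL", 1), pt("INC_OCL", 2),
                               pt("APEX", 10))),
               class = "relrbl_input_error")
  expect_error(make_site(rbind(pt("INC_OCL", 1))), class = "relrbl_input_error")
  expect_error(make_site(rbind(pt("INC_OCL", 1), pt("APEX", 10),
                               pt("AC", 5, aspect = "mesial"),
                               pt("AC", 6, aspect = "mesial"))),
               class = "relrbl_input_error")
  expect_error(make_site(rbind(pt("INC_OCL", -1), pt("APEX", 10))),
               class = "relrbl_input_error")
})

test_that("relRBL is scale- and translation-invariant, a and b scale linearly", {
  set.seed(11)
  for (i in 1:50) {
    y <- sort(runif(4, 0, 400))
    pts <- rbind(pt("INC_OCL", y[1]), pt("CEJ", y[2], aspect = "mesial"),
                 pt("AC", y[3], aspect = "mesial"), pt("APEX", y[4]))
    m0 <- measure_site(make_site(pts, mm_per_px = 0.06), timestamp = "t")
    k <- runif(1, 0.1, 5)
    pts_k <- pts; pts_k$y <- pts_k$y * k
    mk <- measure_site(make_site(pts_k, mm_per_px = 0.06), timestamp = "t")
    expect_equal(mk$a_mm, m0$a_mm * k, tolerance = 1e-12)
    expect_equal(mk$b_mm, m0$b_mm * k, tolerance = 1e-12)
    expect_equal(mk$rel_rbl_pct, m0$rel_rbl_pct, tolerance = 1e-12)
    # same invariance when the calibration, not the pixels, changes
    mc <- measure_site(make_site(pts, mm_per_px = 0.06 * k), timestamp = "t")
    expect_equal(mc$rel_rbl_pct, m0$rel_rbl_pct, tolerance = 1e-12)
    # translation changes nothing
    pts_t <- pts; pts_t$y <- pts_t$y + runif(1, 0, 50)
    mt <- measure_site(make_site(pts_t, mm_per_px = 0.06), timestamp = "t")
    expect_equal(mt$a_mm, m0$a_mm, tolerance = 1e-9)
    expect_equal(mt$b_mm, m0$b_mm, tolerance = 1e-9)
  }
})

test_that("round trip with the projection simulator recovers truth exactly", {
  set.seed(13)
  for (i in 1:20) {
    tm <- random_tooth()
    true_rel <- 100 * (tm$h_cej - tm$h_ac) / (tm$length - tm$apex_heights)
    # plugin parity: untilted parallel projection at zero standoff is exact
    m0 <- measure_projected(project_tooth(tm, projection_geometry("parallel")))
    for (aspect in c("mesial", "distal")) {
      row <- m0[m0$aspect == aspect, ]
      expect_equal(row$a_mm, unname(tm$length - tm$apex_heights[[row$root]]),
                   tolerance = 1e-9)
      expect_equal(row$b_mm, tm$h_cej - tm$h_ac, tolerance = 1e-9)
    }
    # tilted: relRBL still exact, direct RBL biased by exactly the scale factor
    ar <- runif(1, 0, 45)
    g <- projection_geometry("parallel", receptor_tilt_deg = ar)
    m <- measure_projected(project_tooth(tm, g))
    for (aspect in c("mesial", "distal")) {
      row <- m[m$aspect == aspect, ]
      expect_equal(row$rel_rbl_pct,
                   unname(true_rel[[row$root]]), tolerance = 1e-9)
      expect_equal(row$b_mm, (tm$h_cej - tm$h_ac) / cos(ar * pi / 180),
                   tolerance = 1e-9)
    }
  }
})
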