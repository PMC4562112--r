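# Independent oracles used to cross-check the implementation.

# Brute-force ray-plane intersection: the receptor plane is represented by
# three points (origin and two in-plane basis points) and the intersection
# is found by solving the 3x3 linear system
#   S + t (P - S) = u e1 + v e2
# for (t, u, v) with base::solve().  No shared code with project_point().
oracle_project_point <- function(p, geometry) {
  a <- geometry$receptor_tilt_deg * pi / 180
  e1 <- c(1, 0, 0)
  e2 <- c(0, cos(a), sin(a))
  if (geometry$mode == "parallel") {
    dir <- c(0, 0, -1)
    sol <- solve(cbind(dir, -e1, -e2), -p)
  } else {
    s <- c(0, 0, geometry$focal_distance)
    sol <- solve(cbind(p - s, -e1, -e2), -s)
  }
  c(u = sol[2], v = sol[3])
}

# Naive two-way ANOVA mean squares from explicit sums of squares.
oracle_twoway_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  rowm <- rowMeans(mat); colm <- colMeans(mat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (mat[i, j] - rowm[i] - colm[j] + grand)^2
    }
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

oracle_icc21 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  ms <- oracle_twoway_ms(mat)
  (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
}

# Naive one-way ANOVA mean squares (sites as groups, repeats within).
oracle_oneway_ms <- function(mat) {
  n <- nrow(mat); r <- ncol(mat)
  grand <- mean(mat)
  rowm <- rowMeans(mat)
  ssb <- r * sum((rowm - grand)^2)
  ssw <- 0
  for (i in seq_len(n)) ssw <- ssw + sum((mat[i, ] - rowm[i])^2)
  list(msb = ssb / (n - 1), msw = ssw / (n * (r - 1)))
}

oracle_icc11 <- function(mat) {
  r <- ncol(mat)
  ms <- oracle_oneway_ms(mat)
  (ms$msb - ms$msw) / (ms$msb + (r - 1) * ms$msw)
}

# Random valid tooth model for property tests.
random_tooth <- function() {
  len <- runif(1, 15, 28)
  cej <- runif(1, len * 0.75, len * 0.95)
  ac <- runif(1, len * 0.2, cej)
  multi <- runif(1) < 0.5
  apex <- if (multi) c(M = 0, D = runif(1, 0, 2)) else c(single = 0)
  tooth_model(len, cej, ac, apex_heights = apex,
              aspect_offsets = c(mesial = runif(1, -4, -1),
                                 distal = runif(1, 1, 4)))
}

# Measure a projected landmark set through the full pixel-annotation path.
measure_projected <- function(pl, mm_per_px = 0.06, tooth_id = "t") {
  px_x <- (pl$u + 30) / mm_per_px
  px_y <- (60 - pl$v) / mm_per_px
  pts <- data.frame(label = pl$label, aspect = pl$aspect, root = pl$root,
                    x = px_x, y = px_y, stringsAsFactors = FALSE)
  site <- site_annotation("img", tooth_id, pts, calibration(mm_per_px))
  measure_site(site, timestamp = "test")
}
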