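# Independent brute-force oracles.  These re-derive the quantities the
# package computes through a deliberately different, simple-minded code
# path (per-pixel loops, stats::approx interpolation, dense searches) so
# agreement is meaningful.

# per-pixel aperture classification by direct interpolation of each leaf
# trajectory; returns "open", "mlc" or "jaw"
oracle_state <- function(beam, mu, x, y) {
  ms <- vapply(beam$control_points, function(cp) cp$cumulative_meterset, 0)
  lerp_field <- function(get) {
    vals <- t(vapply(beam$control_points, get,
                     numeric(length(get(beam$control_points[[1]])))))
    apply(vals, 2, function(col) stats::approx(ms, col, xout = mu,
                                               ties = "ordered")$y)
  }
  jaws <- lerp_field(function(cp) cp$jaw_positions)
  names(jaws) <- c("x1", "x2", "y1", "y2")
  if (x < jaws["x1"] || x > jaws["x2"] || y < jaws["y1"] || y > jaws["y2"])
    return("jaw")
  bnd <- beam$leaf_boundaries
  li <- NA
  for (i in seq_len(length(bnd) - 1)) {
    if (y >= bnd[i] && y < bnd[i + 1]) { li <- i; break }
  }
  if (is.na(li)) return("mlc")
  a <- lerp_field(function(cp) cp$leaf_a)[li]
  b <- lerp_field(function(cp) cp$leaf_b)[li]
  if (x > a && x < b) "open" else "mlc"
}

# MU-stepped fluence/mask oracle: n_steps equal midpoint sub-intervals.
# The aperture is interpolated once per step with stats::approx and the
# pixels classified with per-row scalar comparisons.
oracle_mask <- function(beam, sb, grid, model, settings, n_steps) {
  ms <- vapply(beam$control_points, function(cp) cp$cumulative_meterset, 0)
  leafA <- t(vapply(beam$control_points, function(cp) cp$leaf_a,
                    numeric(length(beam$control_points[[1]]$leaf_a))))
  leafB <- t(vapply(beam$control_points, function(cp) cp$leaf_b,
                    numeric(ncol(leafA))))
  jawM <- t(vapply(beam$control_points, function(cp) cp$jaw_positions,
                   numeric(4)))
  mids <- sb$mu_start + (seq_len(n_steps) - 0.5) *
    (sb$mu_end - sb$mu_start) / n_steps
  dmu <- (sb$mu_end - sb$mu_start) / n_steps
  interp_cols <- function(mat, mu) {
    apply(mat, 2, function(col) stats::approx(ms, col, xout = mu,
                                              ties = "ordered")$y)
  }
  bnd <- beam$leaf_boundaries
  # leaf index per grid row (y)
  li <- vapply(grid$y, function(y) {
    hit <- which(y >= bnd[-length(bnd)] & y < bnd[-1])
    if (length(hit)) hit[1] else NA_integer_
  }, 0L)
  U <- matrix(0, length(grid$x), length(grid$y))
  Cc <- U
  adj <- (settings$nominal_oofcf - 1) * settings$edf
  for (mu in mids) {
    a <- interp_cols(leafA, mu); b <- interp_cols(leafB, mu)
    j <- interp_cols(jawM, mu)
    for (iy in seq_along(grid$y)) {
      y <- grid$y[iy]
      for (ix in seq_along(grid$x)) {
        x <- grid$x[ix]
        st <- if (x < j[1] || x > j[2] || y < j[3] || y > j[4]) {
          "jaw"
        } else if (!is.na(li[iy]) && x > a[li[iy]] && x < b[li[iy]]) {
          "open"
        } else "mlc"
        w <- switch(st, open = 1, mlc = model$mlc_transmission,
                    jaw = model$jaw_transmission)
        U[ix, iy] <- U[ix, iy] + dmu * w
        Cc[ix, iy] <- Cc[ix, iy] + dmu * (w + if (st == "open") 0 else adj)
      }
    }
  }
  Cc / U
}

# dense exhaustive gamma over every evaluated voxel (no search window)
oracle_gamma <- function(ref_pts, ref_dose, evaluated, dta, tol) {
  ev_pts <- grid_points(evaluated)
  ev <- as.vector(evaluated$values)
  vapply(seq_len(nrow(ref_pts)), function(i) {
    d2 <- (ev_pts[, 1] - ref_pts[i, 1])^2 + (ev_pts[, 2] - ref_pts[i, 2])^2 +
      (ev_pts[, 3] - ref_pts[i, 3])^2
    sqrt(min(d2 / dta^2 + ((ev - ref_dose[i]) / tol[i])^2))
  }, 0)
}

# two-pass textbook mean/sd
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# a small random smooth 3D dose grid (peaked, strictly positive)
random_dose_grid <- function(dim = c(9, 9, 5), spacing = 2, peak = 2) {
  co <- lapply(dim, function(n) (seq_len(n) - (n + 1) / 2) * spacing)
  vals <- array(0, dim)
  for (k in seq_len(dim[3])) {
    vals[, , k] <- peak * outer(exp(-(co[[1]] / (spacing * dim[1] / 3))^2),
                                exp(-(co[[2]] / (spacing * dim[2] / 3))^2)) *
      exp(-(co[[3]][k] / (spacing * dim[3] / 2))^2)
  }
  vals <- vals * (1 + 0.05 * array(stats::runif(prod(dim), -1, 1), dim))
  dose_grid(origin = vapply(co, min, 0), spacing = spacing, values = vals)
}
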