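#' Beam geometry helpers
#'
#' The phantom frame keeps the detector-array cylinder axis along z and
#' the gantry rotating in the x-y plane.  At gantry angle 0 the source
#' sits at (0, SAD, 0) and the central axis points along -y; the angle
#' increases clockwise when viewed from the linac (towards +x at 90
#' degrees).  BEV x (leaf travel) and y (leaf boundaries, i.e. the
#' phantom z axis) span the isocenter plane.
#'
#' @param gantry_angle gantry angle in degrees.
#' @param sad source-axis distance in mm.
#' @return numeric length-3 source position in mm.
#' @export
source_position <- function(gantry_angle, sad = 1000) {
  g <- gantry_angle * pi / 180
  c(sad * sin(g), sad * cos(g), 0)
}

#' Project phantom points to BEV coordinates
#'
#' Central projection of each point onto the isocenter plane following
#' the divergent line from the source through the point.
#'
#' @param points N x 3 matrix (or length-3 vector) of phantom xyz in mm.
#' @param gantry_angle gantry angle in degrees.
#' @param sad source-axis distance in mm.
#' @return N x 2 matrix of BEV (x, y) in mm at the isocenter plane.
#' @export
project_to_bev <- function(points, gantry_angle, sad = 1000) {
  points <- rbind(points)
  g <- gantry_angle * pi / 180
  s <- source_position(gantry_angle, sad)
  # beam axis unit vector (source -> isocenter) and BEV basis
  u <- -s / sad
  ex <- c(cos(g), -sin(g), 0)
  v <- sweep(points, 2, s)                # point - source
  denom <- v %*% u
  if (any(denom <= 1e-9))
    stop("geometry error: ray parallel to the isocenter plane or point at/behind source")
  t <- sad / as.vector(denom)
  q <- sweep(v * t, 2, s, "+")
  cbind(q %*% ex, q[, 3])
}

#' Taper specification for the correction near the array surfaces
#'
#' The correction mask is constant over depth but tapered to unity at
#' the curved entry and exit surfaces of the detector-array cylinder:
#' the applied correction at a point is `1 + weight * (mask - 1)` with
#' the weight ramping linearly from 0 at the surface to 1 at
#' `taper_distance` inside (along the ray).
#'
#' @param taper_distance ramp length in mm along the ray (>= 0); 0 means
#'   full correction everywhere inside the cylinder.
#' @param cylinder_radius radius of the detector-array cylinder in mm.
#' @return an object of class `oof_taper`.
#' @export
taper_spec <- function(taper_distance = 10, cylinder_radius = 104) {
  if (taper_distance < 0) stop("validation: taper_distance must be >= 0")
  structure(list(taper_distance = taper_distance,
                 cylinder_radius = cylinder_radius),
            class = "oof_taper")
}

#' Taper weight of phantom points for one beam direction
#'
#' For each point, the ray from the source through the point is
#' intersected with the detector-array cylinder (axis = z).  The weight
#' is 0 at the entry/exit surface, rising linearly to 1 at
#' `taper_distance` inside, and 1 in the interior.  Points whose ray
#' misses the cylinder, or that lie outside the chord between entry and
#' exit, get weight 0 (no correction).
#'
#' @param points N x 3 matrix of phantom xyz in mm.
#' @param gantry_angle gantry angle in degrees.
#' @param taper an [taper_spec()].
#' @param sad source-axis distance in mm.
#' @return numeric vector of weights in \[0, 1\].
#' @export
taper_weight <- function(points, gantry_angle, taper, sad = 1000) {
  points <- rbind(points)
  s <- source_position(gantry_angle, sad)
  v <- sweep(points, 2, s)
  len <- sqrt(rowSums(v^2))
  d <- v / len
  # intersect ray s + t*d with infinite cylinder x^2 + y^2 = R^2
  a <- d[, 1]^2 + d[, 2]^2
  b <- 2 * (s[1] * d[, 1] + s[2] * d[, 2])
  cc <- s[1]^2 + s[2]^2 - taper$cylinder_radius^2
  disc <- b^2 - 4 * a * cc
  w <- numeric(nrow(points))
  hit <- disc > 0 & a > 1e-12
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t_in <- (-b[hit] - sq) / (2 * a[hit])
    t_out <- (-b[hit] + sq) / (2 * a[hit])
    tp <- len[hit]
    inside <- tp >= t_in & tp <= t_out
    margin <- pmin(tp - t_in, t_out - tp)
    wh <- numeric(length(tp))
    if (taper$taper_distance > 0) {
      wh[inside] <- pmin(margin[inside] / taper$taper_distance, 1)
    } else {
      wh[inside] <- 1
    }
    w[hit] <- wh
  }
  w
}

# Bilinear interpolation of a BEV-map (fluence/mask) at arbitrary BEV
# points; NA outside the map footprint.
sample_bev <- function(map, bev_xy) {
  gx <- map$grid$x; gy <- map$grid$y
  nx <- length(gx); ny <- length(gy)
  fx <- (bev_xy[, 1] - gx[1]) / map$grid$resolution
  fy <- (bev_xy[, 2] - gy[1]) / map$grid$resolution
  out <- rep(NA_real_, nrow(bev_xy))
  ok <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  if (!any(ok)) return(out)
  i0 <- pmax(pmin(floor(fx[ok]), nx - 2), 0)
  j0 <- pmax(pmin(floor(fy[ok]), ny - 2), 0)
  if (nx == 1) i0 <- rep(0, sum(ok))
  if (ny == 1) j0 <- rep(0, sum(ok))
  tx <- fx[ok] - i0; ty <- fy[ok] - j0
  if (nx == 1) tx <- 0
  if (ny == 1) ty <- 0
  v <- map$values
  idx <- function(i, j) 1 + i + nx * j
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  out[ok] <- v[idx(i0, j0)] * (1 - tx) * (1 - ty) +
    v[idx(i1, j0)] * tx * (1 - ty) +
    v[idx(i0, j1)] * (1 - tx) * ty +
    v[idx(i1, j1)] * tx * ty
  out
}

#' Apply a composite OOF correction mask to a subbeam dose grid
#'
#' Every voxel is projected individually to BEV along the divergent ray,
#' the mask is sampled by bilinear interpolation, and the voxel dose is
#' multiplied by `1 + taper_weight * (mask - 1)`.  Voxels projecting
#' outside the mask footprint are left unchanged; their count is
#' attached as attribute `n_outside_mask` (and reported via a message
#' when nonzero).
#'
#' @param subbeam_dose an `oof_dose_grid` holding the uncorrected
#'   subbeam dose.
#' @param mask an `oof_mask` from [composite_mask()].
#' @param gantry_angle beam gantry angle in degrees (subbeam midpoint
#'   angle for arcs).
#' @param taper a [taper_spec()].
#' @param sad source-axis distance in mm.
#' @param quiet suppress the outside-footprint message.
#' @return an `oof_dose_grid` with the corrected dose.
#' @export
apply_mask <- function(subbeam_dose, mask, gantry_angle, taper,
                       sad = 1000, quiet = FALSE) {
  pts <- grid_points(subbeam_dose)
  bev <- project_to_bev(pts, gantry_angle, sad)
  m <- sample_bev(mask, bev)
  n_outside <- sum(is.na(m))
  if (n_outside && !quiet)
    message(n_outside, " voxel(s) project outside the mask footprint; left unchanged")
  m[is.na(m)] <- 1
  w <- taper_weight(pts, gantry_angle, taper, sad)
  factor <- 1 + w * (m - 1)
  out <- subbeam_dose
  out$values <- array(as.vector(subbeam_dose$values) * factor,
                      dim = dim(subbeam_dose$values))
  attr(out, "n_outside_mask") <- n_outside
  out
}

#' Reconstruct OOF-corrected total dose for one beam
#'
#' Convenience pipeline: per subbeam, build the composite correction
#' mask, apply it to the supplied uncorrected subbeam dose grid (with
#' divergent projection, depth constancy and surface taper), then sum.
#'
#' @param beam an `oof_beam`.
#' @param subbeams [segment_subbeams()] output.
#' @param subbeam_doses list of `oof_dose_grid`, one per subbeam row.
#' @param model a [beam_model_params()].
#' @param settings an [oof_settings()].
#' @param taper a [taper_spec()].
#' @param bev BEV grid for the masks; default [bev_grid_for_beam()].
#' @param n_substeps substeps per subbeam (default MU-capped policy).
#' @return an `oof_dose_grid`, the corrected accumulated dose.
#' @export
reconstruct_corrected <- function(beam, subbeams, subbeam_doses, model,
                                  settings, taper,
                                  bev = bev_grid_for_beam(beam),
                                  n_substeps = NULL) {
  stopifnot(nrow(subbeams) == length(subbeam_doses))
  corrected <- vector("list", nrow(subbeams))
  for (i in seq_len(nrow(subbeams))) {
    sb <- as.list(subbeams[i, ])
    msk <- composite_mask(sb, beam, bev, model, settings, n_substeps)
    gmid <- (sb$gantry_start + sb$gantry_end) / 2
    corrected[[i]] <- apply_mask(subbeam_doses[[i]], msk, gmid, taper,
                                 sad = model$source_axis_distance,
                                 quiet = TRUE)
  }
  accumulate_dose(corrected)
}
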