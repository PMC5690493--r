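#' 3D dose grid
#'
#' Scalar dose on a regular 3D lattice in phantom coordinates.  `origin`
#' is the center of voxel (1,1,1) in mm; `spacing` the per-axis voxel
#' pitch in mm; `values` a 3D array in Gy indexed `[ix, iy, iz]`.  The
#' phantom frame has the cylinder axis of the detector array along z and
#' the gantry rotating in the x-y plane (gantry 0 along +y).
#'
#' @param origin numeric length-3, mm.
#' @param spacing numeric length-3 (or scalar), mm, all positive.
#' @param values numeric 3D array, Gy, finite and non-negative.
#' @return an object of class `oof_dose_grid`.
#' @export
dose_grid <- function(origin, spacing, values) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("validation: spacing must be positive")
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(!is.finite(values))) stop("validation: dose values must be finite")
  if (any(values < 0)) stop("validation: dose values must be non-negative")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 values = values),
            class = "oof_dose_grid")
}

#' @export
print.oof_dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("Dose grid ", d[1], "x", d[2], "x", d[3], " @ (",
      paste(format(x$spacing, trim = TRUE), collapse = ", "),
      ") mm, dose range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "] Gy\n", sep = "")
  invisible(x)
}

#' Voxel-center coordinates of a dose grid
#' @param grid an `oof_dose_grid`.
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_coords <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

#' All voxel-center positions of a dose grid
#' @param grid an `oof_dose_grid`.
#' @return N x 3 matrix of xyz positions, N = number of voxels, in the
#'   array's column-major order.
#' @export
grid_points <- function(grid) {
  co <- grid_coords(grid)
  d <- dim(grid$values)
  cbind(rep(co$x, times = d[2] * d[3]),
        rep(rep(co$y, each = d[1]), times = d[3]),
        rep(co$z, each = d[1] * d[2]))
}

same_lattice <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$origin - b$origin)) < 1e-6 &&
    max(abs(a$spacing - b$spacing)) < 1e-9
}

#' Sum corrected subbeam dose grids
#'
#' @param grids list of `oof_dose_grid` objects on identical lattices.
#' @return an `oof_dose_grid`, the voxelwise sum.
#' @export
accumulate_dose <- function(grids) {
  if (!length(grids)) stop("no dose grids to accumulate")
  out <- grids[[1]]
  for (g in grids[-1]) {
    if (!same_lattice(out, g)) stop("dose grid lattice mismatch")
    out$values <- out$values + g$values
  }
  out
}

#' Trilinear sampling of a dose grid at arbitrary points
#'
#' @param grid an `oof_dose_grid`.
#' @param points N x 3 matrix of xyz positions in mm.
#' @return numeric vector of length N; `NA` outside the grid extent.
#' @export
sample_dose <- function(grid, points) {
  points <- rbind(points)
  co <- grid_coords(grid)
  d <- dim(grid$values)
  fx <- (points[, 1] - grid$origin[1]) / grid$spacing[1]
  fy <- (points[, 2] - grid$origin[2]) / grid$spacing[2]
  fz <- (points[, 3] - grid$origin[3]) / grid$spacing[3]
  out <- rep(NA_real_, nrow(points))
  ok <- fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
    fz >= 0 & fz <= d[3] - 1
  if (!any(ok)) return(out)
  i0 <- pmin(floor(fx[ok]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy[ok]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(fz[ok]), d[3] - 2); k0 <- pmax(k0, 0)
  if (d[1] == 1) i0 <- rep(0, sum(ok))
  if (d[2] == 1) j0 <- rep(0, sum(ok))
  if (d[3] == 1) k0 <- rep(0, sum(ok))
  tx <- fx[ok] - i0; ty <- fy[ok] - j0; tz <- fz[ok] - k0
  if (d[1] == 1) tx <- 0
  if (d[2] == 1) ty <- 0
  if (d[3] == 1) tz <- 0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v <- grid$values
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  out[ok] <-
    v[idx(i0, j0, k0)] * (1 - tx) * (1 - ty) * (1 - tz) +
    v[idx(i1, j0, k0)] * tx * (1 - ty) * (1 - tz) +
    v[idx(i0, j1, k0)] * (1 - tx) * ty * (1 - tz) +
    v[idx(i1, j1, k0)] * tx * ty * (1 - tz) +
    v[idx(i0, j0, k1)] * (1 - tx) * (1 - ty) * tz +
    v[idx(i1, j0, k1)] * tx * (1 - ty) * tz +
    v[idx(i0, j1, k1)] * (1 - tx) * ty * tz +
    v[idx(i1, j1, k1)] * tx * ty * tz
  out
}

#' Write / read a dose grid as a self-describing CSV container
#'
#' Header comment lines carry `dim`, `origin` and `spacing`; the body is
#' one `dose` column in column-major voxel order.
#'
#' @param grid an `oof_dose_grid`.
#' @param path file path.
#' @return `write_dose_csv` returns `path` invisibly; `read_dose_csv`
#'   returns an `oof_dose_grid`.
#' @export
write_dose_csv <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# oofrecon dose_grid v1",
    paste0("# dim: ", paste(dim(grid$values), collapse = " ")),
    paste0("# origin: ", paste(sprintf("%.17g", grid$origin), collapse = " ")),
    paste0("# spacing: ", paste(sprintf("%.17g", grid$spacing), collapse = " ")),
    "dose"), con)
  writeLines(sprintf("%.17g", as.vector(grid$values)), con)
  invisible(path)
}

#' @rdname write_dose_csv
#' @export
read_dose_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gethdr <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("parse error: dose grid header missing '", key, "'")
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln[1]), " +")[[1]])
  }
  d <- as.integer(gethdr("dim"))
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "" & body != "dose"]
  vals <- as.numeric(body)
  if (length(vals) != prod(d))
    stop("parse error: dose grid body has ", length(vals),
         " values, expected ", prod(d))
  dose_grid(gethdr("origin"), gethdr("spacing"), array(vals, dim = d))
}
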