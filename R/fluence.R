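#' Regular BEV grid at the isocenter plane
#'
#' Pixel centers on a regular lattice in beam's-eye-view coordinates:
#' x along leaf travel, y along the leaf boundaries, mm at the isocenter
#' plane.
#'
#' @param xlim,ylim numeric length-2 extents in mm.
#' @param resolution pixel spacing in mm (default 1).
#' @return an object of class `oof_bev_grid` with `x`, `y`, `resolution`.
#' @export
bev_grid <- function(xlim, ylim, resolution = 1) {
  if (resolution <= 0) stop("resolution must be positive")
  x <- seq(xlim[1], xlim[2], by = resolution)
  y <- seq(ylim[1], ylim[2], by = resolution)
  if (!length(x) || !length(y)) stop("empty BEV grid")
  structure(list(x = x, y = y, resolution = resolution),
            class = "oof_bev_grid")
}

#' BEV grid covering a beam's apertures
#'
#' Covers the union of all control-point apertures (jaw rectangles) plus
#' a margin.
#'
#' @param beam an `oof_beam`.
#' @param margin margin in mm beyond the jaw extremes (default 20).
#' @param resolution pixel spacing in mm.
#' @return an `oof_bev_grid`.
#' @export
bev_grid_for_beam <- function(beam, margin = 20, resolution = 1) {
  jp <- vapply(beam$control_points, function(cp) cp$jaw_positions, numeric(4))
  bev_grid(c(min(jp["x1", ]) - margin, max(jp["x2", ]) + margin),
           c(min(jp["y1", ]) - margin, max(jp["y2", ]) + margin),
           resolution)
}

# Exposure-state codes over a BEV grid for one instantaneous aperture.
# 0 = open (inside the momentary aperture), 1 = under MLC, 2 = under jaw.
# Pixel-center point test; jaw blocking takes precedence over MLC.
STATE_OPEN <- 0L
STATE_MLC <- 1L
STATE_JAW <- 2L

#' Exposure state of BEV pixels under an instantaneous aperture
#'
#' Classifies each pixel center as directly irradiated (open), under an
#' MLC leaf, or under a jaw.  Jaw blocking takes precedence.  Pixels
#' beyond the transverse MLC leaf coverage are treated as under MLC.
#'
#' @param aperture as returned by [aperture_at()].
#' @param grid an `oof_bev_grid`.
#' @return integer matrix `length(grid$x)` x `length(grid$y)` with values
#'   0 (open), 1 (under_mlc), 2 (under_jaw).
#' @export
exposure_state <- function(aperture, grid) {
  x <- grid$x; y <- grid$y
  nx <- length(x); ny <- length(y)
  jp <- aperture$jaw_positions
  jaw_open_x <- x >= jp["x1"] & x <= jp["x2"]
  jaw_open_y <- y >= jp["y1"] & y <= jp["y2"]
  li <- findInterval(y, aperture$leaf_boundaries)
  covered <- li >= 1L & li <= length(aperture$leaf_a)
  li[!covered] <- 1L                      # placeholder, masked below
  amat <- matrix(aperture$leaf_a[li], nx, ny, byrow = TRUE)
  bmat <- matrix(aperture$leaf_b[li], nx, ny, byrow = TRUE)
  xm <- matrix(x, nx, ny)
  open_mlc <- xm > amat & xm < bmat
  open_mlc[, !covered] <- FALSE
  st <- matrix(STATE_MLC, nx, ny)
  st[open_mlc] <- STATE_OPEN
  jaw_blocked <- !(matrix(jaw_open_x, nx, ny) & matrix(jaw_open_y, nx, ny, byrow = TRUE))
  st[jaw_blocked] <- STATE_JAW
  st
}

#' Out-of-field correction settings
#'
#' @param nominal_oofcf the user-set nominal out-of-field correction
#'   factor; the default 1.0 means "no change".
#' @param edf energy dependence factor (from [beam_model_params()]).
#' @return an object of class `oof_settings`.
#' @export
oof_settings <- function(nominal_oofcf = 1.0, edf = 0.02) {
  if (nominal_oofcf <= 0) stop("validation: nominal_oofcf must be positive")
  structure(list(nominal_oofcf = nominal_oofcf, edf = edf),
            class = "oof_settings")
}

#' Per-MU out-of-field fluence adjustment
#'
#' The adjustment added to the fluence of a collimated pixel per unit MU:
#' `(nominal_oofcf - 1) * edf` for pixels under MLC or jaw, 0 for
#' directly irradiated pixels.
#'
#' @param state exposure state: `"open"`, `"under_mlc"`, `"under_jaw"`
#'   (or the integer codes 0/1/2 from [exposure_state()]).
#' @param settings an [oof_settings()].
#' @return dimensionless increment per unit MU.
#' @export
oof_adjustment <- function(state, settings) {
  code <- if (is.character(state)) {
    match(state, c("open", "under_mlc", "under_jaw")) - 1L
  } else as.integer(state)
  if (anyNA(code) || any(code < 0L | code > 2L)) stop("invalid exposure state")
  ifelse(code == STATE_OPEN, 0, (settings$nominal_oofcf - 1) * settings$edf)
}

# Internal workhorse: accumulate the MU-weighted exposure of every pixel
# over a subbeam.  Summation runs over equal MU sub-intervals; the
# aperture is sampled at the sub-interval midpoint meterset (midpoint
# rule, second-order accurate for linear leaf motion).  Returns the
# uncorrected fluence U and the collimated-MU integral B so that for any
# settings:  corrected = U + (oofcf - 1) * edf * B.
fluence_accumulate <- function(subbeam, beam, grid, model, n_substeps) {
  if (n_substeps < 1) stop("n_substeps must be >= 1")
  nx <- length(grid$x); ny <- length(grid$y)
  if (!nx || !ny) stop("empty BEV grid")
  U <- matrix(0, nx, ny)
  B <- matrix(0, nx, ny)
  w <- c(1, model$mlc_transmission, model$jaw_transmission)
  edges <- seq(subbeam$mu_start, subbeam$mu_end, length.out = n_substeps + 1L)
  dmu <- diff(edges)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  for (i in seq_len(n_substeps)) {
    st <- exposure_state(aperture_at(beam, mids[i]), grid)
    U <- U + dmu[i] * matrix(w[st + 1L], nx, ny)
    B <- B + dmu[i] * (st != STATE_OPEN)
  }
  list(uncorrected = U, blocked_mu = B, grid = grid)
}

default_substeps <- function(subbeam, mu_per_substep = 0.25) {
  max(1L, as.integer(ceiling((subbeam$mu_end - subbeam$mu_start) /
                               mu_per_substep - 1e-12)))
}

as_subbeam_row <- function(subbeam) {
  if (is.data.frame(subbeam)) {
    stopifnot(nrow(subbeam) == 1L)
    as.list(subbeam)
  } else subbeam
}

#' Uncorrected MU-weighted fluence of a subbeam
#'
#' Cumulative "exposure" of every BEV pixel over the subbeam's meterset
#' range: each MU sub-interval contributes its full MU where the pixel is
#' inside the open aperture, the MLC transmission fraction under a leaf,
#' and the jaw transmission fraction under a jaw.
#'
#' @param subbeam one row of [segment_subbeams()] output (or a list with
#'   `mu_start`, `mu_end`).
#' @param beam the `oof_beam` the subbeam belongs to.
#' @param grid an `oof_bev_grid`.
#' @param model a [beam_model_params()].
#' @param n_substeps number of MU sub-intervals; default one per 0.25 MU.
#' @return an object of class `oof_fluence` (`grid` plus `values` matrix
#'   in MU).
#' @export
uncorrected_fluence <- function(subbeam, beam, grid, model,
                                n_substeps = NULL) {
  sb <- as_subbeam_row(subbeam)
  if (is.null(n_substeps)) n_substeps <- default_substeps(sb)
  acc <- fluence_accumulate(sb, beam, grid, model, n_substeps)
  structure(list(grid = grid, values = acc$uncorrected),
            class = "oof_fluence")
}

#' Corrected MU-weighted fluence of a subbeam
#'
#' Uncorrected fluence plus the out-of-field adjustment accumulated over
#' the sub-intervals in which the pixel is collimated.
#'
#' @inheritParams uncorrected_fluence
#' @param settings an [oof_settings()].
#' @return an `oof_fluence`.
#' @export
corrected_fluence <- function(subbeam, beam, grid, model, settings,
                              n_substeps = NULL) {
  sb <- as_subbeam_row(subbeam)
  if (is.null(n_substeps)) n_substeps <- default_substeps(sb)
  acc <- fluence_accumulate(sb, beam, grid, model, n_substeps)
  vals <- acc$uncorrected +
    (settings$nominal_oofcf - 1) * settings$edf * acc$blocked_mu
  structure(list(grid = grid, values = vals), class = "oof_fluence")
}

#' Composite out-of-field correction mask of a subbeam
#'
#' The dimensionless per-pixel ratio of MU-integrated corrected to
#' uncorrected fluence.  It equals 1 exactly where the pixel was open for
#' the whole subbeam and reaches `(T + (oofcf-1)*edf) / T` where the
#' pixel was collimated throughout (T the governing transmission).
#'
#' @inheritParams corrected_fluence
#' @return an object of class `oof_mask` (`grid` plus dimensionless
#'   `values` matrix).
#' @export
composite_mask <- function(subbeam, beam, grid, model, settings,
                           n_substeps = NULL) {
  sb <- as_subbeam_row(subbeam)
  if (is.null(n_substeps)) n_substeps <- default_substeps(sb)
  acc <- fluence_accumulate(sb, beam, grid, model, n_substeps)
  mask_from_accumulator(acc, settings)
}

mask_from_accumulator <- function(acc, settings) {
  if (any(acc$uncorrected <= 0)) {
    bad <- which(acc$uncorrected <= 0, arr.ind = TRUE)[1, ]
    stop("configuration error: zero uncorrected fluence at BEV pixel (",
         acc$grid$x[bad[1]], ", ", acc$grid$y[bad[2]],
         ") mm - is a transmission fraction zero?")
  }
  vals <- 1 + (settings$nominal_oofcf - 1) * settings$edf *
    acc$blocked_mu / acc$uncorrected
  structure(list(grid = acc$grid, values = vals), class = "oof_mask")
}

#' @export
print.oof_mask <- function(x, ...) {
  cat("Composite OOF correction mask: ", length(x$grid$x), " x ",
      length(x$grid$y), " pixels @ ", x$grid$resolution, " mm, values in [",
      format(min(x$values), digits = 6), ", ",
      format(max(x$values), digits = 6), "]\n", sep = "")
  invisible(x)
}

#' @export
print.oof_fluence <- function(x, ...) {
  cat("Fluence map: ", length(x$grid$x), " x ", length(x$grid$y),
      " pixels @ ", x$grid$resolution, " mm, total ",
      format(sum(x$values), digits = 6), " MU.pixel\n", sep = "")
  invisible(x)
}

#' Export a fluence map or mask as CSV with a coordinate header
#'
#' Writes a comment header block (`# x:` / `# y:` coordinate lists) then
#' the value matrix, rows indexed by x, columns by y.
#'
#' @param map an `oof_fluence` or `oof_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bev_csv <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# x: ", paste(format(map$grid$x, trim = TRUE), collapse = " ")),
    paste0("# y: ", paste(format(map$grid$y, trim = TRUE), collapse = " "))
  ), con)
  utils::write.table(map$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
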