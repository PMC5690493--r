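#' Gamma comparison parameters
#'
#' @param dose_criterion dose-difference criterion in percent (e.g. 2 or 3).
#' @param dta distance-to-agreement criterion in mm.
#' @param normalization `"local"` (tolerance is a percent of the local
#'   reference dose) or `"global"` (percent of the reference maximum).
#' @param threshold low-dose analysis threshold as percent of the
#'   reference maximum; points below it are excluded.
#' @param search_radius_factor initial search radius as a multiple of
#'   `dta`; the search expands automatically when the running minimum
#'   could lie beyond it, so the reported gamma is the global minimum.
#' @param interp_fraction evaluated-distribution sampling step as a
#'   fraction of `dta` (default 1/10); `NULL` restricts candidates to
#'   the evaluated grid's own voxel centers (no interpolation).
#' @return an object of class `oof_gamma_params`.
#' @export
gamma_params <- function(dose_criterion = 2, dta = 2,
                         normalization = c("local", "global"),
                         threshold = 10, search_radius_factor = 3,
                         interp_fraction = 0.1) {
  normalization <- match.arg(normalization)
  if (dose_criterion <= 0 || dta <= 0) stop("criteria must be positive")
  if (threshold < 0 || threshold >= 100) stop("threshold must be in [0, 100)")
  structure(list(dose_criterion = dose_criterion, dta = dta,
                 normalization = normalization, threshold = threshold,
                 search_radius_factor = search_radius_factor,
                 interp_fraction = interp_fraction),
            class = "oof_gamma_params")
}

as_ref_points <- function(reference) {
  if (inherits(reference, "oof_dose_grid")) {
    pts <- grid_points(reference)
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
               dose = as.vector(reference$values))
  } else {
    stopifnot(all(c("x", "y", "z", "dose") %in% names(reference)))
    as.data.frame(reference)[, c("x", "y", "z", "dose")]
  }
}

# candidate offsets on a cubic lattice of pitch `step` within `radius`,
# restricted to axes along which the evaluated grid actually extends;
# returned sorted by distance from the origin.
gamma_offsets <- function(step, radius, active_axes) {
  ax <- lapply(1:3, function(k) {
    if (active_axes[k]) seq(-radius, radius, by = step) else 0
  })
  off <- as.matrix(expand.grid(dx = ax[[1]], dy = ax[[2]], dz = ax[[3]]))
  dist <- sqrt(rowSums(off^2))
  keep <- dist <= radius + 1e-9
  off <- off[keep, , drop = FALSE]
  dist <- dist[keep]
  o <- order(dist)
  list(off = off[o, , drop = FALSE], dist = dist[o])
}

#' Gamma-index comparison of a reference against an evaluated dose grid
#'
#' For every reference point above the low-dose threshold, the gamma
#' index is the minimum over the search neighbourhood of
#' `sqrt((distance/dta)^2 + (dose difference/tolerance)^2)`, the
#' tolerance being `dose_criterion` percent of the reference maximum
#' (global normalization) or of the point's own reference dose (local).
#' A point passes when gamma <= 1.
#'
#' @param reference the measured (or stand-in) distribution: an
#'   `oof_dose_grid` or a data.frame with columns `x`, `y`, `z`, `dose`.
#' @param evaluated the reconstructed/calculated distribution: an
#'   `oof_dose_grid`.
#' @param params an [gamma_params()].
#' @return an object of class `oof_gamma_result` with `per_point_gamma`
#'   (NA below threshold), `pass_rate` (%), `n_evaluated`,
#'   `median_dose_diff` (%), `above_threshold` (logical), `params`.
#' @export
gamma_analysis <- function(reference, evaluated, params = gamma_params()) {
  stopifnot(inherits(evaluated, "oof_dose_grid"))
  ref <- as_ref_points(reference)
  ref_max <- max(ref$dose)
  above <- ref$dose >= params$threshold / 100 * ref_max
  if (!any(above)) stop("no evaluable points above the low-dose threshold")
  tol <- if (params$normalization == "global") {
    rep(params$dose_criterion / 100 * ref_max, sum(above))
  } else {
    params$dose_criterion / 100 * ref$dose[above]
  }
  tol <- pmax(tol, 1e-12)
  rp <- as.matrix(ref[above, c("x", "y", "z")])
  rd <- ref$dose[above]
  d <- dim(evaluated$values)
  active <- d > 1
  step <- if (is.null(params$interp_fraction)) {
    NA_real_
  } else params$interp_fraction * params$dta
  gam <- numeric(nrow(rp))
  for (i in seq_len(nrow(rp))) {
    gam[i] <- gamma_one_point(rp[i, ], rd[i], tol[i], evaluated, params,
                              step, active)
  }
  g <- rep(NA_real_, nrow(ref))
  g[above] <- gam
  dd <- 100 * (sample_dose(evaluated, rp) - rd) / rd
  res <- structure(list(
    per_point_gamma = g,
    pass_rate = 100 * mean(gam <= 1 + 1e-9),
    n_evaluated = length(gam),
    median_dose_diff = stats::median(dd, na.rm = TRUE),
    above_threshold = above,
    params = params), class = "oof_gamma_result")
  res
}

# minimum gamma for one reference point, expanding the search radius
# until the running minimum cannot be improved by more distant samples.
gamma_one_point <- function(p, rdose, tol, evaluated, params, step, active) {
  radius <- params$search_radius_factor * params$dta
  repeat {
    g <- gamma_search(p, rdose, tol, evaluated, params$dta, step, radius,
                      active)
    if (g <= radius / params$dta + 1e-12) return(g)
    new_radius <- (g + 0.5) * params$dta
    if (!is.finite(g) || new_radius <= radius * (1 + 1e-9)) return(g)
    radius <- new_radius
  }
}

gamma_search <- function(p, rdose, tol, evaluated, dta, step, radius, active) {
  if (is.na(step)) {
    # voxel mode: candidates are the evaluated grid's own voxel centers
    pts <- grid_points(evaluated)
    dist2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
    keep <- dist2 <= radius^2 + 1e-9
    if (!any(keep)) return(Inf)
    ev <- as.vector(evaluated$values)[keep]
    sqrt(min(dist2[keep] / dta^2 + ((ev - rdose) / tol)^2))
  } else {
    cand <- gamma_offsets(step, radius, active)
    best <- Inf
    n <- nrow(cand$off)
    chunk <- 512L
    i <- 1L
    while (i <= n) {
      j <- min(i + chunk - 1L, n)
      if ((cand$dist[i] / dta)^2 >= best) break
      pos <- sweep(cand$off[i:j, , drop = FALSE], 2, p, "+")
      ev <- sample_dose(evaluated, pos)
      ok <- !is.na(ev)
      if (any(ok)) {
        g2 <- (cand$dist[i:j][ok] / dta)^2 + ((ev[ok] - rdose) / tol)^2
        best <- min(best, min(g2))
      }
      i <- j + 1L
    }
    sqrt(best)
  }
}

#' @export
print.oof_gamma_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Gamma %g%%%s/%g mm (threshold %g%%): pass rate %.1f%% (n = %d), median dose diff %+.2f%%\n",
              p$dose_criterion,
              if (p$normalization == "global") "G" else "L",
              p$dta, p$threshold, x$pass_rate, x$n_evaluated,
              x$median_dose_diff))
  invisible(x)
}

#' Median signed local percent dose difference
#'
#' Median over the above-threshold reference points of
#' `100 * (evaluated - reference) / reference`, the evaluated dose being
#' sampled at the reference positions.  The threshold mirrors the gamma
#' low-dose threshold (percent of reference maximum).
#'
#' @inheritParams gamma_analysis
#' @param threshold percent of the reference maximum.
#' @return the median difference in percent.
#' @export
median_dose_diff <- function(reference, evaluated, threshold = 10) {
  ref <- as_ref_points(reference)
  ref_max <- max(ref$dose)
  above <- ref$dose >= threshold / 100 * ref_max
  if (!any(above)) stop("no evaluable points above the low-dose threshold")
  rp <- as.matrix(ref[above, c("x", "y", "z")])
  ev <- sample_dose(evaluated, rp)
  stats::median(100 * (ev - ref$dose[above]) / ref$dose[above], na.rm = TRUE)
}

#' Append a per-comparison report row
#'
#' Builds (and optionally appends to CSV) one row shaped like the
#' published QA result tables: identifiers, criteria, pass rate and
#' median dose difference.
#'
#' @param plan,energy,technique identifiers.
#' @param result an `oof_gamma_result`.
#' @param path optional CSV path; the row is appended (with a header if
#'   the file does not yet exist).
#' @return the row as a one-line data.frame, invisibly if written.
#' @export
gamma_report_row <- function(plan, energy, technique, result, path = NULL) {
  p <- result$params
  row <- data.frame(
    plan = plan, energy = energy, technique = technique,
    criteria = sprintf("%g%%%s/%gmm", p$dose_criterion,
                       if (p$normalization == "global") "G" else "L", p$dta),
    pass_rate = result$pass_rate,
    median_dd = result$median_dose_diff)
  if (!is.null(path)) {
    utils::write.table(row, path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(path), append = file.exists(path))
    return(invisible(row))
  }
  row
}
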