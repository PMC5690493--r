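#' Control point of a beam
#'
#' A control point is a snapshot of the machine state at a cumulative
#' meterset value: gantry angle, the two MLC leaf banks and the jaws.
#' Positions are in mm projected to the isocenter plane, IEC-style beam
#' coordinates: BEV x is the leaf-travel direction, BEV y the
#' leaf-boundary direction.  Bank A tips must not exceed bank B tips
#' (equal means the pair is closed).
#'
#' @param cumulative_meterset cumulative meterset in MU at this snapshot.
#' @param gantry_angle gantry angle in degrees.
#' @param leaf_a,leaf_b numeric vectors of leaf-tip positions (mm) for the
#'   two banks, one entry per leaf pair; bank A is the low-x bank.
#' @param jaw_positions named numeric vector or list with elements
#'   `x1`, `x2`, `y1`, `y2` (mm); `x1 <= x2`, `y1 <= y2`.
#' @return an object of class `oof_cp`.
#' @export
control_point <- function(cumulative_meterset, gantry_angle, leaf_a, leaf_b,
                          jaw_positions) {
  jp <- unlist(jaw_positions)[c("x1", "x2", "y1", "y2")]
  if (anyNA(jp)) stop("jaw_positions must supply x1, x2, y1, y2")
  cp <- structure(list(
    cumulative_meterset = as.numeric(cumulative_meterset),
    gantry_angle = as.numeric(gantry_angle),
    leaf_a = as.numeric(leaf_a),
    leaf_b = as.numeric(leaf_b),
    jaw_positions = as.numeric(jp)
  ), class = "oof_cp")
  names(cp$jaw_positions) <- c("x1", "x2", "y1", "y2")
  validate_control_point(cp)
  cp
}

validate_control_point <- function(cp) {
  if (length(cp$leaf_a) != length(cp$leaf_b))
    stop("validation: leaf banks differ in length")
  if (any(cp$leaf_a > cp$leaf_b + 1e-9))
    stop("validation: bank A leaf position exceeds bank B for leaf pair ",
         which(cp$leaf_a > cp$leaf_b + 1e-9)[1])
  jp <- cp$jaw_positions
  if (jp["x1"] > jp["x2"] || jp["y1"] > jp["y2"])
    stop("validation: jaws do not form a rectangle (x1<=x2, y1<=y2 required)")
  invisible(cp)
}

#' Beam: an ordered control-point sequence plus MLC leaf geometry
#'
#' @param control_points list of [control_point()] objects ordered by
#'   cumulative meterset (non-decreasing).
#' @param leaf_boundaries numeric vector of the transverse leaf edges in mm
#'   (length = number of leaf pairs + 1), strictly increasing.
#' @param name beam label.
#' @param energy energy label, e.g. `"6X"`, `"15X"`, `"10XFFF"`.
#' @return an object of class `oof_beam`.
#' @export
beam <- function(control_points, leaf_boundaries, name = "beam", energy = "6X") {
  b <- structure(list(
    name = as.character(name),
    energy = as.character(energy),
    leaf_boundaries = as.numeric(leaf_boundaries),
    control_points = control_points
  ), class = "oof_beam")
  validate_beam(b)
  b
}

validate_beam <- function(b) {
  if (length(b$control_points) < 1) stop("validation: beam has no control points")
  if (is.unsorted(b$leaf_boundaries, strictly = TRUE))
    stop("validation: leaf_boundaries must be strictly increasing")
  nl <- length(b$leaf_boundaries) - 1L
  ms <- vapply(b$control_points, function(cp) cp$cumulative_meterset, 0)
  if (any(diff(ms) < -1e-9))
    stop("validation: cumulative_meterset decreases at control point ",
         which(diff(ms) < -1e-9)[1] + 1L)
  for (cp in b$control_points) {
    validate_control_point(cp)
    if (length(cp$leaf_a) != nl)
      stop("validation: control point has ", length(cp$leaf_a),
           " leaf pairs but leaf_boundaries define ", nl)
  }
  invisible(b)
}

#' Treatment plan: a named collection of beams
#'
#' @param beams list of [beam()] objects.
#' @param name plan label.
#' @return an object of class `oof_plan`.
#' @export
treatment_plan <- function(beams, name = "plan") {
  if (inherits(beams, "oof_beam")) beams <- list(beams)
  p <- structure(list(name = as.character(name), beams = beams),
                 class = "oof_plan")
  for (b in p$beams) validate_beam(b)
  p
}

#' @export
print.oof_plan <- function(x, ...) {
  cat("Treatment plan '", x$name, "': ", length(x$beams), " beam(s)\n", sep = "")
  for (b in x$beams) {
    ms <- meterset_range(b)
    cat("  ", b$name, " [", b$energy, "]: ",
        length(b$control_points), " control points, ",
        format(ms[2] - ms[1]), " MU\n", sep = "")
  }
  invisible(x)
}

#' @export
print.oof_beam <- function(x, ...) {
  ms <- meterset_range(x)
  cat("Beam '", x$name, "' [", x$energy, "]: ",
      length(x$control_points), " control points, meterset ",
      format(ms[1]), "-", format(ms[2]), " MU, ",
      length(x$leaf_boundaries) - 1L, " leaf pairs\n", sep = "")
  invisible(x)
}

metersets <- function(beam) {
  vapply(beam$control_points, function(cp) cp$cumulative_meterset, 0)
}

#' Meterset range of a beam
#' @param beam an `oof_beam`.
#' @return numeric length-2 vector, first and last cumulative meterset (MU).
#' @export
meterset_range <- function(beam) range(metersets(beam))

#' Beam model parameters
#'
#' Per-energy scalars entering the fluence and correction model: the MLC
#' and jaw transmission fractions, the energy dependence factor (EDF)
#' scaling the out-of-field adjustment (a small number, on the order of
#' 0.01 to 0.025, increasing with energy), and the source-axis distance.
#'
#' @param energy_label text label, e.g. `"6X"`.
#' @param edf energy dependence factor, dimensionless, in (0, 0.1).
#' @param mlc_transmission MLC transmission fraction in (0, 1).
#' @param jaw_transmission jaw transmission fraction, `0 <= jaw <= mlc`.
#' @param source_axis_distance source-axis distance in mm.
#' @return an object of class `oof_beam_model`.
#' @export
beam_model_params <- function(energy_label = "6X", edf = 0.02,
                              mlc_transmission = 0.02,
                              jaw_transmission = 0.005,
                              source_axis_distance = 1000) {
  if (!(mlc_transmission > 0 && mlc_transmission < 1))
    stop("validation: mlc_transmission must be in (0, 1)")
  if (jaw_transmission < 0 || jaw_transmission > mlc_transmission)
    stop("validation: jaw_transmission must satisfy 0 <= jaw <= mlc transmission")
  if (!(edf > 0 && edf < 0.1))
    stop("validation: edf must be in (0, 0.1)")
  structure(list(energy_label = energy_label, edf = edf,
                 mlc_transmission = mlc_transmission,
                 jaw_transmission = jaw_transmission,
                 source_axis_distance = source_axis_distance),
            class = "oof_beam_model")
}

#' Cylindrical detector array / phantom geometry
#'
#' Defaults describe a helical diode array: 1386 point detectors on a
#' 104 mm radius cylindrical surface inside a doughnut-shaped phantom of
#' 266 mm outer diameter, modeled with uniform relative density 1.15 and
#' the central plug inserted.
#'
#' @param array_radius radius of the detector cylinder, mm.
#' @param n_detectors number of point detectors.
#' @param phantom_outer_diameter outer diameter of the phantom, mm.
#' @param plug_present logical, central plug inserted.
#' @param relative_density phantom relative electron density.
#' @return an object of class `oof_detector_geometry`.
#' @export
detector_geometry <- function(array_radius = 104, n_detectors = 1386,
                              phantom_outer_diameter = 266,
                              plug_present = TRUE, relative_density = 1.15) {
  if (!(array_radius < phantom_outer_diameter / 2))
    stop("validation: array_radius must be smaller than the phantom outer radius")
  if (n_detectors <= 0) stop("validation: n_detectors must be positive")
  structure(list(array_radius = array_radius, n_detectors = n_detectors,
                 phantom_outer_diameter = phantom_outer_diameter,
                 plug_present = plug_present,
                 relative_density = relative_density),
            class = "oof_detector_geometry")
}

#' Segment a beam into time-resolved subbeams
#'
#' The default segmentation is one subbeam per control-point interval
#' (the finest granularity the plan defines); an interval whose meterset
#' exceeds `max_mu_per_subbeam` is split into equal parts.  Zero-MU
#' intervals (step-and-shoot aperture reconfigurations) carry no dose and
#' are skipped.  The MU ranges of the subbeams tile the beam meterset
#' range without overlap.
#'
#' @param beam an `oof_beam` with at least 2 control points.
#' @param max_mu_per_subbeam MU cap per subbeam; `Inf` disables splitting.
#' @return a data.frame of class `oof_subbeams` with columns `mu_start`,
#'   `mu_end`, `cp_start`, `cp_end`, `gantry_start`, `gantry_end`.
#' @export
segment_subbeams <- function(beam, max_mu_per_subbeam = Inf) {
  if (length(beam$control_points) < 2)
    stop("beam must have at least 2 control points")
  ms <- metersets(beam)
  ga <- vapply(beam$control_points, function(cp) cp$gantry_angle, 0)
  total <- ms[length(ms)] - ms[1]
  if (total <= 0) {
    warning("zero-MU beam: no subbeams")
    return(empty_subbeams())
  }
  rows <- list()
  for (k in seq_len(length(ms) - 1L)) {
    dmu <- ms[k + 1L] - ms[k]
    if (dmu <= 0) next
    nsplit <- max(1L, as.integer(ceiling(dmu / max_mu_per_subbeam - 1e-12)))
    edges <- seq(ms[k], ms[k + 1L], length.out = nsplit + 1L)
    gedges <- ga[k] + (edges - ms[k]) / dmu * (ga[k + 1L] - ga[k])
    for (j in seq_len(nsplit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mu_start = edges[j], mu_end = edges[j + 1L],
        cp_start = k, cp_end = k + 1L,
        gantry_start = gedges[j], gantry_end = gedges[j + 1L])
    }
  }
  sb <- do.call(rbind, rows)
  class(sb) <- c("oof_subbeams", "data.frame")
  sb
}

empty_subbeams <- function() {
  sb <- data.frame(mu_start = numeric(0), mu_end = numeric(0),
                   cp_start = integer(0), cp_end = integer(0),
                   gantry_start = numeric(0), gantry_end = numeric(0))
  class(sb) <- c("oof_subbeams", "data.frame")
  sb
}

#' Instantaneous aperture at a meterset value
#'
#' Leaf and jaw positions (and gantry angle) are linearly interpolated in
#' cumulative meterset between the bracketing control points; at a stored
#' control point the stored positions are returned verbatim.  Where
#' several control points share one meterset value (step-and-shoot), the
#' last of them is used.
#'
#' @param beam an `oof_beam`.
#' @param mu meterset value within the beam's meterset range.
#' @return list with `leaf_a`, `leaf_b`, `jaw_positions`, `gantry_angle`,
#'   `leaf_boundaries`.
#' @export
aperture_at <- function(beam, mu) {
  ms <- metersets(beam)
  n <- length(ms)
  if (mu < ms[1] - 1e-9 || mu > ms[n] + 1e-9)
    stop("mu = ", mu, " outside beam meterset range [", ms[1], ", ", ms[n], "]")
  exact <- which(abs(ms - mu) <= 1e-9)
  if (length(exact)) {
    cp <- beam$control_points[[max(exact)]]
    return(list(leaf_a = cp$leaf_a, leaf_b = cp$leaf_b,
                jaw_positions = cp$jaw_positions,
                gantry_angle = cp$gantry_angle,
                leaf_boundaries = beam$leaf_boundaries))
  }
  k <- findInterval(mu, ms)
  cp0 <- beam$control_points[[k]]
  cp1 <- beam$control_points[[k + 1L]]
  f <- (mu - ms[k]) / (ms[k + 1L] - ms[k])
  lerp <- function(a, b) a + f * (b - a)
  list(leaf_a = lerp(cp0$leaf_a, cp1$leaf_a),
       leaf_b = lerp(cp0$leaf_b, cp1$leaf_b),
       jaw_positions = lerp(cp0$jaw_positions, cp1$jaw_positions),
       gantry_angle = lerp(cp0$gantry_angle, cp1$gantry_angle),
       leaf_boundaries = beam$leaf_boundaries)
}

#' Write / read a plan in the simple structured-text dialect
#'
#' One human-readable YAML document per plan; keys follow the control
#' point field names (`cumulative_meterset`, `gantry_angle`,
#' `leaf_positions` with banks `a`/`b`, `jaw_positions`,
#' `leaf_boundaries`).  Numeric values are written with 17 significant
#' digits so a write/read round trip reproduces every field exactly.
#'
#' @param plan an `oof_plan`.
#' @param path file path.
#' @return `write_simple_plan` returns `path` invisibly;
#'   `read_simple_plan` returns an `oof_plan`.
#' @export
write_simple_plan <- function(plan, path) {
  doc <- list(
    name = plan$name,
    beams = lapply(plan$beams, function(b) list(
      name = b$name,
      energy = b$energy,
      leaf_boundaries = b$leaf_boundaries,
      control_points = lapply(b$control_points, function(cp) list(
        cumulative_meterset = cp$cumulative_meterset,
        gantry_angle = cp$gantry_angle,
        leaf_positions = list(a = cp$leaf_a, b = cp$leaf_b),
        jaw_positions = as.list(cp$jaw_positions)
      ))
    ))
  )
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' @rdname write_simple_plan
#' @export
read_simple_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse error in plan file '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$beams)) stop("parse error: plan file has no 'beams' record")
  beams <- lapply(doc$beams, function(b) {
    if (is.null(b$control_points))
      stop("parse error: beam '", b$name, "' has no 'control_points' record")
    cps <- lapply(b$control_points, function(cp) {
      control_point(cp$cumulative_meterset, cp$gantry_angle,
                    unlist(cp$leaf_positions$a), unlist(cp$leaf_positions$b),
                    cp$jaw_positions)
    })
    beam(cps, unlist(b$leaf_boundaries),
         name = if (is.null(b$name)) "beam" else b$name,
         energy = if (is.null(b$energy)) "6X" else b$energy)
  })
  treatment_plan(beams, name = if (is.null(doc$name)) "plan" else doc$name)
}

#' Load a treatment plan
#'
#' @param path file path.
#' @param dialect only `"simple"` (the structured-text plan dialect) is
#'   supported.
#' @return an `oof_plan`.
#' @export
load_plan <- function(path, dialect = c("simple")) {
  dialect <- match.arg(dialect)
  read_simple_plan(path)
}
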