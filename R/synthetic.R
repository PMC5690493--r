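#' Maximum measured out-of-field response ratio between array versions
#'
#' The ratio of old-design to new-design diode overresponse outside the
#' field varied from 1.0 to 1.17 across aperture geometries and
#' energies; the maximum, 1.17, is the natural cap for the nominal OOF
#' correction factor.
#' @export
MAX_OOF_RATIO <- 1.17

read_extdata <- function(fname) {
  path <- system.file("extdata", fname, package = "oofrecon")
  if (path == "") stop("packaged fixture not found: ", fname)
  utils::read.csv(path)
}

# monotone (Fritsch-Carlson) interpolator through the anchors, constant
# beyond the anchor range
anchor_curve <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  f <- stats::splinefun(x, y, method = "monoH.FC")
  function(q) f(pmin(pmax(q, x[1]), x[length(x)]))
}

#' Diode response model
#'
#' Multiplicative perturbations of a point-diode reading relative to an
#' ion chamber: low-MU (per-segment) nonlinearity, dose-per-pulse
#' (via source-to-detector distance), repetition-rate dependence
#' (anchored to 1 at 400 MU/min), an out-of-field overresponse factor
#' applied to the collimated dose component only, and optional
#' multiplicative Gaussian noise.  Curves interpolate monotonically
#' between packaged anchors; only the anchors marked `printed` in the
#' fixtures are measured values, the rest are smooth synthetic fill.
#'
#' @param energy `"6X"` or `"10XFFF"` (curve selection).
#' @param lowmu_setting acquisition setting, `"modified"` (long
#'   integration, the recommended default) or `"default"`.
#' @param lowmu_position `"entrance"` or `"exit"` diode curve.
#' @param oof_overresponse factor applied to the out-of-field (collimated)
#'   dose component; 1.0 models the redesigned array, 1.17 the maximum
#'   measured old-design overresponse.
#' @param noise_sd relative SD of multiplicative Gaussian noise (0 = none).
#' @param seed integer seed for the noise stream.
#' @return an object of class `oof_response_model` with curve functions
#'   `low_mu(mu)`, `dpp(sdd_mm)`, `rep_rate(mu_per_min)`.
#' @export
response_model <- function(energy = "6X", lowmu_setting = "modified",
                           lowmu_position = "entrance",
                           oof_overresponse = 1.0, noise_sd = 0,
                           seed = 1L) {
  rr <- read_extdata("response_reprate_anchors.csv")
  rr <- rr[rr$energy == energy, ]
  if (!nrow(rr)) stop("no repetition-rate anchors for energy ", energy)
  dp <- read_extdata("response_dpp_anchors.csv")
  dp <- dp[dp$energy == energy, ]
  lm <- read_extdata("response_lowmu_anchors.csv")
  lm <- lm[lm$setting == lowmu_setting & lm$position == lowmu_position, ]
  rep_curve <- anchor_curve(rr$mu_per_min, rr$relative_sensitivity)
  dpp_curve <- anchor_curve(dp$sdd_mm, dp$relative_sensitivity)
  lowmu_curve <- anchor_curve(lm$mu, lm$relative_sensitivity)
  if (abs(rep_curve(400) - 1) > 1e-9)
    stop("validation: repetition-rate curve must be 1 at 400 MU/min")
  if (abs(dpp_curve(896) - 1) > 1e-9)
    stop("validation: dose-per-pulse curve must be 1 at the 896 mm calibration SDD")
  structure(list(energy = energy, low_mu = lowmu_curve, dpp = dpp_curve,
                 rep_rate = rep_curve, oof_overresponse = oof_overresponse,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "oof_response_model")
}

#' Toy dose engine parameters
#'
#' A deliberately simple divergent-beam dose model used to exercise the
#' correction pipeline: dose = MU x calibration x inverse-square x
#' exponential attenuation along the water-equivalent path, with a
#' scatter floor plus transmission for collimated rays.  The default
#' attenuation coefficient is calibrated so the exit dose of the
#' cylindrical phantom is about one quarter of the entrance dose.
#'
#' @param mu_to_gy Gy per MU at the isocenter for an open ray before
#'   attenuation.
#' @param attenuation_coeff per mm of water-equivalent path.
#' @param scatter_floor fraction of the open-field dose reaching
#'   collimated rays (in addition to transmission).
#' @param sad source-axis distance, mm.
#' @return an object of class `oof_toy_params`.
#' @export
toy_dose_params <- function(mu_to_gy = 0.008, attenuation_coeff = 0.00405,
                            scatter_floor = 0.05, sad = 1000) {
  if (mu_to_gy <= 0 || attenuation_coeff <= 0 || scatter_floor <= 0)
    stop("validation: toy dose parameters must be positive")
  if (scatter_floor >= 1) stop("validation: scatter_floor must be < 1")
  structure(list(mu_to_gy = mu_to_gy, attenuation_coeff = attenuation_coeff,
                 scatter_floor = scatter_floor, sad = sad),
            class = "oof_toy_params")
}

# exposure state for arbitrary BEV points (vectorized scalar version of
# the grid classifier; same conventions)
exposure_state_points <- function(aperture, bev_x, bev_y) {
  jp <- aperture$jaw_positions
  st <- rep(STATE_MLC, length(bev_x))
  li <- findInterval(bev_y, aperture$leaf_boundaries)
  covered <- li >= 1L & li <= length(aperture$leaf_a)
  lic <- ifelse(covered, li, 1L)
  open_mlc <- covered & bev_x > aperture$leaf_a[lic] & bev_x < aperture$leaf_b[lic]
  st[open_mlc] <- STATE_OPEN
  jaw_blocked <- !(bev_x >= jp["x1"] & bev_x <= jp["x2"] &
                     bev_y >= jp["y1"] & bev_y <= jp["y2"])
  st[jaw_blocked] <- STATE_JAW
  st
}

#' Toy dose of a subbeam at arbitrary phantom points
#'
#' Per point: `dMU * mu_to_gy * inverse-square * exp(-mu_att * wepl) *
#' aperture_factor`, with the aperture sampled at the subbeam midpoint
#' meterset and the water-equivalent path measured from the phantom
#' entry surface along the divergent ray (geometric path times the
#' phantom relative density).  Open rays get aperture factor 1;
#' collimated rays get `scatter_floor + transmission`.
#'
#' @param subbeam one row of [segment_subbeams()] output.
#' @param beam the parent `oof_beam`.
#' @param points N x 3 matrix of phantom xyz, mm.
#' @param phantom a [detector_geometry()].
#' @param params a [toy_dose_params()].
#' @param model a [beam_model_params()] (transmission fractions).
#' @return numeric dose vector, Gy.
#' @export
toy_dose_at_points <- function(subbeam, beam, points, phantom, params,
                               model) {
  sb <- as_subbeam_row(subbeam)
  points <- rbind(points)
  dmu <- sb$mu_end - sb$mu_start
  mu_mid <- (sb$mu_start + sb$mu_end) / 2
  ap <- aperture_at(beam, mu_mid)
  gant <- ap$gantry_angle
  s <- source_position(gant, params$sad)
  v <- sweep(points, 2, s)
  r <- sqrt(rowSums(v^2))
  inv_sq <- (params$sad / r)^2
  # entry of the ray into the phantom outer cylinder
  d <- v / r
  Rout <- phantom$phantom_outer_diameter / 2
  a <- d[, 1]^2 + d[, 2]^2
  b <- 2 * (s[1] * d[, 1] + s[2] * d[, 2])
  cc <- s[1]^2 + s[2]^2 - Rout^2
  disc <- pmax(b^2 - 4 * a * cc, 0)
  t_in <- (-b - sqrt(disc)) / (2 * pmax(a, 1e-12))
  depth <- pmax(r - t_in, 0)
  depth[disc <= 0] <- 0
  wepl <- depth * phantom$relative_density
  bev <- project_to_bev(points, gant, params$sad)
  st <- exposure_state_points(ap, bev[, 1], bev[, 2])
  trans <- c(1, model$mlc_transmission, model$jaw_transmission)[st + 1L]
  apfac <- ifelse(st == STATE_OPEN, 1, params$scatter_floor + trans)
  dmu * params$mu_to_gy * inv_sq * exp(-params$attenuation_coeff * wepl) * apfac
}

#' Toy dose of a subbeam on a 3D dose grid
#'
#' @inheritParams toy_dose_at_points
#' @param lattice an `oof_dose_grid` defining the target lattice (its
#'   values are ignored).
#' @return an `oof_dose_grid`.
#' @export
toy_subbeam_dose <- function(subbeam, beam, lattice, phantom, params,
                             model) {
  pts <- grid_points(lattice)
  dose <- toy_dose_at_points(subbeam, beam, pts, phantom, params, model)
  dose_grid(lattice$origin, lattice$spacing,
            array(dose, dim = dim(lattice$values)))
}

#' Generate a synthetic treatment plan
#'
#' Plan menu: `static` open field (2 control points), `sliding_window`
#' leaf sweep, `arc` (full or partial rotation at a control-point
#' increment), `oof_test` (a narrow aperture offset so the isocenter
#' sits a set distance outside the field, as in the out-of-field
#' sensitivity measurements), and `random_dynamic` (random monotone leaf
#' trajectories, for property tests).  Deterministic given `seed`.
#'
#' @param type plan geometry, see above.
#' @param field_size length-2 field size (x, y) in mm.
#' @param n_control_points number of control points (>= 2; ignored for
#'   `static`/`oof_test`, which always use 2).
#' @param total_mu total beam meterset, MU.
#' @param seed integer seed (used by `random_dynamic`).
#' @param aperture_width `sliding_window`/`oof_test` aperture width, mm.
#' @param offset `oof_test`: distance from the isocenter to the nearer
#'   field edge, mm (10 or 20 in the measurement geometry).
#' @param arc_span `arc`: gantry span in degrees.
#' @param leaf_width uniform MLC leaf width, mm.
#' @param n_leaves number of leaf pairs.
#' @param energy energy label.
#' @return an `oof_plan` with one beam.
#' @export
generate_plan <- function(type = c("static", "sliding_window", "arc",
                                   "oof_test", "random_dynamic"),
                          field_size = c(100, 100), n_control_points = 2,
                          total_mu = 100, seed = 1L, aperture_width = 20,
                          offset = 10, arc_span = 360, leaf_width = 5,
                          n_leaves = 40, energy = "6X") {
  type <- match.arg(type)
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  bounds <- (seq_len(n_leaves + 1) - 1 - n_leaves / 2) * leaf_width
  half <- field_size / 2
  centers <- (bounds[-1] + bounds[-length(bounds)]) / 2
  in_field <- abs(centers) <= half[2] + 1e-9
  open_a <- ifelse(in_field, -half[1], 0)
  open_b <- ifelse(in_field, half[1], 0)
  jaws <- c(x1 = -half[1], x2 = half[1], y1 = -half[2], y2 = half[2])
  mk_cp <- function(mu, g, a, b, j = jaws) control_point(mu, g, a, b, j)
  cps <- switch(type,
    static = list(mk_cp(0, 0, open_a, open_b),
                  mk_cp(total_mu, 0, open_a, open_b)),
    oof_test = {
      # jaws stay wide; the MLC forms the narrow aperture offset from the
      # isocenter, so the measurement point sits under leaves, not jaws
      a <- ifelse(in_field, offset, offset)
      b <- ifelse(in_field, offset + aperture_width, offset)
      list(mk_cp(0, 0, a, b), mk_cp(total_mu, 0, a, b))
    },
    sliding_window = {
      n <- max(2L, as.integer(n_control_points))
      lapply(seq_len(n), function(k) {
        f <- (k - 1) / (n - 1)
        a0 <- -half[1] + f * (field_size[1] - aperture_width)
        a <- ifelse(in_field, a0, 0)
        b <- ifelse(in_field, a0 + aperture_width, 0)
        mk_cp(f * total_mu, 0, a, b)
      })
    },
    arc = {
      n <- max(2L, as.integer(n_control_points))
      lapply(seq_len(n), function(k) {
        f <- (k - 1) / (n - 1)
        mk_cp(f * total_mu, f * arc_span, open_a, open_b)
      })
    },
    random_dynamic = {
      n <- max(2L, as.integer(n_control_points))
      rs <- local_rng(seed, {
        lapply(seq_len(n), function(k) {
          a <- ifelse(in_field,
                      stats::runif(n_leaves, -half[1], half[1] - 5), 0)
          b <- ifelse(in_field, a + stats::runif(n_leaves, 1, half[1]), 0)
          list(a = a, b = pmin(b, half[1]))
        })
      })
      lapply(seq_len(n), function(k) {
        mk_cp((k - 1) / (n - 1) * total_mu, 0, rs[[k]]$a, rs[[k]]$b)
      })
    })
  treatment_plan(beam(cps, bounds, name = type, energy = energy),
                 name = paste0("synthetic-", type))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Positions of virtual diodes on the cylindrical array surface
#'
#' A regular ring lattice standing in for the helical array: `n_phi`
#' diodes per ring, `n_z` rings spanning `±z_extent`.
#'
#' @param geometry a [detector_geometry()].
#' @param n_phi diodes per ring.
#' @param n_z number of rings.
#' @param z_extent half-length of the sampled cylinder, mm.
#' @return N x 3 matrix of xyz positions, mm.
#' @export
diode_positions <- function(geometry = detector_geometry(), n_phi = 24,
                            n_z = 5, z_extent = 50) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  z <- if (n_z == 1) 0 else seq(-z_extent, z_extent, length.out = n_z)
  R <- geometry$array_radius
  pts <- expand.grid(phi = phi, z = z)
  cbind(R * cos(pts$phi), R * sin(pts$phi), pts$z)
}

#' Simulate diode readings from true dose
#'
#' `reading = true_dose x low_mu(segment MU) x dpp(SDD) x
#' rep_rate(rate) x (1 + collimated_fraction x (oof_overresponse - 1))
#' x noise`.  The response effects are composited multiplicatively and
#' independently; the overresponse applies only to the out-of-field
#' (collimated) dose component, whose share per diode is
#' `collimated_fraction`.
#'
#' @param true_dose numeric vector of true doses at the diodes, Gy.
#' @param segment_mu meterset of the delivered segment, MU (scalar or
#'   per diode).
#' @param rep_rate repetition rate, MU/min.
#' @param sdd source-to-detector distance, mm (scalar or per diode).
#' @param collimated_fraction per-diode fraction of the dose delivered
#'   while the diode was out of field (0 = fully in-field, 1 = fully
#'   blocked).
#' @param response an [response_model()].
#' @return numeric vector of simulated readings, Gy.
#' @export
virtual_diode_readings <- function(true_dose, segment_mu, rep_rate, sdd,
                                   collimated_fraction = 0,
                                   response = response_model()) {
  if (any(true_dose < 0)) stop("true_dose must be non-negative")
  n <- length(true_dose)
  fac <- response$low_mu(rep(segment_mu, length.out = n)) *
    response$dpp(rep(sdd, length.out = n)) *
    response$rep_rate(rep(rep_rate, length.out = n)) *
    (1 + rep(collimated_fraction, length.out = n) *
       (response$oof_overresponse - 1))
  noise <- if (response$noise_sd > 0) {
    local_rng(response$seed, 1 + stats::rnorm(n, 0, response$noise_sd))
  } else rep(1, n)
  true_dose * fac * noise
}

#' Normalized sensitivity-ratio analysis
#'
#' Divides device readings by reference readings condition by condition
#' and normalizes the ratios to a chosen condition (an open-field pair,
#' the 400 MU/min repetition rate, or the calibration SDD), as in the
#' dosimeter characterization analyses.
#'
#' @param device,reference numeric reading vectors over matched
#'   conditions.
#' @param conditions vector labeling the conditions (numeric or
#'   character).
#' @param normalize_at the condition whose ratio becomes 1.
#' @return data.frame with `condition`, `ratio`, `normalized_ratio`.
#' @export
sensitivity_ratio_analysis <- function(device, reference, conditions,
                                       normalize_at) {
  if (length(device) != length(reference) ||
      length(device) != length(conditions))
    stop("device, reference and conditions must have equal length")
  i <- which(conditions == normalize_at)
  if (!length(i)) stop("normalization condition '", normalize_at,
                       "' not present")
  ratio <- device / reference
  data.frame(condition = conditions, ratio = ratio,
             normalized_ratio = ratio / mean(ratio[i]))
}

#' Ratio of normalized sensitivity ratios between two device versions
#'
#' The per-condition ratio of two [sensitivity_ratio_analysis()] tables
#' (e.g. old-design over new-design array), quantifying the response
#' difference between hardware versions.
#'
#' @param tab_a,tab_b analysis tables over identical conditions.
#' @return data.frame with `condition` and `ratio_of_ratios`.
#' @export
ratio_of_ratios <- function(tab_a, tab_b) {
  if (!identical(tab_a$condition, tab_b$condition))
    stop("condition lists differ")
  data.frame(condition = tab_a$condition,
             ratio_of_ratios = tab_a$normalized_ratio / tab_b$normalized_ratio)
}
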