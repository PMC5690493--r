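# Shared builders for pipeline-level cases.

default_model <- function(edf = 0.02) {
  beam_model_params(energy_label = "6X", edf = edf, mlc_transmission = 0.02,
                    jaw_transmission = 0.005, source_axis_distance = 1000)
}

# a two-control-point beam whose bank-B leaves sweep linearly from x0 to
# x1 over total_mu (bank A parked wide open), for closed-form fluence
sweep_beam <- function(b0 = 0, b1 = 50, total_mu = 10, a = -50) {
  jaws <- c(x1 = -60, x2 = 60, y1 = -20, y2 = 20)
  cps <- list(
    control_point(0, 0, rep(a, 8), rep(b0, 8), jaws),
    control_point(total_mu, 0, rep(a, 8), rep(b1, 8), jaws))
  beam(cps, seq(-20, 20, by = 5))
}

# closed-loop tuning case: a small arc on the cylindrical phantom, toy
# subbeam doses on a coarse lattice, and a reference built by applying
# the correction with the true overresponse ratio; scored at biplanar
# detector positions in the phantom interior.
closed_loop_case <- function(true_R, n_cp = 13, field = 40, total_mu = 180,
                             edf = 0.02) {
  model <- default_model(edf)
  plan <- generate_plan("arc", field_size = field, n_control_points = n_cp,
                        total_mu = total_mu)
  b <- plan$beams[[1]]
  sbs <- segment_subbeams(b)
  lattice <- dose_grid(origin = c(-90, -90, -30), spacing = c(10, 10, 10),
                       values = array(0, c(19, 19, 7)))
  geom <- detector_geometry()
  tdp <- toy_dose_params()
  doses <- lapply(seq_len(nrow(sbs)), function(i)
    toy_subbeam_dose(as.list(sbs[i, ]), b, lattice, geom, tdp, model))
  taper <- taper_spec(10, geom$array_radius)
  bev <- bev_grid_for_beam(b, margin = 20, resolution = 2)
  ref_grid <- reconstruct_corrected(b, sbs, doses, model,
                                    oof_settings(true_R, edf), taper,
                                    bev = bev, n_substeps = 2)
  pts <- biplanar_positions()
  reference <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          dose = sample_dose(ref_grid, pts))
  list(beam = b, subbeams = sbs, doses = doses, reference = reference,
       model = model, taper = taper, bev = bev, lattice = lattice,
       ref_grid = ref_grid)
}

# two orthogonal detector planes inside the phantom (biplanar dosimeter
# stand-in), clear of the taper zone
biplanar_positions <- function(r = 80, step = 20, z_extent = 20) {
  u <- seq(-r, r, by = step)
  z <- seq(-z_extent, z_extent, by = 20)
  p1 <- expand.grid(x = u, y = 0, z = z)
  p2 <- expand.grid(x = 0, y = u[u != 0], z = z)
  as.matrix(rbind(p1, p2))
}

tuning_gparams <- function() {
  gamma_params(dose_criterion = 2, dta = 2, normalization = "local",
               threshold = 10, search_radius_factor = 2,
               interp_fraction = 0.5)
}
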