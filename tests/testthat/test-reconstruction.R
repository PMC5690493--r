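model <- default_model()

test_that("divergent projection maps phantom points onto the isocenter plane", {
  expect_equal(as.numeric(project_to_bev(c(0, 0, 0), 0)), c(0, 0))
  expect_equal(as.numeric(project_to_bev(c(10, 0, 0), 0)), c(10, 0))
  # 100 mm upstream of isocenter: magnified by SAD/(SAD - 100)
  expect_equal(as.numeric(project_to_bev(c(10, 100, 0), 0, sad = 1000)),
               c(10 * 1000 / 900, 0), tolerance = 1e-12)
  # gantry rotation: the same physical point seen from 90 degrees
  expect_equal(as.numeric(project_to_bev(c(0, 10, 0), 90, sad = 1000)),
               c(-10, 0), tolerance = 1e-9)
  # z is the BEV y axis for any gantry angle
  expect_equal(project_to_bev(c(0, 0, 25), 137)[2], 25, tolerance = 1e-9)
  expect_error(project_to_bev(c(0, 2000, 0), 0, sad = 1000), "geometry error")
})

test_that("taper weight ramps linearly from the array surfaces", {
  tp <- taper_spec(10, 104)
  expect_equal(taper_weight(c(0, 104, 0), 0, tp), 0)    # entry surface
  expect_equal(taper_weight(c(0, -104, 0), 0, tp), 0)   # exit surface
  expect_equal(taper_weight(c(0, 99, 0), 0, tp), 0.5)   # half a ramp in
  expect_equal(taper_weight(c(0, 0, 0), 0, tp), 1)      # interior
  expect_equal(taper_weight(c(0, 150, 0), 0, tp), 0)    # outside cylinder
  # degenerate taper: full weight everywhere inside
  tp0 <- taper_spec(0, 104)
  expect_equal(taper_weight(rbind(c(0, 0, 0), c(0, 103.9, 0)), 0, tp0),
               c(1, 1))
  expect_error(taper_spec(-1), "taper_distance")
})

test_that("applying an identity mask leaves dose unchanged", {
  g <- dose_grid(c(-50, -50, -10), 10, array(runif(11 * 11 * 3, 1, 2),
                                             c(11, 11, 3)))
  mask1 <- structure(list(grid = bev_grid(c(-80, 80), c(-80, 80), 4),
                          values = matrix(1, 41, 41)), class = "oof_mask")
  out <- apply_mask(g, mask1, 0, taper_spec(10, 104), quiet = TRUE)
  expect_equal(out$values, g$values)
})

test_that("a uniform mask with zero taper scales every interior voxel", {
  # all voxels inside the array cylinder
  g <- dose_grid(c(-50, -50, -10), 10, array(1, c(11, 11, 3)))
  masku <- structure(list(grid = bev_grid(c(-120, 120), c(-120, 120), 4),
                          values = matrix(1.17, 61, 61)), class = "oof_mask")
  out <- apply_mask(g, masku, 0, taper_spec(0, 104), quiet = TRUE)
  expect_equal(out$values, array(1.17, c(11, 11, 3)), tolerance = 1e-12)
})

test_that("the applied correction follows the ramp-plateau-ramp closed form along a ray", {
  # voxel column along the gantry-0 central axis (the y axis)
  ys <- seq(-100, 100, by = 5)
  g <- dose_grid(c(0, -100, 0), c(1, 5, 1),
                 array(1, c(1, length(ys), 1)))
  masku <- structure(list(grid = bev_grid(c(-10, 10), c(-10, 10), 5),
                          values = matrix(1.2, 5, 5)), class = "oof_mask")
  td <- 10
  out <- apply_mask(g, masku, 0, taper_spec(td, 104), quiet = TRUE)
  got <- as.vector(out$values)
  # closed form: weight = clamp(min(104 - |y|...) along the ray) — on the
  # central axis the ray depth from entry is (104 - y), to exit (y + 104)
  w <- pmax(pmin(pmin(104 - ys, ys + 104) / td, 1), 0)
  expect_equal(got, 1 + w * 0.2, tolerance = 1e-9)
})

test_that("dose accumulation is exact and validates lattices", {
  g1 <- dose_grid(c(0, 0, 0), 5, array(1:8 / 8, c(2, 2, 2)))
  expect_equal(accumulate_dose(list(g1))$values, g1$values)
  expect_equal(accumulate_dose(list(g1, g1))$values, 2 * g1$values)
  g2 <- dose_grid(c(1, 0, 0), 5, array(1, c(2, 2, 2)))
  expect_error(accumulate_dose(list(g1, g2)), "mismatch")
})

test_that("total corrected dose is invariant under subbeam re-segmentation at OOFCF 1", {
  plan <- generate_plan("static", field_size = 60, total_mu = 50)
  b <- plan$beams[[1]]
  geom <- detector_geometry()
  tdp <- toy_dose_params()
  lattice <- dose_grid(c(-60, -60, -10), 20, array(0, c(7, 7, 2)))
  taper <- taper_spec(10, 104)
  bev <- bev_grid_for_beam(b, 20, 4)
  total_for <- function(max_mu) {
    sbs <- segment_subbeams(b, max_mu)
    doses <- lapply(seq_len(nrow(sbs)), function(i)
      toy_subbeam_dose(as.list(sbs[i, ]), b, lattice, geom, tdp, model))
    reconstruct_corrected(b, sbs, doses, model, oof_settings(1.0, 0.02),
                          taper, bev = bev, n_substeps = 2)
  }
  one <- total_for(Inf)
  many <- total_for(7.3)   # 7 unequal subbeams
  expect_lt(max(abs(one$values - many$values)), 1e-9)
})

test_that("correction adds dose only under collimation and is depth-constant", {
  plan <- generate_plan("oof_test", aperture_width = 20, offset = 10,
                        total_mu = 100)
  b <- plan$beams[[1]]
  sbs <- segment_subbeams(b)
  geom <- detector_geometry()
  lattice <- dose_grid(c(-40, -80, 0), c(5, 8, 1),
                       array(0, c(17, 21, 1)))
  doses <- list(toy_subbeam_dose(as.list(sbs[1, ]), b, lattice, geom,
                                 toy_dose_params(), model))
  unc <- reconstruct_corrected(b, sbs, doses, model, oof_settings(1, 0.02),
                               taper_spec(10, 104), n_substeps = 2)
  cor <- reconstruct_corrected(b, sbs, doses, model,
                               oof_settings(1.17, 0.02),
                               taper_spec(10, 104), n_substeps = 2)
  ratio <- cor$values / unc$values
  co <- grid_coords(lattice)
  # voxels whose rays stay inside the aperture: unchanged exactly
  open_x <- which(abs(co$x - 20) <= 4)   # near aperture center x=20
  expect_true(all(abs(ratio[open_x, 11, 1] - 1) < 1e-6))
  # blocked voxels inside the array get boosted
  blk_x <- which(co$x == 0)
  expect_true(all(ratio[blk_x, 8:14, 1] > 1.0001))
  # depth constancy away from the taper: along y at x=0 the applied
  # correction is constant where the taper weight is 1
  interior <- which(abs(co$y) <= 80)
  vals <- ratio[blk_x, interior, 1]
  expect_lt(max(vals) - min(vals), 1e-3)
})

test_that("dose grids round-trip through the CSV container", {
  g <- random_dose_grid(c(4, 3, 2), spacing = 2.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dose_csv(g, f)
  back <- read_dose_csv(f)
  expect_equal(back$values, g$values)
  expect_equal(back$origin, g$origin)
  expect_equal(back$spacing, g$spacing)
})

test_that("trilinear sampling reproduces a linear dose field exactly", {
  co <- list(x = seq(0, 10, 2), y = seq(0, 8, 2), z = seq(0, 4, 2))
  vals <- array(0, c(6, 5, 3))
  for (i in 1:6) for (j in 1:5) for (k in 1:3)
    vals[i, j, k] <- 1 + 0.3 * co$x[i] - 0.2 * co$y[j] + 0.1 * co$z[k]
  g <- dose_grid(c(0, 0, 0), 2, pmax(vals, 0))
  pts <- rbind(c(1.3, 2.7, 0.9), c(5, 5, 2.5), c(0, 0, 0))
  want <- 1 + 0.3 * pts[, 1] - 0.2 * pts[, 2] + 0.1 * pts[, 3]
  expect_equal(sample_dose(g, pts), want, tolerance = 1e-12)
  expect_true(is.na(sample_dose(g, c(-1, 0, 0))))
})
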