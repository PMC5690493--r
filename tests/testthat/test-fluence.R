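model <- default_model(edf = 0.02)

test_that("exposure state classifies open, jaw and abutted-leaf pixels", {
  plan <- generate_plan("static", field_size = 100, total_mu = 100)
  b <- plan$beams[[1]]
  ap <- aperture_at(b, 50)
  g <- bev_grid(c(-70, 70), c(-70, 70), 10)
  st <- exposure_state(ap, g)
  center <- c(which(g$x == 0), which(g$y == 0))
  expect_equal(st[center[1], center[2]], 0L)            # open
  expect_equal(st[which(g$x == 60), which(g$y == 0)], 2L)  # 1 cm outside jaw
  # abutted leaf tips: bank A = bank B -> pixel between them is under MLC
  nl <- length(b$leaf_boundaries) - 1
  ap2 <- ap
  ap2$leaf_a <- rep(0, nl); ap2$leaf_b <- rep(0, nl)
  st2 <- exposure_state(ap2, g)
  expect_equal(st2[center[1], center[2]], 1L)
  # and the oracle's independent point test agrees across the grid
  for (ix in seq(1, length(g$x), by = 3)) for (iy in seq(1, length(g$y), by = 3)) {
    want <- switch(oracle_state(b, 50, g$x[ix], g$y[iy]),
                   open = 0L, mlc = 1L, jaw = 2L)
    expect_equal(st[ix, iy], want)
  }
})

test_that("static fluence equals MU times the transmission weight", {
  plan <- generate_plan("static", field_size = 100, total_mu = 10)
  b <- plan$beams[[1]]
  sb <- as.list(segment_subbeams(b)[1, ])
  g <- bev_grid(c(-45, 45), c(-45, 45), 15)
  fl <- uncorrected_fluence(sb, b, g, model, n_substeps = 3)
  expect_true(all(abs(fl$values - 10) < 1e-12))  # fully open field
  # fully blocked pixel: narrow aperture far from origin
  p2 <- generate_plan("oof_test", aperture_width = 5, offset = 10,
                      total_mu = 10)
  b2 <- p2$beams[[1]]
  sb2 <- as.list(segment_subbeams(b2)[1, ])
  g0 <- bev_grid(c(0, 0), c(0, 0), 1)
  fl2 <- uncorrected_fluence(sb2, b2, g0, model, n_substeps = 2)
  expect_equal(as.numeric(fl2$values), 10 * 0.02, tolerance = 1e-12)
})

test_that("a pixel open for half a linear sweep accumulates half MU plus transmission", {
  b <- sweep_beam(b0 = 0, b1 = 50, total_mu = 10)
  g <- bev_grid(c(25, 25), c(0, 0), 1)   # bank B crosses x=25 at MU 5
  fl <- uncorrected_fluence(as.list(segment_subbeams(b)[1, ]), b, g, model,
                            n_substeps = 4096)
  expect_equal(as.numeric(fl$values), 5 * 1 + 5 * 0.02, tolerance = 1e-3)
})

test_that("the OOF adjustment follows the two-branch rule", {
  s <- oof_settings(1.17, edf = 0.02)
  expect_equal(oof_adjustment("open", s), 0)
  expect_equal(oof_adjustment("under_mlc", oof_settings(1.0, 0.02)), 0)
  expect_equal(oof_adjustment("under_mlc", s), 0.17 * 0.02)
  expect_equal(oof_adjustment("under_jaw", s), 0.17 * 0.02)
  expect_equal(oof_adjustment(0L, s), 0)
  expect_error(oof_adjustment("elsewhere", s), "invalid")
  expect_error(oof_settings(0), "positive")
})

test_that("corrected fluence adds the adjustment only under collimation", {
  p <- generate_plan("oof_test", aperture_width = 5, offset = 10,
                     total_mu = 10)
  b <- p$beams[[1]]
  sb <- as.list(segment_subbeams(b)[1, ])
  s <- oof_settings(1.17, edf = 0.02)
  g0 <- bev_grid(c(0, 0), c(0, 0), 1)      # always blocked
  cf <- corrected_fluence(sb, b, g0, model, s, n_substeps = 2)
  expect_equal(as.numeric(cf$values), (0.02 + 0.17 * 0.02) * 10,
               tolerance = 1e-12)
  gopen <- bev_grid(c(12, 12), c(0, 0), 1) # inside the aperture
  expect_equal(as.numeric(corrected_fluence(sb, b, gopen, model, s,
                                            n_substeps = 2)$values),
               as.numeric(uncorrected_fluence(sb, b, gopen, model,
                                              n_substeps = 2)$values))
  # OOFCF = 1: corrected == uncorrected everywhere
  g <- bev_grid(c(-30, 30), c(-30, 30), 10)
  expect_equal(corrected_fluence(sb, b, g, model, oof_settings(1, 0.02),
                                 n_substeps = 4)$values,
               uncorrected_fluence(sb, b, g, model, n_substeps = 4)$values)
})

test_that("composite mask hits the analytic extremes", {
  # fully open static field: mask identically 1
  p <- generate_plan("static", field_size = 100, total_mu = 10)
  b <- p$beams[[1]]
  sb <- as.list(segment_subbeams(b)[1, ])
  g <- bev_grid(c(-45, 45), c(-45, 45), 15)
  msk <- composite_mask(sb, b, g, model, oof_settings(1.17, 0.02),
                        n_substeps = 2)
  expect_true(all(abs(msk$values - 1) < 1e-12))
  # always-blocked pixel: (T + (oofcf-1)*edf) / T
  p2 <- generate_plan("oof_test", aperture_width = 5, offset = 10,
                      total_mu = 10)
  b2 <- p2$beams[[1]]
  sb2 <- as.list(segment_subbeams(b2)[1, ])
  g0 <- bev_grid(c(0, 0), c(0, 0), 1)
  m2 <- composite_mask(sb2, b2, g0, model, oof_settings(1.17, 0.02),
                       n_substeps = 2)
  expect_equal(as.numeric(m2$values), (0.02 + 0.17 * 0.02) / 0.02,
               tolerance = 1e-12)
  # pixel open half the MU: ratio of half-open to half-blocked integrals
  bsw <- sweep_beam(b0 = 0, b1 = 50, total_mu = 10)
  gh <- bev_grid(c(25, 25), c(0, 0), 1)
  mh <- composite_mask(as.list(segment_subbeams(bsw)[1, ]), bsw, gh, model,
                       oof_settings(1.17, 0.02), n_substeps = 4096)
  expect_equal(as.numeric(mh$values),
               (0.5 * 1 + 0.5 * 0.0234) / (0.5 * 1 + 0.5 * 0.02),
               tolerance = 1e-4)
})

test_that("mask is identity at OOFCF 1, monotone and bounded in OOFCF", {
  for (seed in 1:4) {
    plan <- generate_plan("random_dynamic", n_control_points = 4,
                          total_mu = 20, seed = seed)
    b <- plan$beams[[1]]
    sb <- as.list(segment_subbeams(b, 10)[1, ])
    g <- bev_grid(c(-60, 60), c(-60, 60), 12)
    m1 <- composite_mask(sb, b, g, model, oof_settings(1.0, 0.02),
                         n_substeps = 8)
    expect_true(all(abs(m1$values - 1) < 1e-12))
    prev <- m1$values
    for (f in c(1.05, 1.1, 1.17, 1.25)) {
      mf <- composite_mask(sb, b, g, model, oof_settings(f, 0.02),
                           n_substeps = 8)$values
      expect_true(all(mf >= prev - 1e-12))    # non-decreasing in OOFCF
      expect_true(all(mf >= 1 - 1e-12))
      # bound with the smallest applicable transmission
      expect_true(all(mf <= 1 + (f - 1) * 0.02 / model$jaw_transmission + 1e-12))
      prev <- mf
    }
  }
})

test_that("substep integration agrees with the brute-force oracle and converges", {
  plan <- generate_plan("random_dynamic", n_control_points = 5,
                        total_mu = 16, seed = 11)
  b <- plan$beams[[1]]
  sb <- as.list(segment_subbeams(b, 16)[1, ])
  g <- bev_grid(c(-50, 50), c(-50, 50), 5)   # 21 x 21
  s <- oof_settings(1.17, 0.02)
  slow <- oracle_mask(b, sb, g, model, s, n_steps = 4096)
  # at matched discretization the two code paths compute the same integral
  fast4096 <- composite_mask(sb, b, g, model, s, n_substeps = 4096)$values
  expect_lt(max(abs(fast4096 - slow)), 1e-10)
  # coarser substeps converge towards the fine oracle ...
  errs <- vapply(c(16, 64, 256), function(n)
    max(abs(composite_mask(sb, b, g, model, s, n_substeps = n)$values -
              slow)), 0)
  expect_lt(errs[3], errs[1])
  # ... and each error respects the open-fraction quantization bound
  # |dm/df| <= (oofcf-1)*edf / T_mlc^2 with |df| <= 1/(2n) + 1/(2*4096)
  bound <- function(n) 0.17 * 0.02 / 0.02^2 * (0.5 / n + 0.5 / 4096)
  expect_lt(errs[1], bound(16))
  expect_lt(errs[2], bound(64))
  expect_lt(errs[3], bound(256))
})

test_that("zero transmission is reported as a configuration error", {
  # a transmission of exactly zero cannot arise from the constructor, so
  # emulate a degenerate accumulator directly through the mask pipeline
  p <- generate_plan("static", field_size = 100, total_mu = 0.5)
  b <- p$beams[[1]]
  g <- bev_grid(c(0, 0), c(0, 0), 1)
  expect_error(
    composite_mask(list(mu_start = 0, mu_end = 0), b, g, model,
                   oof_settings(1.1, 0.02), n_substeps = 1),
    "zero uncorrected fluence")
})

test_that("fluence maps export as CSV with a coordinate header", {
  p <- generate_plan("static", field_size = 40, total_mu = 5)
  b <- p$beams[[1]]
  g <- bev_grid(c(-10, 10), c(-10, 10), 10)
  fl <- uncorrected_fluence(as.list(segment_subbeams(b)[1, ]), b, g, model,
                            n_substeps = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_bev_csv(fl, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# x: ")
  expect_match(lines[2], "^# y: ")
  vals <- as.matrix(utils::read.csv(f, header = FALSE, comment.char = "#"))
  expect_equal(dim(vals), c(3, 3))
  expect_equal(as.numeric(vals[2, 2]), 5)
})
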