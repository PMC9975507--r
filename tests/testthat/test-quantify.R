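test_that("PDL formula evaluates correctly and rejects bad counts", {
  expect_equal(compute_pdl(2e5, 2e5, 7), 7.0)
  expect_equal(compute_pdl(4e5, 2e5, 5), 5.9633, tolerance = 1e-3)
  # doubling the harvest adds exactly 3.2 * log10(2), independent of scale
  for (h in c(1e4, 3e5, 2e6)) {
    expect_equal(compute_pdl(2 * h, h, 0), 3.2 * log10(2))
    expect_equal(compute_pdl(2 * h, 1e4, 2) - compute_pdl(h, 1e4, 2),
                 3.2 * log10(2))
  }
  expect_error(compute_pdl(1e5, 0, 3), "positive")
  expect_error(compute_pdl(0, 1e5, 3), "positive")
})

test_that("CTCF is the background-corrected integrated density", {
  expect_equal(compute_ctcf(1000, 50, 10), 500)
  # uniform region: integrated density = v * area, background = v -> 0
  expect_equal(compute_ctcf(42 * 30, 30, 42), 0)
  expect_equal(compute_ctcf(1234, 10, 0), 1234)
  # unit slope in integrated density, slope -area in background
  expect_equal(compute_ctcf(2000, 50, 10) - compute_ctcf(1000, 50, 10), 1000)
  expect_equal(compute_ctcf(2000, 50, 12) - compute_ctcf(2000, 50, 10),
               -50 * 2)
  expect_warning(out <- compute_ctcf(100, 50, 10), "negative CTCF")
  expect_equal(out, -400)
  expect_error(compute_ctcf(100, 0, 1), "area")
})

test_that("foci counting applies band, size and mask rules", {
  img <- matrix(0, 32, 32)
  expect_equal(count_foci(img), 0)
  # three disjoint 3x3 blocks at intensity 100
  img[2:4, 2:4] <- 100; img[10:12, 10:12] <- 100; img[20:22, 25:27] <- 100
  expect_equal(count_foci(img), 3)
  # below min_size
  small <- matrix(0, 10, 10); small[2:3, 2:3] <- 100
  expect_equal(count_foci(small), 0)
  expect_equal(count_foci(small, min_size = 4), 1)
  # above the band
  bright <- matrix(0, 10, 10); bright[2:4, 2:4] <- 250
  expect_equal(count_foci(bright), 0)
  # band is inclusive at both ends
  edge <- matrix(0, 10, 10); edge[1:3, 1:3] <- 20; edge[6:8, 6:8] <- 200
  expect_equal(count_foci(edge), 2)
  # mask removes out-of-nucleus foci
  mask <- matrix(0, 32, 32); mask[1:16, ] <- 1
  expect_equal(count_foci(img, mask), 2)
  # diagonal contact merges components (8-connectivity)
  diag2 <- matrix(0, 10, 10)
  diag2[2:4, 2:4] <- 100; diag2[5:7, 5:7] <- 100
  expect_equal(count_foci(diag2), 1)
  expect_error(count_foci(img, matrix(1, 2, 2)), "shape")
  expect_error(count_foci(img, band = c(200, 20)), "band")
})

test_that("foci counter agrees with a flood-fill oracle on random patches", {
  set.seed(20240101)
  for (i in seq_len(200)) {
    img <- matrix(sample(c(0, 50, 250), 32 * 32, replace = TRUE,
                         prob = c(0.72, 0.2, 0.08)), 32, 32)
    mask <- matrix(rbinom(32 * 32, 1, 0.85), 32, 32)
    ms <- sample(1:6, 1)
    expect_identical(count_foci(img, mask, min_size = ms),
                     oracle_count_foci(img, mask, min_size = ms))
  }
})

test_that("nucleus area is the mask pixel count", {
  expect_equal(measure_nucleus_area(matrix(1, 10, 10)), 100)
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  expect_equal(measure_nucleus_area(m), 1)
  set.seed(7)
  rnd <- matrix(rbinom(400, 1, 0.4), 20, 20)
  rnd[1, 1] <- 1
  expect_equal(measure_nucleus_area(rnd), sum(rnd))
  expect_error(measure_nucleus_area(matrix(0, 4, 4)), "empty")
})

test_that("delta-delta-Ct fold changes", {
  # dCt equal to the calibrator -> fold 1
  expect_equal(relative_expression(c(24, 24), c(20, 20), 4), 1.0)
  # one extra doubling
  expect_equal(relative_expression(c(23, 23), c(20, 20), 4), 2.0)
  # duplicates averaged on the Cq scale: ddCt = 5.1 - 4.1 = 1 -> 0.5
  expect_equal(relative_expression(c(25.0, 25.2), c(20.0, 20.0), 4.1), 0.5,
               tolerance = 1e-6)
  # a sample against itself as calibrator is exactly 1
  tc <- c(27.3, 27.5); rc <- c(19.9, 20.1)
  expect_identical(relative_expression(tc, rc, mean(tc) - mean(rc)), 1)
  expect_error(relative_expression(numeric(0), c(20)), "non-empty")
})

test_that("standard curves fit, invert and report efficiency", {
  conc <- 100 / 3^(0:6)
  sc <- fit_standard_curve(conc, 30 - 3.3219 * log10(conc))
  expect_equal(sc$slope, -3.3219, tolerance = 1e-6)
  expect_equal(sc$efficiency, 1.0, tolerance = 0.01)
  expect_equal(sc$r_squared, 1.0, tolerance = 1e-9)
  # two points: interpolation is exact
  sc2 <- fit_standard_curve(c(1, 100), c(30, 23))
  expect_equal(invert_standard_curve(sc2, 30), 1, tolerance = 1e-12)
  expect_equal(invert_standard_curve(sc2, 23), 100, tolerance = 1e-12)
  # fit + inversion is the identity on noiseless data
  sc3 <- fit_standard_curve(conc, 28 - 3.45 * log10(conc))
  expect_equal(invert_standard_curve(sc3, 28 - 3.45 * log10(conc)), conc,
               tolerance = 1e-9)
  # noisy recovery of a known slope
  set.seed(11)
  noisy <- fit_standard_curve(conc, 30 - 3.5 * log10(conc) +
                                rnorm(7, 0, 0.05))
  expect_equal(noisy$slope, -3.5, tolerance = 0.05)
  expect_error(fit_standard_curve(c(10, 10), c(25, 25.1)), "distinct")
  expect_error(fit_standard_curve(5, 25), "distinct|lengths")
})

test_that("telomere T/S ratio inverts per-plate curves and runs QC", {
  curves <- list(
    P1 = list(telomere = make_curve(22), single_copy = make_curve(28)),
    P2 = list(telomere = make_curve(22.5), single_copy = make_curve(27.5)),
    P3 = list(telomere = make_curve(21.8), single_copy = make_curve(28.2))
  )
  cq_at <- function(curve, q) curve$intercept + curve$slope * log10(q)
  # sample equal to the 10 ng/uL standard on both targets -> ratio 1
  cq1 <- do.call(rbind, lapply(names(curves), function(p) {
    data.frame(plate_id = p, target = c("telomere", "single_copy"),
               cq = c(cq_at(curves[[p]]$telomere, 10),
                      cq_at(curves[[p]]$single_copy, 10)))
  }))
  r1 <- telomere_ts_ratio(cq1, curves)
  expect_equal(r1$per_plate_ratios, rep(1, 3), tolerance = 1e-9)
  expect_equal(r1$tlr, 1, tolerance = 1e-9)
  expect_equal(r1$cv, 0, tolerance = 1e-9)
  expect_true(r1$qc_pass)
  # forward-simulated 2-fold telomere excess
  cq2 <- do.call(rbind, lapply(names(curves), function(p) {
    data.frame(plate_id = p, target = c("telomere", "single_copy"),
               cq = c(cq_at(curves[[p]]$telomere, 40),
                      cq_at(curves[[p]]$single_copy, 20)))
  }))
  expect_equal(telomere_ts_ratio(cq2, curves)$tlr, 2, tolerance = 1e-6)
  # invariance to a common input-quantity factor
  for (f in c(0.25, 3)) {
    cqf <- do.call(rbind, lapply(names(curves), function(p) {
      data.frame(plate_id = p, target = c("telomere", "single_copy"),
                 cq = c(cq_at(curves[[p]]$telomere, 40 * f),
                        cq_at(curves[[p]]$single_copy, 20 * f)))
    }))
    expect_equal(telomere_ts_ratio(cqf, curves)$tlr, 2, tolerance = 1e-6)
  }
  # plate ratios {1, 1, 2}: CV = sd/mean of that triple, QC fails
  cq3 <- do.call(rbind, lapply(seq_along(curves), function(i) {
    p <- names(curves)[i]
    qt <- if (i == 3) 20 else 10
    data.frame(plate_id = p, target = c("telomere", "single_copy"),
               cq = c(cq_at(curves[[p]]$telomere, qt),
                      cq_at(curves[[p]]$single_copy, 10)))
  }))
  r3 <- telomere_ts_ratio(cq3, curves)
  expect_equal(r3$cv, sd(c(1, 1, 2)) / mean(c(1, 1, 2)), tolerance = 1e-9)
  expect_false(r3$qc_pass)
  expect_error(telomere_ts_ratio(cq1[-1, ], curves), "exactly one")
})

test_that("SA-bGal positive fraction", {
  expect_equal(sabgal_fraction(20, 100), 0.2)
  expect_equal(sabgal_fraction(0, 50), 0)
  expect_equal(sabgal_fraction(50, 50), 1)
  expect_error(sabgal_fraction(5, 0), "total")
  expect_error(sabgal_fraction(60, 50), "positive")
})
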