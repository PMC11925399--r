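test_that("sphere shells are deterministic, closed and near-uniform", {
  sh1 <- generate_sphere_shell(200, seed = 1)
  sh2 <- generate_sphere_shell(200, seed = 1)
  expect_identical(sh1, sh2)
  d <- validate_shell(sh1)
  expect_true(d$ok)
  expect_identical(d$euler, 2L)
  g <- shell_geometry(sh1)
  R <- sqrt(200 / (4 * pi))
  expect_lt(abs(mean(g$areas) - 4 * pi * R^2 / 200) /
              (4 * pi * R^2 / 200), 0.1)
})

test_that("nematic patterns have the prescribed defect content", {
  sh <- generate_sphere_shell(200, seed = 1)

  f_late <- init_nematic(sh, "late_defects")
  d <- detect_defects(sh, f_late)
  expect_equal(attr(d, "total_charge"), 2)
  expect_setequal(round(2 * sort(d$charge)) / 2, c(0.5, 0.5, 1))
  expect_equal(nrow(d), 3L)

  f4 <- init_nematic(sh, "four_half")
  d4 <- detect_defects(sh, f4)
  expect_equal(nrow(d4), 4L)
  expect_true(all(abs(d4$charge - 0.5) < 1e-9))
  expect_equal(attr(d4, "total_charge"), 2)

  f_r1 <- init_nematic(sh, "random", seed = 9)
  f_r2 <- init_nematic(sh, "random", seed = 9)
  expect_identical(f_r1$psi, f_r2$psi)
})

test_that("every pattern on a closed shell carries total charge +2", {
  sh <- generate_sphere_shell(150, seed = 4)
  for (pat in c("fragment", "late_defects", "four_half", "uniform",
                "random"))
    expect_equal(attr(detect_defects(sh, init_nematic(sh, pat,
                                                      seed = 2)),
                      "total_charge"), 2)
})

test_that("fragment pattern confines defects to the disordered region", {
  sh <- generate_sphere_shell(200, seed = 1)
  f <- init_nematic(sh, "fragment", seed = 3)
  info <- attr(f, "pattern_info")
  expect_true(abs(mean(info$region == "disordered") - 1 / 3) < 0.12)
  d <- detect_defects(sh, f)
  # no defect interior to the ordered band: every defect within one cell
  # of the disordered region (boundary vertices touch both regions)
  gd <- graph_distances(sh, which(info$region == "disordered"))
  expect_true(all(gd[d$cell] <= 1))
  expect_equal(attr(d, "total_charge"), 2)
})

test_that("fiber image rendering is deterministic with exact ground truth", {
  im1 <- render_fiber_image("pair", size = 96, noise = 0.2, seed = 5)
  im2 <- render_fiber_image("pair", size = 96, noise = 0.2, seed = 5)
  expect_identical(im1$image, im2$image)

  st <- render_fiber_image("stripes", size = 64, angle = pi / 6)
  expect_true(all(abs(st$orientation - pi / 6) < 1e-12))

  as <- render_fiber_image("aster", size = 64)
  ctr <- as$center
  i <- 10; j <- 50
  expect_equal(as$orientation[i, j],
               atan2(i - ctr[2], j - ctr[1]) %% pi, tolerance = 1e-12)
})

test_that("synthetic event series reproduces its own ground truth", {
  n <- 60
  dmap <- c(0L, rep(1L, 5), rep(2L, 10), rep(3L, 14), rep(4L, 14),
            rep(5L, 16))
  flat <- synthetic_event_series(n, 20, dmap, amplitude = 0)
  expect_true(all(abs(flat$areas - 1) < 1e-12))
  prof0 <- log_area_strain_profile(flat$areas[1, ], flat$areas[10, ],
                                   dmap)
  expect_identical(classify_event(prof0), "none")

  ser <- synthetic_event_series(n, 31, dmap, amplitude = log(2),
                                duration = 2)
  pk <- find_peak_frame(ser$areas, dmap)
  expect_equal(pk, ser$truth$peak_frame)
  prof <- log_area_strain_profile(ser$areas[1, ], ser$areas[pk, ], dmap)
  expect_equal(attr(prof, "core"), log(2), tolerance = 1e-6)
})

test_that("noisy series recover the generator truth within 3 sigma", {
  n <- 60
  dmap <- c(0L, rep(1L, 5), rep(2L, 10), rep(3L, 14), rep(4L, 14),
            rep(5L, 16))
  noise <- 0.05
  fails <- 0L
  for (s in 1:100) {
    ser <- synthetic_event_series(n, 21, dmap, amplitude = log(2),
                                  noise = noise, seed = s)
    pk <- find_peak_frame(ser$areas, dmap)
    prof <- log_area_strain_profile(ser$areas[1, ], ser$areas[pk, ],
                                    dmap)
    tr <- ser$truth$profile
    # 3 sigma of the per-distance mean of a log-normal difference
    for (k in seq_len(nrow(tr))) {
      nd <- sum(dmap == tr$distance[k])
      tol <- 3 * noise * sqrt(2) / sqrt(nd)
      if (abs(prof$mean[k] - tr$mean[k]) > tol + 0.05)
        fails <- fails + 1L
    }
  }
  expect_lte(fails, 5L)
})
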