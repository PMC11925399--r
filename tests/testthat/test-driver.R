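test_that("contraction amplitude is a Gaussian pulse train", {
  pr <- contraction_protocol(2, dT = 3, period = 30)
  pr$centers <- c(10, 40)
  expect_equal(contraction_amplitude(10, pr), 2, tolerance = 1e-12)
  expect_equal(contraction_amplitude(13, pr), 2 * exp(-0.5),
               tolerance = 1e-6)
  pr2 <- contraction_protocol(1, dT = 1, period = 40)
  pr2$centers <- c(0, 40)
  expect_lt(contraction_amplitude(20, pr2), 1e-21)
  expect_error(contraction_protocol(-1), "non-negative")
  expect_error(contraction_protocol(1, dT = 50, period = 30), "period")
})

test_that("zero-amplitude events produce zero strain", {
  scn <- event_scenario(n_cells = 120, seed = 2)
  rec <- run_single_event(scn, contraction_protocol(0))
  for (f in rec$foci)
    expect_lt(abs(f$core_strain), 1e-4)
})

test_that("single events recover elastically after the pulse", {
  scn <- event_scenario(n_cells = 150, seed = 3)
  rec <- run_single_event(scn, contraction_protocol(0.7),
                          t_end = scn$state$time + 18)
  st <- rec$final_state
  st <- relax_state(st, tol = 1e-3, max_steps = 10000, t1 = FALSE)
  a_end <- shell_geometry(st$shell)$areas
  a_start <- rec$area_series[1, ]
  expect_lt(max(abs(a_end / a_start - 1)), 0.01)
  expect_identical(rec$n_t1, 0L)
})

test_that("fragment events focus comparable strain at both caps", {
  # single realizations fluctuate with the random cap orientations; the
  # two foci are statistically equivalent, so compare seed-averaged
  # core strains
  s1 <- s2 <- numeric(0)
  for (seed in 1:3) {
    scn <- event_scenario(n_cells = 300, seed = seed,
                          pattern = "fragment")
    rec <- suppressWarnings(
      run_single_event(scn, contraction_protocol(1.05)))
    s1 <- c(s1, rec$foci$cap_head$core_strain)
    s2 <- c(s2, rec$foci$cap_foot$core_strain)
  }
  expect_gt(mean(s1), 0.1)
  expect_gt(mean(s2), 0.1)
  expect_lt(abs(mean(s1) - mean(s2)) / max(mean(s1), mean(s2)), 0.25)
})

test_that("calibration returns zero for a zero target and is monotone", {
  scn <- event_scenario(n_cells = 120, seed = 4)
  expect_equal(calibrate_zeta(scn, target = 0)$zeta_M, 0)
  cal <- calibrate_zeta(scn, target = 0.3, tol = 0.06, max_iter = 8)
  h <- cal$history[order(cal$history$zeta_M), ]
  h <- h[!is.na(h$strain), ]
  expect_true(all(diff(h$strain) > -0.05))
})

test_that("outcome classification follows the organizer rules", {
  sh <- generate_sphere_shell(150, seed = 5)
  g <- shell_geometry(sh)

  # four +1/2 defects, uniform low morphogen -> four_half
  nem4 <- init_nematic(sh, "four_half")
  mor0 <- morphogen_field(sh, N = 0.01)
  out4 <- classify_outcome(sh, nem4, mor0)
  expect_identical(out4$category, "four_half")

  # +1 with an adjacent peak plus a +1/2 pair -> single organizer
  nemL <- init_nematic(sh, "late_defects")
  d <- detect_defects(sh, nemL)
  plus1_cell <- d$cell[abs(d$charge - 1) < 1e-9]
  morP <- morphogen_field(sh, N = 0.01)
  morP$N[plus1_cell] <- 5
  outS <- classify_outcome(sh, nemL, morP)
  expect_identical(outS$category, "single_organizer")

  # two +1 defects (uniform axial pattern) with peaks at both poles
  nemU <- init_nematic(sh, "uniform")
  dU <- detect_defects(sh, nemU)
  morT <- morphogen_field(sh, N = 0.01)
  morT$N[dU$cell] <- 5
  outT <- classify_outcome(sh, nemU, morT)
  expect_identical(outT$category, "two_organizers")
})

test_that("short regeneration runs are bitwise deterministic", {
  r1 <- run_regeneration(n_cells = 60, seed = 2, n_pulses = 2)
  r2 <- run_regeneration(n_cells = 60, seed = 2, n_pulses = 2)
  expect_identical(r1$outcome$category, r2$outcome$category)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$state$shell$positions, r2$state$shell$positions)
  expect_identical(r1$state$nematic$psi, r2$state$nematic$psi)
})

test_that("phase scan emits a tidy table and records failures", {
  tab <- phase_scan(eps_th_values = c(0.45, 5), alpha_values = c(0, 5),
                    seeds = 1, n_cells = 60, n_pulses = 2)
  expect_identical(nrow(tab), 4L)
  expect_true(all(c("eps_th", "alpha", "seed", "outcome", "n_plus1",
                    "n_half", "n_peaks", "error") %in% names(tab)))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$n_plus1[tab$alpha == 0] == 0))
})
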