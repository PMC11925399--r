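# Scenario orchestration: Gaussian contraction pulse trains, single-event
# strain-focusing simulations, full mechanochemical regeneration runs with
# the strain -> morphogen -> fiber-alignment feedback loop, outcome
# classification, and the (eps_th, alpha) phase scan.

#' Gaussian contraction pulse protocol
#'
#' `zeta(t) = zeta_M * sum_k exp(-(t - t_k)^2 / (2 dT^2))` over scheduled
#' pulse centers `t_k`: a single pulse for event runs, `t_k = k * T` for
#' regeneration runs.
#'
#' @param zeta_M pulse amplitude (active stress, model units; >= 0).
#' @param dT pulse width (time; default 3).
#' @param period pulse period `T` for trains (default 30 in the reduced
#'   runs used here; must exceed `dT`).
#' @param centers explicit pulse centers (overrides `period` scheduling).
#' @return a `contraction_protocol`.
#' @export
contraction_protocol <- function(zeta_M, dT = 3, period = 30,
                                 centers = NULL) {
  if (zeta_M < 0) stop("zeta_M must be non-negative")
  if (!is.null(period) && dT >= period)
    stop("pulse width dT must be smaller than the period")
  structure(list(zeta_M = zeta_M, dT = dT, period = period,
                 centers = centers),
            class = "contraction_protocol")
}

#' Active stress amplitude at time t
#'
#' @param t time (vectorized).
#' @param protocol a [contraction_protocol()].
#' @return `zeta(t)`.
#' @export
contraction_amplitude <- function(t, protocol) {
  ctr <- protocol$centers
  if (is.null(ctr)) stop("protocol has no scheduled pulse centers")
  out <- 0
  for (tk in ctr)
    out <- out + exp(-(t - tk)^2 / (2 * protocol$dT^2))
  protocol$zeta_M * out
}

#' Build a relaxed single-event scenario
#'
#' Generates a spheroid, relaxes it mechanically, initializes the
#' requested nematic pattern on the relaxed shell, and locates the strain
#' foci (the +1 defect and the midpoint of the +1/2 pair for
#' `late_defects`; the two cap centers for `fragment`).
#'
#' @param n_cells number of cells (default 200).
#' @param seed mesh + pattern seed.
#' @param pattern `"late_defects"` (default) or `"fragment"`.
#' @param params [mechanics_params()].
#' @param relax_tol force residual required before events (default 1e-4).
#' @param ... passed to [init_nematic()].
#' @return an `event_scenario`: list with the relaxed `state`, `foci`
#'   (cell ids), per-focus `distances`, and `defects`.
#' @export
event_scenario <- function(n_cells = 300, seed = 1L,
                           pattern = c("late_defects", "fragment"),
                           params = mechanics_params(),
                           relax_tol = 1e-4, ...) {
  pattern <- match.arg(pattern)
  shell <- generate_sphere_shell(n_cells, seed = seed)
  st <- shell_state(shell, params)
  st <- relax_state(st, tol = relax_tol, max_steps = 40000L)
  st$time <- 0
  nem <- init_nematic(st$shell, pattern, seed = seed, ...)
  st$nematic <- nem
  st$normals <- shell_geometry(st$shell)$normals
  d <- detect_defects(st$shell, nem)
  if (pattern == "late_defects") {
    plus1 <- d$cell[abs(d$charge - 1) < 1e-9]
    halves <- d[abs(d$charge - 0.5) < 1e-9, , drop = FALSE]
    if (length(plus1) != 1L || nrow(halves) != 2L)
      stop("late_defects scenario did not produce {+1, +1/2, +1/2}")
    midpt <- colMeans(halves[, c("x", "y", "z")])
    ctr <- shell_kernel(st$shell)$centers
    pairmid <- which.min((ctr[, 1] - midpt[1])^2 +
                         (ctr[, 2] - midpt[2])^2 +
                         (ctr[, 3] - midpt[3])^2)
    foci <- c(plus1 = plus1, pair = pairmid)
  } else {
    foci <- attr(nem, "pattern_info")$foci
    names(foci) <- c("cap_head", "cap_foot")
  }
  dists <- lapply(foci, function(f) graph_distances(st$shell, f))
  structure(list(state = st, pattern = pattern, foci = foci,
                 distances = dists, defects = d, seed = seed),
            class = "event_scenario")
}

#' Simulate a single global contraction event
#'
#' Nematic and morphogen dynamics are frozen (the fiber pattern evolves on
#' hours while events last minutes); the mechanics is stepped through one
#' Gaussian pulse while per-cell areas are recorded, and strain-vs-distance
#' profiles are computed around each focus at the event peak.  T1s are not
#' expected during calibrated events and raise a warning if they occur.
#'
#' @param scenario an [event_scenario()] (relaxed; a residual above
#'   10x `relax_tol` is an error).
#' @param protocol a [contraction_protocol()] (single pulse; its center
#'   defaults to `3 * dT` after the current time).
#' @param record_dt area-recording cadence (default 0.5 time units).
#' @param t_end simulation horizon after the pulse center (default
#'   `3 * dT`).
#' @param keep_frames if `TRUE`, store the vertex positions of every
#'   recorded frame (for shape-tensor analysis at the peak).
#' @return an `event_record`: per-focus `profiles` (strain_profile),
#'   `peak_frame`, `core_strain`, `classification`; plus the `area_series`
#'   matrix, recording `times`, and `n_t1`.
#' @export
run_single_event <- function(scenario, protocol, record_dt = 0.5,
                             t_end = NULL, keep_frames = FALSE) {
  st <- scenario$state
  kr <- shell_kernel(st$shell, st$params, forces = TRUE)
  res <- max(abs(volume_constrained_forces(st$shell, kr$forces,
                                           kr$volgrad)$forces))
  if (res > 1e-2)
    stop(sprintf("scenario not relaxed (residual %.3g)", res))
  dT <- protocol$dT
  t0 <- st$time
  tc <- t0 + 3 * dT
  if (is.null(t_end)) t_end <- tc + 3 * dT
  prot <- protocol
  prot$centers <- tc
  zf <- function(t) contraction_amplitude(t, prot)
  areas0 <- shell_geometry(st$shell)$areas
  n_t1_0 <- st$n_t1
  times <- t0
  series <- list(areas0)
  frames <- if (keep_frames) list(scenario$state$shell$positions)
  dt <- st$params$dt
  steps_per_rec <- max(1L, round(record_dt / dt))
  nrec <- ceiling((t_end - t0) / (steps_per_rec * dt))
  for (r in seq_len(nrec)) {
    st <- step_dynamics(st, steps_per_rec, zeta = zf)
    series[[r + 1L]] <- shell_geometry(st$shell)$areas
    if (keep_frames) frames[[r + 1L]] <- st$shell$positions
    times <- c(times, st$time)
  }
  if (st$n_t1 > n_t1_0)
    warning(sprintf("%d T1 transition(s) during a single event",
                    st$n_t1 - n_t1_0))
  area_series <- do.call(rbind, series)
  per_focus <- lapply(names(scenario$foci), function(nm) {
    dmap <- scenario$distances[[nm]]
    pk <- find_peak_frame(area_series, dmap)
    prof <- log_area_strain_profile(area_series[1, ], area_series[pk, ],
                                    dmap)
    list(focus = scenario$foci[[nm]], peak_frame = pk,
         profile = prof, core_strain = attr(prof, "core"),
         classification = classify_event(prof))
  })
  names(per_focus) <- names(scenario$foci)
  structure(list(foci = per_focus, area_series = area_series,
                 times = times, zeta_M = protocol$zeta_M,
                 n_t1 = st$n_t1 - n_t1_0, final_state = st,
                 frames = if (keep_frames) frames),
            class = "event_record")
}

#' Calibrate the pulse amplitude to a target core strain
#'
#' Bisection on `zeta_M` until the mean core (graph distance <= 1 from the
#' +1 focus) logarithmic area strain at the event peak is within `tol` of
#' `target` (default `log(2)`, the observed average core strain).
#' Monotonicity of the achieved strain in `zeta_M` over the bracket is the
#' bisection's validity condition; numerical blow-up marks the instability
#' onset and caps the bracket.
#'
#' @param scenario an [event_scenario()] (late_defects).
#' @param target target core log strain (default `log(2)`).
#' @param tol calibration tolerance (default 0.05).
#' @param dT pulse width (default 3).
#' @param z_init initial upper bracket guess (default 0.8).
#' @param max_iter bisection budget.
#' @return list with `zeta_M`, `achieved`, `profile`, and the evaluation
#'   `history`.
#' @export
calibrate_zeta <- function(scenario, target = log(2), tol = 0.05,
                           dT = 3, z_init = 0.8, max_iter = 12L) {
  if (target == 0)
    return(list(zeta_M = 0, achieved = 0, profile = NULL,
                history = data.frame(zeta_M = 0, strain = 0)))
  focus1 <- names(scenario$foci)[1]
  hist <- data.frame(zeta_M = numeric(0), strain = numeric(0))
  ev <- function(z) {
    rec <- tryCatch(
      run_single_event(scenario, contraction_protocol(z, dT = dT)),
      error = function(e) NULL)
    s <- if (is.null(rec)) NA_real_ else rec$foci[[focus1]]$core_strain
    hist[nrow(hist) + 1L, ] <<- c(z, s)
    list(strain = s, rec = rec)
  }
  lo <- 0; s_lo <- 0; rec_lo <- NULL
  hi <- z_init
  repeat {
    r <- ev(hi)
    if (is.na(r$strain)) { hi_unstable <- hi; hi <- (lo + hi) / 2 }
    else if (r$strain < target) {
      lo <- hi; s_lo <- r$strain; rec_lo <- r$rec
      hi <- hi * 1.6
      if (hi > 50) stop("target unreachable: bracket exceeded zeta_M = 50")
    } else { s_hi <- r$strain; rec_hi <- r$rec; break }
    if (hi - lo < 1e-3)
      stop(sprintf(paste0("target core strain %.3f unreachable before ",
                          "instability onset (best %.3f at zeta_M %.3f)"),
                   target, s_lo, lo))
  }
  best <- rec_hi; bz <- hi; bs <- s_hi
  for (it in seq_len(max_iter)) {
    if (abs(bs - target) <= tol) break
    mid <- (lo + hi) / 2
    r <- ev(mid)
    if (is.na(r$strain)) { hi <- mid; next }
    if (abs(r$strain - target) < abs(bs - target)) {
      best <- r$rec; bz <- mid; bs <- r$strain
    }
    if (r$strain < target) lo <- mid else hi <- mid
  }
  if (abs(bs - target) > tol)
    warning(sprintf("calibration stopped at strain %.3f (target %.3f)",
                    bs, target))
  list(zeta_M = bz, achieved = bs,
       profile = best$foci[[focus1]]$profile, history = hist)
}

#' Run a full mechanochemical regeneration simulation
#'
#' Starts from a relaxed spheroid with a `fragment` nematic pattern (a
#' large disordered region of net charge +2) and zero morphogen, and
#' interleaves: vertex-model mechanics under a Gaussian contraction pulse
#' train, morphogen reaction-diffusion with strain-gated production
#' (strain measured against the t = 0 areas), and nematic alignment with
#' morphogen-gradient coupling.  The final state is classified with
#' [classify_outcome()].
#'
#' @param n_cells,seed mesh / disorder seed.
#' @param n_pulses number of contraction cycles (default 20).
#' @param protocol a [contraction_protocol()]; its `period` sets the
#'   cycle length.
#' @param params [mechanics_params()].
#' @param tau_q,alpha nematic alignment timescale and gradient coupling.
#' @param D,r_plus,r_minus,eps_th,w morphogen parameters (see
#'   [morphogen_field()]).
#' @param slow_every nematic/morphogen update cadence in mechanics steps
#'   (default 5; both fields are much slower than the mechanics).
#' @param record_every record a summary row every k-th pulse (default 1).
#' @return a `regeneration_record`: `outcome` (see [classify_outcome()]),
#'   final `state`, per-pulse `summary` data.frame, `n_t1`.
#' @export
run_regeneration <- function(n_cells = 200, seed = 1L, n_pulses = 20L,
                             protocol = NULL,
                             params = mechanics_params(),
                             tau_q = 2, alpha = 5,
                             D = 0.2, r_plus = 1, r_minus = 0.1,
                             eps_th = 0.45, w = 10,
                             slow_every = 5L, record_every = 1L) {
  if (is.null(protocol)) protocol <- contraction_protocol(1.05)
  scn <- event_scenario(n_cells, seed = seed, pattern = "fragment",
                        params = params, tau_q = tau_q, alpha = alpha)
  st <- scn$state
  st$morphogen <- morphogen_field(st$shell, N = 0, D = D, r_plus = r_plus,
                                  r_minus = r_minus, eps_th = eps_th,
                                  w = w)
  period <- protocol$period
  dt <- params$dt
  steps_slow <- slow_every
  rows <- list()
  for (pulse in seq_len(n_pulses)) {
    prot <- protocol
    prot$centers <- st$time + period / 2
    zf <- function(t) contraction_amplitude(t, prot)
    t_target <- st$time + period
    while (st$time < t_target - 1e-9) {
      nst <- min(steps_slow, ceiling((t_target - st$time) / dt))
      st <- step_dynamics(st, nst, zeta = zf)
      st <- step_slow_fields(st, nst * dt)
    }
    if (pulse %% record_every == 0L) {
      g <- shell_geometry(st$shell)
      d <- detect_defects(st$shell, st$nematic)
      phi <- st$morphogen$N / g$areas
      rows[[length(rows) + 1L]] <- data.frame(
        pulse = pulse, time = st$time,
        n_plus1 = sum(abs(d$charge - 1) < 1e-9),
        n_half = sum(abs(d$charge - 0.5) < 1e-9),
        n_defects = nrow(d), total_N = sum(st$morphogen$N),
        max_phi = max(phi), n_t1 = st$n_t1)
    }
  }
  outcome <- classify_outcome(st$shell, st$nematic, st$morphogen)
  structure(list(outcome = outcome, state = st,
                 summary = do.call(rbind, rows), n_t1 = st$n_t1,
                 seed = seed),
            class = "regeneration_record")
}

# advance nematic + morphogen by dt_slow on the current (frozen) geometry,
# sub-stepping to respect the diffusion stability bound
step_slow_fields <- function(st, dt_slow) {
  g <- shell_geometry(st$shell)
  mor <- st$morphogen
  nem <- st$nematic
  if (!is.null(mor)) {
    bound <- morphogen_dt_bound(mor, g)
    nsub <- max(1L, ceiling(dt_slow / (0.9 * bound)))
    for (s in seq_len(nsub))
      mor <- step_morphogen(st$shell, mor, dt_slow / nsub, geometry = g)
    st$morphogen <- mor
  }
  if (!is.null(nem)) {
    grads <- NULL
    phi <- NULL
    if (nem$alpha > 0 && !is.null(mor)) {
      phi <- mor$N / g$areas
      grads <- gradient_estimate_all(st$shell, phi, nem, g)
    }
    st$nematic <- step_nematic(st$shell, nem, phi = phi, dt = dt_slow,
                               gradients = grads)
  }
  st
}

#' Classify the final defect / morphogen configuration
#'
#' Morphogen peaks are cells that are local maxima of the 1-ring-smoothed
#' concentration with smoothed value at least twice the global mean.  An
#' organizer is a +1 defect (a detected charge-1 cluster, or two +1/2
#' defects within 2 cells of each other) with a peak within graph
#' distance 2.  Categories: `single_organizer` (one organizer),
#' `two_organizers`, `four_half` (exactly four +1/2 defects, no
#' organizer), `other`.
#'
#' @param shell a `cellular_shell`.
#' @param nematic a [nematic_field()].
#' @param morphogen a [morphogen_field()] (or NULL for no morphogen).
#' @return an `outcome_label`: list with `category`, `defects`, `peaks`
#'   (cell ids), `organizers` (cell ids of organizer defects).
#' @export
classify_outcome <- function(shell, nematic, morphogen = NULL) {
  g <- shell_geometry(shell)
  d <- detect_defects(shell, nematic)
  peaks <- integer(0)
  if (!is.null(morphogen) && any(morphogen$N > 0)) {
    phi <- morphogen$N / g$areas
    sm <- vapply(seq_along(phi), function(c)
      mean(phi[c(c, shell$cell_neighbors[[c]])]), 1.0)
    is_peak <- vapply(seq_along(sm), function(c)
      sm[c] >= max(sm[shell$cell_neighbors[[c]]]), TRUE)
    peaks <- which(is_peak & sm >= 2 * mean(sm))
  }
  plus1_cells <- d$cell[abs(d$charge - 1) < 1e-9]
  half_cells <- d$cell[abs(d$charge - 0.5) < 1e-9]
  # composite asters: +1/2 pairs within 2 cells of each other
  composite <- integer(0)
  if (length(half_cells) >= 2) {
    used <- rep(FALSE, length(half_cells))
    for (i in seq_along(half_cells)) {
      if (used[i]) next
      gd <- graph_distances(shell, half_cells[i])
      j <- which(!used & seq_along(half_cells) != i &
                 gd[half_cells] <= 2)
      if (length(j)) {
        j <- j[1]
        used[c(i, j)] <- TRUE
        composite <- c(composite, half_cells[i])
      }
    }
  }
  asters <- c(plus1_cells, composite)
  organizers <- integer(0)
  if (length(asters) && length(peaks)) {
    gdp <- graph_distances(shell, peaks)
    organizers <- asters[gdp[asters] <= 2]
  }
  n_half_free <- length(half_cells) - 2 * length(composite)
  category <-
    if (length(organizers) == 1L) "single_organizer"
    else if (length(organizers) >= 2L) "two_organizers"
    else if (length(half_cells) == 4L && length(plus1_cells) == 0L &&
             length(composite) == 0L) "four_half"
    else "other"
  structure(list(category = category, defects = d, peaks = peaks,
                 organizers = organizers, n_plus1 = length(plus1_cells),
                 n_half = length(half_cells),
                 n_half_free = n_half_free),
            class = "outcome_label")
}

#' Scan the (eps_th, alpha) feedback parameter plane
#'
#' Runs [run_regeneration()] for every grid point and seed; failures are
#' recorded and the scan continues.
#'
#' @param eps_th_values,alpha_values grid axes (non-empty).
#' @param seeds integer vector of seeds per grid point.
#' @param ... passed to [run_regeneration()] (e.g. `n_cells`, `n_pulses`,
#'   `protocol`).
#' @return tidy data.frame: `eps_th, alpha, seed, outcome, n_plus1,
#'   n_half, n_peaks, error`.
#' @export
phase_scan <- function(eps_th_values, alpha_values, seeds = 1:3, ...) {
  if (!length(eps_th_values) || !length(alpha_values))
    stop("empty grid")
  grid <- expand.grid(eps_th = eps_th_values, alpha = alpha_values,
                      seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gi <- grid[i, ]
    rec <- tryCatch(
      run_regeneration(seed = gi$seed, alpha = gi$alpha,
                       eps_th = gi$eps_th, ...),
      error = function(e) e)
    if (inherits(rec, "error"))
      data.frame(gi, outcome = NA_character_, n_plus1 = NA_integer_,
                 n_half = NA_integer_, n_peaks = NA_integer_,
                 error = conditionMessage(rec))
    else
      data.frame(gi, outcome = rec$outcome$category,
                 n_plus1 = rec$outcome$n_plus1,
                 n_half = rec$outcome$n_half,
                 n_peaks = length(rec$outcome$peaks),
                 error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
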