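# Vertex-model energetics and overdamped dynamics on the closed shell.
#
# E = sum_c K/2 (A_c - A0)^2          cell area elasticity
#   + sum_b Lambda L_b                bond tension (adhesion; Lambda < 0)
#   + sum_c Gamma/2 P_c^2             perimeter elasticity
#   + sum_b beta/2 theta_b^2          cell-cell bending
#
# The lumen volume enters the dynamics (not E) through a Lagrange
# multiplier mu: gamma dR/dt = F_el + F_act - mu dV/dR.

#' Mechanical parameter set
#'
#' Model units: lengths in units of sqrt(A0), energies in units of K*A0^2,
#' time in units of gamma/(K*A0).  The reference `(Lambda, Gamma)` pair is
#' chosen so the relaxed network has a negative 2D Poisson ratio (see
#' [measure_poisson_ratio()]; the defaults give about -0.12): the
#' perimeter term pre-compresses cells below their preferred area, so a
#' uniaxial stretch lets cells regain area by expanding in both
#' directions.  Together with the adhesion-signed bond tension (Lambda <
#' 0 penalizes short bonds) and a stiff bending modulus (suppressing
#' contraction-induced wrinkling), this lets the shell sustain large
#' isotropic strains at defect cores without cell rearrangements.
#'
#' @param K area elastic modulus (energy / length^4).
#' @param A0 preferred cell area (length^2).
#' @param Lambda bond tension (energy / length); negative values model
#'   cell-cell adhesion.
#' @param Gamma perimeter elastic modulus (energy / length^2).
#' @param beta cell-cell bending modulus (energy).
#' @param gamma friction coefficient (energy * time / length^2).
#' @param dt explicit-Euler time step; default is the empirical stability
#'   bound `0.1 * gamma / (K * A0 + Gamma + beta / A0)` rounded down.
#' @param L_th bond-collapse threshold length for T1 transitions.
#' @return a `mechanics_params` list.
#' @export
mechanics_params <- function(K = 1, A0 = 1, Lambda = -0.1, Gamma = 0.25,
                             beta = 2, gamma = 1, dt = NULL,
                             L_th = 0.05) {
  if (any(c(K, A0, Gamma, beta, gamma, L_th) <= 0))
    stop("K, A0, Gamma, beta, gamma and L_th must be positive")
  if (L_th >= sqrt(A0))
    stop("L_th must be small compared to the cell size sqrt(A0)")
  bound <- 0.1 * gamma / (K * A0 + Gamma + beta / A0)
  if (is.null(dt)) dt <- signif(0.9 * bound, 2)
  if (dt > bound * 1.0001)
    stop(sprintf("dt = %g exceeds the stability bound %g", dt, bound))
  structure(list(K = K, A0 = A0, Lambda = Lambda, Gamma = Gamma,
                 beta = beta, gamma = gamma, dt = dt, L_th = L_th,
                 dt_bound = bound),
            class = "mechanics_params")
}

#' Vertex-model elastic energy
#'
#' @param shell a `cellular_shell` or open `cell_patch`.
#' @param params a [mechanics_params()] set.
#' @return scalar energy (the volume constraint enters the dynamics, not E).
#' @export
elastic_energy <- function(shell, params) {
  k <- shell_kernel(shell, params)
  if (any(k$areas <= 1e-12)) {
    bad <- which(k$areas <= 1e-12)[1]
    stop(sprintf("degenerate cell %d: non-positive area", bad))
  }
  k$E_elastic
}

#' Elastic forces (exact negative energy gradient)
#'
#' @inheritParams elastic_energy
#' @return n_vertices x 3 matrix of forces.
#' @export
elastic_forces <- function(shell, params) {
  shell_kernel(shell, params, forces = TRUE)$forces
}

#' Active forces from nematic contractile stress
#'
#' Each cell carries a traceless active stress `zeta * q_c` along its fiber
#' axis.  The discretization is a virtual-work construction: the active
#' energy is `zeta/2 * sum_c sum_{v in c} r_v . Q_c r_v` with `r_v` the
#' vertex offsets from the cell center and `Q_c` the cell's (3D-embedded)
#' unit nematic tensor; forces are its exact gradient at fixed nematic.
#' With `zeta > 0` a cell contracts along its fiber axis and extends
#' perpendicular to it; the stress is traceless so cell area is preserved
#' to first order in `zeta`.
#'
#' @param shell a `cellular_shell`.
#' @param nematic a [nematic_field()] (unit magnitude enforced).
#' @param zeta active stress amplitude.
#' @return n_vertices x 3 matrix of forces.
#' @export
active_forces <- function(shell, nematic, zeta) {
  if (zeta == 0) return(matrix(0, nrow(shell$positions), 3))
  stopifnot(inherits(nematic, "nematic_field"))
  q3 <- nematic_q3(nematic)
  shell_kernel(shell, params = NULL, q3 = q3, zeta = zeta,
               forces = TRUE)$forces
}

#' Project forces onto the lumen-volume-conserving subspace
#'
#' Computes the Lagrange multiplier `mu = (F . G) / (G . G)` with
#' `G = dV/dR`, and the projected forces `F - mu G`, which satisfy
#' `sum_i F'_i . G_i = 0` (instantaneous dV/dt = 0).
#'
#' @param shell a `cellular_shell`.
#' @param raw_forces n_vertices x 3 matrix.
#' @param volgrad optional precomputed volume gradient.
#' @return list with `forces` (projected) and `mu`.
#' @export
volume_constrained_forces <- function(shell, raw_forces, volgrad = NULL) {
  if (is.null(volgrad))
    volgrad <- shell_kernel(shell, forces = TRUE)$volgrad
  gg <- sum(volgrad * volgrad)
  if (gg < 1e-20) stop("degenerate volume gradient")
  mu <- sum(raw_forces * volgrad) / gg
  list(forces = raw_forces - mu * volgrad, mu = mu)
}

#' Create a dynamical state for a shell
#'
#' Bundles the shell with mechanics parameters, the conserved lumen volume
#' `V0`, per-cell tangent frames (transported continuously through time
#' steps), and optional nematic / morphogen fields.
#'
#' @param shell a `cellular_shell`.
#' @param params [mechanics_params()].
#' @param nematic optional [nematic_field()].
#' @param morphogen optional [morphogen_field()].
#' @return a `shell_state` list.
#' @export
shell_state <- function(shell, params = mechanics_params(),
                        nematic = NULL, morphogen = NULL) {
  g <- shell_geometry(shell)
  structure(list(shell = shell, params = params, nematic = nematic,
                 morphogen = morphogen, V0 = g$volume, time = 0,
                 mu = 0, zeta = 0, normals = g$normals,
                 n_t1 = 0L, n_clamp = 0L),
            class = "shell_state")
}

#' @export
print.shell_state <- function(x, ...) {
  cat(sprintf(
    "<shell_state> t = %.3f, %d cells, V0 = %.4g, mu = %.3g, T1s = %d\n",
    x$time, length(x$shell$cells), x$V0, x$mu, x$n_t1))
  invisible(x)
}

#' Advance the overdamped vertex dynamics
#'
#' Explicit Euler steps `gamma dR = dt (F_el + F_act - mu G)` with the
#' exact volume constraint (force projection each step plus a position
#' rescaling about the centroid that removes the residual O(dt^2) volume
#' drift).  Tangent frames are transported by the minimal rotation between
#' successive cell normals, and the nematic field is convected/co-rotated
#' with them.  Bonds shorter than `L_th` trigger T1 handling (see
#' [handle_topology()]) unless `t1 = FALSE`.
#'
#' @param state a [shell_state()].
#' @param n_steps number of Euler steps.
#' @param zeta active amplitude: scalar or `function(t)`.
#' @param dt time step (default `params$dt`).
#' @param t1 allow topology changes (default TRUE).
#' @return updated state.
#' @export
step_dynamics <- function(state, n_steps = 1L, zeta = 0, dt = NULL,
                          t1 = TRUE) {
  p <- state$params
  if (is.null(dt)) dt <- p$dt
  if (dt > p$dt_bound * 1.0001)
    stop(sprintf("dt = %g exceeds the stability bound %g", dt, p$dt_bound))
  zfun <- if (is.function(zeta)) zeta else function(t) zeta
  shell <- state$shell
  nem <- state$nematic
  for (k in seq_len(n_steps)) {
    z <- zfun(state$time)
    # active stress stiffens the dynamics; sub-step under strong pulses
    zbound <- 0.1 * p$gamma / (p$K * p$A0 + p$Gamma + p$beta / p$A0 + abs(z))
    nsub <- max(1L, ceiling(dt / zbound))
    dts <- dt / nsub
    q3 <- if (!is.null(nem) && z != 0) nematic_q3(nem) else NULL
    for (ss in seq_len(nsub)) {
      kr <- shell_kernel(shell, p, q3 = q3, zeta = z, forces = TRUE)
      if (!is.finite(kr$volume) || !all(is.finite(kr$forces)))
        stop(sprintf("non-finite state at t = %g (step blow-up)",
                     state$time))
      gg <- sum(kr$volgrad^2)
      mu <- sum(kr$forces * kr$volgrad) / gg
      shell$positions <- shell$positions +
        (dts / p$gamma) * (kr$forces - mu * kr$volgrad)
      # exact volume restoration of the residual O(dt^2) drift
      V <- vm_volume_cpp(shell$positions, shell$cell_vert,
                         shell$cell_ptr)
      if (!is.finite(V) || V <= 0)
        stop(sprintf("non-finite state at t = %g (step blow-up)",
                     state$time))
      s <- (state$V0 / V)^(1 / 3)
      if (abs(s - 1) > 1e-15) {
        ctr <- colMeans(shell$positions)
        shell$positions <- sweep(s * sweep(shell$positions, 2, ctr), 2,
                                 ctr, "+")
      }
    }
    state$mu <- mu
    state$zeta <- z
    state$time <- state$time + dt
    # transport frames (and with them the nematic) to the new normals
    if (!is.null(nem)) {
      g2 <- shell_kernel(shell)
      nem <- transport_field_frames(nem, state$normals, g2$normals)
      state$normals <- g2$normals
      if (t1 && g2$min_bond < p$L_th) {
        state$shell <- shell
        state$nematic <- nem
        state <- handle_topology(state)
        shell <- state$shell
        nem <- state$nematic
      }
    } else if (t1 && kr$min_bond < p$L_th) {
      state$shell <- shell
      state <- handle_topology(state)
      shell <- state$shell
      state$normals <- shell_kernel(shell)$normals
    }
  }
  state$shell <- shell
  state$nematic <- nem
  if (is.null(nem)) state$normals <- shell_kernel(shell)$normals
  state
}

#' Relax a state to mechanical equilibrium
#'
#' Pure gradient descent (`zeta = 0`) until the maximum projected vertex
#' force falls below `tol`.
#'
#' @param state a [shell_state()].
#' @param tol force residual tolerance (default 1e-4).
#' @param max_steps step budget.
#' @param t1 allow topology changes during relaxation.
#' @return updated state (attribute `residual` holds the final residual).
#' @export
relax_state <- function(state, tol = 1e-4, max_steps = 20000L, t1 = TRUE) {
  p <- state$params
  done <- FALSE
  chunk <- 50L
  steps <- 0L
  res <- Inf
  while (steps < max_steps) {
    state <- step_dynamics(state, chunk, zeta = 0, t1 = t1)
    steps <- steps + chunk
    kr <- shell_kernel(state$shell, p, forces = TRUE)
    pf <- volume_constrained_forces(state$shell, kr$forces, kr$volgrad)
    res <- max(abs(pf$forces))
    if (res < tol) { done <- TRUE; break }
  }
  if (!done)
    warning(sprintf("relaxation stopped at residual %.3g after %d steps",
                    res, steps))
  attr(state, "residual") <- res
  state
}

#' Two-dimensional Poisson ratio of the cell network
#'
#' Measured on a flat periodic hexagonal lattice represented by its
#' single-cell unit: a hexagon with two vertical edges, parametrized by
#' half-width `s`, slant height `h` and total height `H` (area `2 s H`,
#' perimeter `4 sqrt(s^2 + h^2) + 2 (H - h)`).  The rest state is found by
#' minimizing the per-cell energy (`K/2 (A - A0)^2 + Gamma/2 P^2 +
#' Lambda P / 2`, bond tension shared between neighbor cells); a small
#' uniaxial strain `eps_xx` is then imposed on `s` and the remaining
#' degrees of freedom relax (no T1s, flat so bending is inactive).
#'
#' @param params [mechanics_params()].
#' @param eps_xx imposed strain (default 1e-2; must be nonzero).
#' @return `nu = -eps_yy / eps_xx` (negative for the default parameters).
#' @export
measure_poisson_ratio <- function(params, eps_xx = 1e-2) {
  if (eps_xx == 0) stop("eps_xx must be nonzero")
  p <- params
  energy <- function(s, h, H) {
    if (H <= h || h <= 0 || s <= 0) return(1e10)
    A <- 2 * s * H
    P <- 4 * sqrt(s^2 + h^2) + 2 * (H - h)
    0.5 * p$K * (A - p$A0)^2 + 0.5 * p$Gamma * P^2 + 0.5 * p$Lambda * P
  }
  minimize <- function(fn, x0) {
    best <- NULL
    for (scl in c(1, 0.8, 1.25)) {
      r <- stats::nlminb(x0 * scl, fn,
                         control = list(rel.tol = 1e-15, iter.max = 2000))
      r2 <- stats::optim(r$par, fn, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 10000))
      if (is.null(best) || r2$value < best$value) best <- r2
    }
    best
  }
  a <- sqrt(2 * p$A0 / (3 * sqrt(3)))  # regular-hexagon edge at area A0
  x0 <- c(s = sqrt(3) * a / 2, h = a / 2, H = 1.5 * a)
  rest <- minimize(function(x) energy(x[1], x[2], x[3]), x0)
  s0 <- rest$par[1]
  rest2 <- minimize(function(x) energy(s0, x[1], x[2]), rest$par[2:3])
  H0 <- rest2$par[2]
  if (!is.finite(H0) || H0 <= 0) stop("rest-state relaxation failed")
  s1 <- s0 * (1 + eps_xx)
  def <- minimize(function(x) energy(s1, x[1], x[2]), rest2$par)
  if (!is.finite(def$value)) stop("strained-state relaxation failed")
  eps_yy <- def$par[2] / H0 - 1
  -eps_yy / eps_xx
}

#' Open flat patch of cells (test fixture constructor)
#'
#' Builds the connectivity arrays used by the energy/force kernels for a
#' non-closed patch (boundary bonds border a single cell and carry no
#' bending).  Patches support energies and forces but not volume
#' constraints or dynamics.
#'
#' @param positions n x 3 matrix.
#' @param cells list of vertex cycles.
#' @return a `cell_patch` (duck-typed subset of `cellular_shell`).
#' @export
cell_patch <- function(positions, cells) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  cells <- lapply(cells, as.integer)
  nc <- length(cells)
  nv <- nrow(positions)
  m <- vapply(cells, length, 1L)
  from <- unlist(cells, use.names = FALSE)
  to <- unlist(lapply(cells, function(v) c(v[-1], v[1])), use.names = FALSE)
  ecell <- rep.int(seq_len(nc), m)
  key <- pmin(from, to) * (nv + 1) + pmax(from, to)
  ord <- order(key)
  ks <- key[ord]
  grp <- cumsum(!duplicated(ks))
  first <- ord[!duplicated(ks)]
  nb <- max(grp)
  c2 <- rep(NA_integer_, nb)
  dup <- ord[duplicated(ks)]
  c2[grp[match(dup, ord)]] <- ecell[dup]
  bonds <- cbind(v1 = from[first], v2 = to[first], c1 = ecell[first],
                 c2 = ifelse(is.na(c2), ecell[first], c2))
  interior <- bonds[, "c1"] != bonds[, "c2"]
  nbr <- lapply(seq_len(nc), function(ci) {
    b <- bonds[interior, , drop = FALSE]
    unique(c(b[b[, "c1"] == ci, "c2"], b[b[, "c2"] == ci, "c1"]))
  })
  structure(list(positions = positions, cells = cells,
                 cell_ptr = c(0L, cumsum(m)),
                 cell_vert = from - 1L, bonds = bonds,
                 cell_neighbors = nbr),
            class = c("cell_patch", "cellular_shell"))
}
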