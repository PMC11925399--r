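# Morphogen molecule counts per cell: inter-cell diffusion along bonds,
# constant degradation, strain-gated sigmoid production, and tangent-plane
# least-squares gradient estimation.

#' Create a morphogen field
#'
#' Molecule numbers `N_c` per cell; concentrations are `phi_c = N_c / A_c`.
#' With `r_plus = 1` (the default, fixed without loss of generality) `N_c`
#' is expressed in units of `r_plus / r_minus`.  The derived scales are the
#' degradation time `1 / r_minus` and the screening length
#' `ell = sqrt(D / r_minus)`, the distance a molecule diffuses before
#' degrading.
#'
#' @param shell a `cellular_shell`.
#' @param N initial molecule numbers (recycled; default 0).
#' @param D effective inter-cell diffusion coefficient (length^2 / time).
#' @param r_plus maximal production rate (molecules / time).
#' @param r_minus degradation rate (1 / time).
#' @param eps_th strain threshold of the production sigmoid (> 0).
#' @param w sigmoid sharpness (default 10).
#' @param A_ref reference (t = 0) cell areas for the strain; defaults to
#'   the current areas.
#' @param sigmoid_convention `"shifted"` (default) uses
#'   `f = (1 + tanh(w (eps - eps_th) / eps_th)) / 2`, which is non-negative
#'   and saturates at `r_plus`; `"raw"` keeps the bare
#'   `f = tanh(...) / 2` for sensitivity checks.
#' @return a `morphogen_field`.
#' @export
morphogen_field <- function(shell, N = 0, D = 0.15, r_plus = 1,
                            r_minus = 0.1, eps_th = 0.3, w = 10,
                            A_ref = NULL, sigmoid_convention = "shifted") {
  nc <- length(shell$cells)
  if (eps_th <= 0) stop("eps_th must be positive")
  if (r_minus <= 0 || D < 0) stop("need r_minus > 0 and D >= 0")
  sigmoid_convention <- match.arg(sigmoid_convention, c("shifted", "raw"))
  if (is.null(A_ref)) A_ref <- shell_geometry(shell)$areas
  if (any(A_ref <= 0)) stop("non-positive reference area")
  structure(list(N = pmax(0, rep_len(as.numeric(N), nc)), D = D,
                 r_plus = r_plus, r_minus = r_minus, eps_th = eps_th,
                 w = w, A_ref = rep_len(A_ref, nc),
                 sigmoid_convention = sigmoid_convention),
            class = "morphogen_field")
}

#' Cell area strain
#'
#' `eps_c = (A_c - A_ref) / A_ref` relative to the reference (initial)
#' area.
#'
#' @param A current cell area(s).
#' @param A_ref reference area(s), positive.
#' @return strain(s).
#' @export
cell_strain <- function(A, A_ref) {
  if (any(A_ref <= 0)) stop("non-positive reference area")
  (A - A_ref) / A_ref
}

#' Strain-gated morphogen production rate
#'
#' Sigmoid gate `r_plus * f(eps)` with
#' `f = (1 + tanh(w (eps - eps_th) / eps_th)) / 2` (shifted convention):
#' half-maximal at the threshold, vanishing far below it and saturating to
#' `r_plus` far above it.
#'
#' @param eps cell area strain(s).
#' @param field a [morphogen_field()] (or any list with `r_plus`, `eps_th`,
#'   `w`, `sigmoid_convention`).
#' @return production rate(s).
#' @export
production_rate <- function(eps, field) {
  if (field$eps_th <= 0) stop("eps_th must be positive")
  th <- tanh(field$w * (eps - field$eps_th) / field$eps_th)
  if (identical(field$sigmoid_convention, "raw")) field$r_plus * th / 2
  else field$r_plus * (1 + th) / 2
}

#' Diffusive part of the morphogen dynamics
#'
#' `dN_c/dt = sum_{c'} D L_{cc'} (phi_c' - phi_c)` over the bonds of each
#' cell, with `L` the shared bond length.  Antisymmetric per bond, hence
#' exactly conservative.
#'
#' @param shell a `cellular_shell`.
#' @param field a [morphogen_field()].
#' @param geometry optional precomputed [shell_geometry()] result.
#' @return per-cell `dN/dt` vector.
#' @export
diffusion_rhs <- function(shell, field, geometry = NULL) {
  if (is.null(geometry)) geometry <- shell_geometry(shell)
  phi <- field$N / geometry$areas
  b <- shell$bonds
  flux <- field$D * geometry$bond_lengths *
    (phi[b[, "c2"]] - phi[b[, "c1"]])  # flow into c1
  nc <- length(shell$cells)
  out <- numeric(nc)
  acc <- rowsum(c(flux, -flux), c(b[, "c1"], b[, "c2"]))
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Least-squares in-plane morphogen gradient for one cell
#'
#' Finds the tangent-plane vector `g` minimizing the squared error of
#' `phi_c' - phi_c = g . (R_c' - R_c)` over all neighbors, with center
#' offsets projected into the cell's tangent plane.  Exact for fields
#' linear in the tangent coordinates.  Collinear neighborhoods fall back
#' to the minimum-norm solution (flagged via attribute `degenerate`).
#'
#' @param shell a `cellular_shell`.
#' @param phi per-cell concentration vector.
#' @param cell cell index.
#' @return length-2 gradient in the cell's tangent frame.
#' @export
gradient_estimate <- function(shell, phi, cell) {
  nb <- shell$cell_neighbors[[cell]]
  if (length(nb) < 2L) stop("need at least 2 neighbors")
  geom <- build_cell_geometry(shell, cell)
  ctr <- shell_kernel(shell)$centers
  dx <- sweep(ctr[nb, , drop = FALSE], 2, ctr[cell, ])
  X <- cbind(rowSums(sweep(dx, 2, geom$e1, "*")),
             rowSums(sweep(dx, 2, geom$e2, "*")))
  y <- phi[nb] - phi[cell]
  xtx <- crossprod(X)
  det <- xtx[1, 1] * xtx[2, 2] - xtx[1, 2]^2
  if (det < 1e-12 * (xtx[1, 1] + xtx[2, 2])^2) {
    g <- c(MASS_ginv2(xtx) %*% crossprod(X, y))
    attr(g, "degenerate") <- TRUE
    return(g)
  }
  c(solve(xtx, crossprod(X, y)))
}

# tiny 2x2 pseudo-inverse (avoids a MASS dependency)
MASS_ginv2 <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > 1e-12 * max(e$values, 0)
  inv <- ifelse(pos, 1 / pmax(e$values, 1e-300), 0)
  e$vectors %*% (inv * t(e$vectors))
}

# vectorized gradients for all cells (frames taken from `field`, a
# nematic_field supplying e1/normals, or recomputed when NULL)
gradient_estimate_all <- function(shell, phi, field = NULL,
                                  geometry = NULL) {
  if (is.null(geometry)) geometry <- shell_geometry(shell)
  if (is.null(field)) {
    fr <- shell_frames(geometry$normals)
    e1 <- fr$e1
    normals <- geometry$normals
  } else {
    e1 <- field$e1
    normals <- field$normals
  }
  e2 <- frame_e2(e1, normals)
  nc <- length(shell$cells)
  nbj <- unlist(shell$cell_neighbors, use.names = FALSE)
  deg <- lengths(shell$cell_neighbors)
  nbi <- rep.int(seq_len(nc), deg)
  dx <- geometry$centers[nbj, , drop = FALSE] -
    geometry$centers[nbi, , drop = FALSE]
  x1 <- rowSums(dx * e1[nbi, , drop = FALSE])
  x2 <- rowSums(dx * e2[nbi, , drop = FALSE])
  y <- phi[nbj] - phi[nbi]
  s11 <- rowsum(x1 * x1, nbi)[, 1]
  s12 <- rowsum(x1 * x2, nbi)[, 1]
  s22 <- rowsum(x2 * x2, nbi)[, 1]
  b1 <- rowsum(x1 * y, nbi)[, 1]
  b2 <- rowsum(x2 * y, nbi)[, 1]
  det <- s11 * s22 - s12^2
  det[det < 1e-14] <- Inf  # degenerate -> zero gradient
  cbind((s22 * b1 - s12 * b2) / det, (s11 * b2 - s12 * b1) / det)
}

#' Advance the morphogen field by one explicit Euler step
#'
#' `N_c <- max(0, N_c + dt (diffusion + r_plus f(eps_c) - r_minus N_c))`.
#' The step must respect the diffusion stability bound
#' `dt <= 0.2 min(A) / (D max(P))`; violations raise before stepping.
#' Negative-clamping events are counted in attribute `n_clamped` (they do
#' not occur at stable step sizes).
#'
#' @param shell a `cellular_shell`.
#' @param field a [morphogen_field()].
#' @param dt time step.
#' @param geometry optional precomputed geometry.
#' @param production if `FALSE`, skip the source term.
#' @return updated field.
#' @export
step_morphogen <- function(shell, field, dt, geometry = NULL,
                           production = TRUE) {
  if (is.null(geometry)) geometry <- shell_geometry(shell)
  bound <- morphogen_dt_bound(field, geometry)
  if (dt > bound * 1.0001)
    stop(sprintf("morphogen dt = %g exceeds stability bound %g", dt, bound))
  rhs <- diffusion_rhs(shell, field, geometry) - field$r_minus * field$N
  if (production && field$r_plus != 0) {
    eps <- cell_strain(geometry$areas, field$A_ref)
    rhs <- rhs + production_rate(eps, field)
  }
  Nn <- field$N + dt * rhs
  ncl <- sum(Nn < 0)
  field$N <- pmax(0, Nn)
  if (ncl > 0) attr(field, "n_clamped") <- ncl
  field
}

morphogen_dt_bound <- function(field, geometry) {
  if (field$D == 0) return(Inf)
  0.2 * min(geometry$areas) / (field$D * max(geometry$perimeters))
}
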