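# Initial nematic configurations emulating the fiber patterns of
# regenerating spheroids: a partially ordered "fragment" pattern, a fully
# ordered pattern with a +1 defect and a +1/2 pair ("late_defects"), the
# four-+1/2 ground state, a uniform axial pattern, and i.i.d. random
# orientations.  Smooth defect fields are built by stereographic pullback
# of planar multi-defect orientation fields (conformal, so defect charges
# are preserved and the total is +2 by construction).

#' Initialize a nematic pattern on a shell
#'
#' @param shell a `cellular_shell` (spheroidal; patterns are defined
#'   relative to the mesh z-axis).
#' @param pattern one of `"fragment"`, `"late_defects"`, `"four_half"`,
#'   `"uniform"`, `"random"`.
#' @param seed seed for the random orientations (fragment disordered
#'   region, random pattern).
#' @param tau_q,alpha alignment parameters stored on the field.
#' @param disordered_fraction fragment pattern: fraction of the sphere
#'   area occupied by the disordered region (default 1/3; the ordered band
#'   then spans about two-thirds of the circumference).
#' @param bridge_rows fragment pattern: width of the disordered bridge in
#'   cell rows (default 2).
#' @param pair_sep late_defects pattern: geodesic separation of the +1/2
#'   pair, in cell diameters (default 4).
#' @return a [nematic_field()]; attribute `pattern_info` carries the
#'   pattern name, focus cells, per-cell region labels and defect anchor
#'   points.
#' @export
init_nematic <- function(shell, pattern = c("fragment", "late_defects",
                                            "four_half", "uniform",
                                            "random"),
                         seed = 1L, tau_q = 1, alpha = 0,
                         disordered_fraction = 1 / 3, bridge_rows = 2,
                         pair_sep = 4) {
  pattern <- match.arg(pattern)
  g <- shell_geometry(shell)
  fr <- shell_frames(g$normals)
  frames <- list(e1 = fr$e1, normals = g$normals)
  ctr <- g$centers
  R <- mean(sqrt(rowSums(ctr^2)))
  dirs <- ctr / sqrt(rowSums(ctr^2))
  nc <- nrow(ctr)
  dc <- cell_diameter(shell)

  psi <- numeric(nc)
  info <- list(pattern = pattern)

  if (pattern == "uniform" || pattern == "fragment") {
    psi <- axis_projection_psi(frames, c(0, 0, 1))
    # the projected axial field is singular at the two polar cells
    polar <- abs(dirs[, 3]) > 1 - 1e-9
    info$singular_cells <- which(polar | !is.finite(psi))
    psi[!is.finite(psi)] <- 0
  }

  if (pattern == "fragment") {
    # disordered region: two polar caps plus a meridional bridge of
    # ~bridge_rows cell rows, totalling disordered_fraction of the area
    delta <- bridge_rows * dc / (2 * R)          # bridge half-angle
    cos_cap <- (1 - disordered_fraction) / (1 - delta / pi)
    cos_cap <- min(cos_cap, 1 - 1e-6)
    polar_ang <- acos(pmin(1, pmax(-1, dirs[, 3])))
    in_cap <- abs(cos(polar_ang)) > cos_cap
    az <- atan2(dirs[, 2], dirs[, 1])
    in_bridge <- abs(az) < delta & !in_cap
    dis <- in_cap | in_bridge
    psi[dis] <- with_seed(seed, stats::runif(sum(dis), 0, pi))
    info$region <- ifelse(dis, "disordered", "ordered")
    info$foci <- c(which.max(dirs[, 3]), which.min(dirs[, 3]))
  }

  if (pattern == "late_defects") {
    sep_ang <- pair_sep * dc / (2 * R)
    d1 <- c(sin(pi - sep_ang), 0, cos(pi - sep_ang))    # +1/2
    d2 <- c(-sin(pi - sep_ang), 0, cos(pi - sep_ang))   # +1/2
    psi <- stereographic_defect_psi(dirs, frames,
                                    rbind(d1, d2), c(0.5, 0.5),
                                    pole = c(0, 0, 1))
    info$defect_points <- rbind(plus1 = c(0, 0, 1), half1 = d1, half2 = d2)
    info$foci <- c(which.max(dirs[, 3]), which.min(dirs[, 3]))
  }

  if (pattern == "four_half") {
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                 c(-1, -1, 1)) / sqrt(3)
    pole <- -tet[4, ]
    psi <- stereographic_defect_psi(dirs, frames, tet,
                                    rep(0.5, 4), pole = pole)
    info$defect_points <- tet
  }

  if (pattern == "random")
    psi <- with_seed(seed, stats::runif(nc, 0, pi))

  field <- nematic_field(shell, psi, tau_q = tau_q, alpha = alpha,
                         frames = frames)
  attr(field, "pattern_info") <- info
  field
}

# fiber angle of the tangent projection of a global axis, per cell
axis_projection_psi <- function(frames, axis) {
  n <- frames$normals
  d <- matrix(axis, nrow(n), 3, byrow = TRUE)
  d <- d - rowSums(d * n) * n
  nd <- sqrt(rowSums(d^2))
  e2 <- frame_e2(frames$e1, n)
  out <- atan2(rowSums(d * e2), rowSums(d * frames$e1)) %% pi
  out[nd < 1e-9] <- NA_real_
  out
}

# Orientation field with prescribed defects, by stereographic pullback:
# planar angle theta(w) = sum_k s_k arg(w - w_k); the projection pole
# carries the complementary charge 2 - sum(s_k).
stereographic_defect_psi <- function(dirs, frames, defect_dirs, charges,
                                     pole) {
  pole <- pole / sqrt(sum(pole^2))
  # orthonormal basis of the projection plane
  t1 <- if (abs(pole[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- t1 - sum(t1 * pole) * pole
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- cross3(pole, t1)
  proj <- function(P) {
    # rows of P: unit directions; stereographic from `pole`
    den <- 1 - P %*% pole
    den[den < 1e-12] <- 1e-12
    cbind((P %*% t1) / den, (P %*% t2) / den)
  }
  wk <- proj(defect_dirs)
  planar_theta <- function(w) {
    th <- 0
    for (k in seq_len(nrow(wk)))
      th <- th + charges[k] * atan2(w[, 2] - wk[k, 2], w[, 1] - wk[k, 1])
    th
  }
  w0 <- proj(dirs)
  th0 <- planar_theta(w0)
  # push the frame axes through the differential of the projection to map
  # the planar angle back into each cell's tangent frame
  h <- 1e-6
  p1 <- dirs + h * frames$e1
  p1 <- p1 / sqrt(rowSums(p1^2))
  e2 <- frame_e2(frames$e1, frames$normals)
  p2 <- dirs + h * e2
  p2 <- p2 / sqrt(rowSums(p2^2))
  dw1 <- proj(p1) - w0
  dw2 <- proj(p2) - w0
  a1 <- atan2(dw1[, 2], dw1[, 1])
  a2 <- atan2(dw2[, 2], dw2[, 1])
  # conformal (+1) or anticonformal (-1) orientation of the pullback
  sig <- sign(sin(a2 - a1))
  sig[sig == 0] <- 1
  (sig * (th0 - a1)) %% pi
}
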