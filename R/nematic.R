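# Per-cell tangent-plane unit nematic field: transport, alignment dynamics
# and topological-defect detection with exact charge accounting.
#
# Convention: each cell carries an angle psi (mod pi) in its orthonormal
# tangent frame (e1, e2, normal).  The tensor form is
#   q = (1/sqrt(2)) [[cos 2psi, sin 2psi], [sin 2psi, -cos 2psi]]
# which has unit Frobenius norm ("unit nematic").  The alignment couplings
# tau_q and alpha are defined under this convention.

#' Create a per-cell unit nematic field
#'
#' @param shell a `cellular_shell`.
#' @param psi per-cell fiber angle (radians, mod pi) in the cell tangent
#'   frame; recycled if scalar.
#' @param tau_q neighbor-alignment timescale (> 0).
#' @param alpha morphogen-gradient coupling strength (>= 0).
#' @param frames optional list(e1, normals); defaults to the shell's
#'   deterministic frames.
#' @return a `nematic_field` with fields `psi`, `e1`, `normals`, `tau_q`,
#'   `alpha`.
#' @export
nematic_field <- function(shell, psi = 0, tau_q = 1, alpha = 0,
                          frames = NULL) {
  nc <- length(shell$cells)
  psi <- rep_len(as.numeric(psi), nc) %% pi
  if (tau_q <= 0) stop("tau_q must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  if (is.null(frames)) {
    g <- shell_geometry(shell)
    fr <- shell_frames(g$normals)
    frames <- list(e1 = fr$e1, normals = g$normals)
  }
  structure(list(psi = psi, e1 = frames$e1, normals = frames$normals,
                 tau_q = tau_q, alpha = alpha),
            class = "nematic_field")
}

# e2 = n x e1 for frame matrices
frame_e2 <- function(e1, normals) cross3m(normals, e1)

# 3D-embedded symmetric components (xx,yy,zz,xy,xz,yz) of the unit tensor
nematic_q3 <- function(field) {
  c2 <- cos(2 * field$psi) / sqrt(2)
  s2 <- sin(2 * field$psi) / sqrt(2)
  e1 <- field$e1
  e2 <- frame_e2(field$e1, field$normals)
  cbind(c2 * (e1[, 1]^2 - e2[, 1]^2) + s2 * (2 * e1[, 1] * e2[, 1]),
        c2 * (e1[, 2]^2 - e2[, 2]^2) + s2 * (2 * e1[, 2] * e2[, 2]),
        c2 * (e1[, 3]^2 - e2[, 3]^2) + s2 * (2 * e1[, 3] * e2[, 3]),
        c2 * (e1[, 1] * e1[, 2] - e2[, 1] * e2[, 2]) +
          s2 * (e1[, 1] * e2[, 2] + e2[, 1] * e1[, 2]),
        c2 * (e1[, 1] * e1[, 3] - e2[, 1] * e2[, 3]) +
          s2 * (e1[, 1] * e2[, 3] + e2[, 1] * e1[, 3]),
        c2 * (e1[, 2] * e1[, 3] - e2[, 2] * e2[, 3]) +
          s2 * (e1[, 2] * e2[, 3] + e2[, 2] * e1[, 3]))
}

# 2x2 tensor from an angle (unit Frobenius norm times `mag`)
q_tensor <- function(psi, mag = 1) {
  m <- mag / sqrt(2)
  matrix(c(m * cos(2 * psi), m * sin(2 * psi),
           m * sin(2 * psi), -m * cos(2 * psi)), 2, 2)
}

# angle and magnitude of a traceless symmetric 2x2 tensor
tensor_angle <- function(q) atan2(q[1, 2], q[1, 1]) / 2
tensor_mag <- function(q) sqrt(2 * (q[1, 1]^2 + q[1, 2]^2))

# Rodrigues rotation of rows of v by the minimal rotation taking unit rows
# n1 onto unit rows n2
minimal_rotate_rows <- function(v, n1, n2) {
  k <- cross3m(n1, n2)
  sk <- sqrt(rowSums(k^2))
  ck <- rowSums(n1 * n2)
  if (any(ck < -1 + 1e-12))
    stop("antipodal normals: minimal rotation undefined")
  kk <- k
  ok <- sk > 1e-15
  kk[ok, ] <- k[ok, , drop = FALSE] / sk[ok]
  kv <- cross3m(kk, v)
  kdv <- rowSums(kk * v)
  out <- v * ck + kv * sk + kk * kdv * (1 - ck)
  out[!ok, ] <- v[!ok, , drop = FALSE]
  out
}

# angle offset a(i->j) for each directed pair: a direction with angle phi in
# frame i maps, under minimal-rotation transport, to angle phi + a in frame j
pair_transport_angles <- function(e1, normals, i, j) {
  v <- minimal_rotate_rows(e1[i, , drop = FALSE],
                           normals[i, , drop = FALSE],
                           normals[j, , drop = FALSE])
  e1j <- e1[j, , drop = FALSE]
  e2j <- frame_e2(e1j, normals[j, , drop = FALSE])
  atan2(rowSums(v * e2j), rowSums(v * e1j))
}

# transport all frames of a field from old normals to new ones (convection /
# co-rotation of the nematic with the moving tissue; psi is unchanged in the
# co-moving frame)
transport_field_frames <- function(field, old_normals, new_normals) {
  e1 <- minimal_rotate_rows(field$e1, old_normals, new_normals)
  # remove numerical drift out of the tangent plane
  e1 <- e1 - rowSums(e1 * new_normals) * new_normals
  e1 <- e1 / sqrt(rowSums(e1^2))
  field$e1 <- e1
  field$normals <- new_normals
  field
}

#' Transport a nematic tensor between tangent frames
#'
#' The source frame is carried onto the target tangent plane by the minimal
#' rotation about `old_normal x new_normal`; the tensor's components are
#' then re-expressed in the target frame.  Norm-preserving; errors for
#' antipodal normals.
#'
#' @param q 2x2 traceless symmetric tensor (components in `from` frame) or
#'   a scalar angle.
#' @param from,to frames: lists with unit `e1` and `normal`.
#' @return 2x2 tensor in the `to` frame (or angle, matching the input type).
#' @export
transport_nematic <- function(q, from, to) {
  a <- pair_transport_angles(rbind(from$e1, to$e1),
                             rbind(from$normal, to$normal), 1L, 2L)
  if (is.matrix(q)) q_tensor(tensor_angle(q) + a, tensor_mag(q))
  else (q + a) %% pi
}

#' Average neighbor nematic tensor
#'
#' Each neighbor's tensor is transported into the cell's tangent plane
#' (minimal rotation), and the arithmetic mean over the `n_c` neighbors is
#' returned -- not renormalized, so its magnitude measures local alignment.
#'
#' @param shell a `cellular_shell`.
#' @param field a [nematic_field()].
#' @param cell cell index.
#' @return 2x2 traceless symmetric tensor in the cell's frame.
#' @export
neighbor_average <- function(shell, field, cell) {
  nb <- shell$cell_neighbors[[cell]]
  if (length(nb) < 1L) stop("isolated cell")
  a <- pair_transport_angles(field$e1, field$normals, nb,
                             rep.int(cell, length(nb)))
  u1 <- mean(cos(2 * (field$psi[nb] + a)))
  u2 <- mean(sin(2 * (field$psi[nb] + a)))
  matrix(c(u1, u2, u2, -u1) / sqrt(2), 2, 2)
}

#' Nematic alignment tensor of an in-plane gradient
#'
#' `T = g g^T - (|g|^2 / 2) I`: the traceless-symmetric part of the outer
#' product, invariant under `g -> -g` (the nematic aligns to the gradient
#' axis, not its polarity), with principal axis along `g`.
#'
#' @param grad in-plane 2D vector.
#' @return 2x2 traceless symmetric tensor.
#' @export
gradient_alignment_tensor <- function(grad) {
  g2 <- sum(grad^2)
  matrix(c(grad[1]^2 - g2 / 2, grad[1] * grad[2],
           grad[1] * grad[2], grad[2]^2 - g2 / 2), 2, 2)
}

#' Advance the nematic field by one alignment step
#'
#' Unconstrained rate `r_c = <q>_c / tau_q + alpha T(grad phi_c)`; the
#' update is projected orthogonal to `q_c` and the result renormalized,
#' which realizes the unit-norm Lagrange multiplier to first order in dt.
#' With `alpha = 0` a uniform flat field is stationary.
#'
#' @param shell a `cellular_shell`.
#' @param field a [nematic_field()].
#' @param phi per-cell morphogen concentration (used when `alpha > 0`).
#' @param dt time step.
#' @param gradients optional precomputed n_c x 2 in-plane gradient matrix.
#' @return updated field.
#' @export
step_nematic <- function(shell, field, phi = NULL, dt = 0.1,
                         gradients = NULL) {
  nc <- length(shell$cells)
  pairs_j <- unlist(shell$cell_neighbors, use.names = FALSE)
  deg <- lengths(shell$cell_neighbors)
  pairs_i <- rep.int(seq_len(nc), deg)
  a <- pair_transport_angles(field$e1, field$normals, pairs_j, pairs_i)
  tw <- 2 * (field$psi[pairs_j] + a)
  u1 <- rowsum(cos(tw), pairs_i)[, 1] / deg
  u2 <- rowsum(sin(tw), pairs_i)[, 1] / deg
  r1 <- u1 / field$tau_q
  r2 <- u2 / field$tau_q
  if (field$alpha > 0) {
    if (is.null(gradients)) {
      if (is.null(phi)) stop("phi required when alpha > 0")
      gradients <- gradient_estimate_all(shell, phi, field)
    }
    # doubled-angle components of sqrt(2) * T(g): T11*sqrt2, T12*sqrt2
    r1 <- r1 + field$alpha * sqrt(2) * (gradients[, 1]^2 -
                                          gradients[, 2]^2) / 2
    r2 <- r2 + field$alpha * sqrt(2) * gradients[, 1] * gradients[, 2]
  }
  c0 <- cos(2 * field$psi)
  s0 <- sin(2 * field$psi)
  # project rate orthogonal to q (in doubled-angle vector space)
  dp <- r1 * c0 + r2 * s0
  n1 <- c0 + dt * (r1 - dp * c0)
  n2 <- s0 + dt * (r2 - dp * s0)
  nn <- sqrt(n1^2 + n2^2)
  bad <- nn < 1e-12
  psi <- field$psi
  psi[!bad] <- (atan2(n2[!bad], n1[!bad]) / 2) %% pi
  field$psi <- psi
  if (any(bad))
    attr(field, "degenerate_updates") <- sum(bad)
  field
}

#' Detect topological defects and their charges
#'
#' For every vertex, the ordered ring of incident cells is traversed; the
#' step-to-step change of the fiber angle is measured after
#' minimal-rotation transport and wrapped to (-pi/2, pi/2], and the loop's
#' holonomy (the net frame rotation accumulated around the ring, equal to
#' the spherical area swept by the cell normals) is added back.  The
#' resulting winding is an exact half-integer up to float noise, and the
#' vertex charges sum to exactly +2 on any closed genus-0 shell
#' (Poincare-Hopf), for arbitrary unit fields.  Charged vertices within
#' about one cell of each other (single-linkage at `merge_dist` cell
#' diameters) are merged into single defects, so a discrete +1 aster whose
#' winding is spread over two adjacent vertices is reported as one +1.
#'
#' @param shell a `cellular_shell`.
#' @param field a [nematic_field()].
#' @param merge_dist single-linkage merge radius in units of the typical
#'   cell diameter (default 1.25).
#' @return a `defect_set`: data.frame with `x, y, z, charge, cell`
#'   (nearest cell), plus attributes `total_charge` and `vertex_charges`.
#' @export
detect_defects <- function(shell, field, merge_dist = 1.25) {
  nv <- nrow(shell$positions)
  rings <- shell$vertex_cells
  # all consecutive ring pairs, batched
  m <- lengths(rings)
  ci <- unlist(rings, use.names = FALSE)
  nxt <- unlist(lapply(rings, function(r) c(r[-1], r[1])), use.names = FALSE)
  vid <- rep.int(seq_len(nv), m)
  a <- pair_transport_angles(field$e1, field$normals, ci, nxt)
  dpsi <- field$psi[nxt] - field$psi[ci] - a
  wr <- dpsi - pi * round(dpsi / pi)          # wrap to (-pi/2, pi/2]
  s_v <- rowsum(wr, vid)[, 1]
  a_v <- rowsum(a, vid)[, 1]
  hol <- a_v - 2 * pi * round(a_v / (2 * pi))  # wrap to (-pi, pi]
  q_raw <- (s_v + hol) / (2 * pi)
  q_v <- round(2 * q_raw) / 2
  charged <- which(q_v != 0)
  # single-linkage clustering of charged vertices within ~one cell
  defects <- list()
  if (length(charged)) {
    rad <- merge_dist * cell_diameter(shell)
    close <- as.matrix(stats::dist(
      shell$positions[charged, , drop = FALSE])) <= rad
    left <- seq_along(charged)
    while (length(left)) {
      comp <- left[1]
      repeat {
        grow <- left[colSums(close[comp, left, drop = FALSE]) > 0]
        grow <- setdiff(grow, comp)
        if (!length(grow)) break
        comp <- c(comp, grow)
      }
      defects[[length(defects) + 1L]] <- charged[comp]
      left <- setdiff(left, comp)
    }
  }
  out <- do.call(rbind, lapply(defects, function(vs) {
    w <- abs(q_v[vs])
    pos <- colSums(shell$positions[vs, , drop = FALSE] * w) / sum(w)
    data.frame(x = pos[1], y = pos[2], z = pos[3],
               charge = sum(q_v[vs]), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      charge = numeric(0))
  out <- out[out$charge != 0, , drop = FALSE]
  if (nrow(out)) {
    ctr <- shell_kernel(shell)$centers
    out$cell <- vapply(seq_len(nrow(out)), function(i) {
      d2 <- (ctr[, 1] - out$x[i])^2 + (ctr[, 2] - out$y[i])^2 +
        (ctr[, 3] - out$z[i])^2
      which.min(d2)
    }, 1L)
  } else out$cell <- integer(0)
  structure(out, class = c("defect_set", "data.frame"),
            total_charge = sum(q_v), vertex_charges = q_v)
}

# vertex adjacency list from bonds
vertex_adjacency <- function(shell) {
  nv <- nrow(shell$positions)
  b <- shell$bonds
  adj <- split(c(b[, "v2"], b[, "v1"]), c(b[, "v1"], b[, "v2"]))
  out <- vector("list", nv)
  out[as.integer(names(adj))] <- adj
  out
}

#' Greedy nearest-neighbor matching of defect sets across frames
#'
#' @param prev,cur `defect_set`s from [detect_defects()].
#' @param max_dist maximum matching distance.
#' @return integer vector: for each row of `cur`, the matched row of
#'   `prev` or `NA`.
#' @export
match_defects <- function(prev, cur, max_dist = Inf) {
  if (!nrow(cur)) return(integer(0))
  out <- rep(NA_integer_, nrow(cur))
  if (!nrow(prev)) return(out)
  avail <- seq_len(nrow(prev))
  d <- outer(seq_len(nrow(cur)), seq_len(nrow(prev)), function(i, j) {
    sqrt((cur$x[i] - prev$x[j])^2 + (cur$y[i] - prev$y[j])^2 +
           (cur$z[i] - prev$z[j])^2)
  })
  for (k in order(apply(d, 1, min))) {
    if (!length(avail)) break
    j <- avail[which.min(d[k, avail])]
    if (d[k, j] <= max_dist &&
        abs(cur$charge[k] - prev$charge[j]) < 0.26) {
      out[k] <- j
      avail <- setdiff(avail, j)
    }
  }
  out
}
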