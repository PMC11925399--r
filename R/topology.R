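# Topology changes: bond collapse below the threshold length and
# resolution of multi-fold vertices (T1 transitions).

#' Handle short bonds and multi-fold vertices
#'
#' Every bond shorter than `L_th` is collapsed to a single vertex (merging
#' its endpoints at their midpoint).  Each fourfold vertex is then tested
#' against its two threefold resolutions -- reverting to the original
#' neighbor topology or rearranging (a T1 transition) -- by placing a trial
#' bond of length `2 L_th` and comparing energies; the resolution with the
#' larger energy decrease is applied, and on a tie (or if neither decreases
#' the energy) the vertex stays merged.  Vertices with more than four cells
#' are left merged (they are supported but not resolved).  Per-cell fields
#' (nematic angle, morphogen count, reference areas) are untouched: cells
#' persist through T1s.
#'
#' @param state a [shell_state()].
#' @param L_th collapse threshold; defaults to `params$L_th`.
#' @return updated state (`n_t1` counts applied rearrangements).
#' @export
handle_topology <- function(state, L_th = NULL) {
  if (is.null(L_th)) L_th <- state$params$L_th
  repeat {
    g <- shell_kernel(state$shell)
    short <- which(g$bond_lengths < L_th)
    if (!length(short)) break
    b <- short[which.min(g$bond_lengths[short])]
    state2 <- tryCatch(collapse_bond(state, b), error = function(e) {
      warning(sprintf("skipping bond collapse: %s", conditionMessage(e)))
      NULL
    })
    if (is.null(state2)) break
    state <- state2
  }
  # resolve fourfold vertices
  repeat {
    rings <- state$shell$vertex_cells
    four <- which(lengths(rings) == 4L)
    if (!length(four)) break
    changed <- FALSE
    for (v in four) {
      res <- resolve_fourfold(state, v, L_th)
      if (!is.null(res)) {
        state <- res
        changed <- TRUE
        break  # connectivity changed; recompute vertex list
      }
    }
    if (!changed) break
  }
  state
}

# merge the two endpoints of bond b into one vertex at the midpoint
collapse_bond <- function(state, b) {
  shell <- state$shell
  v1 <- shell$bonds[b, "v1"]
  v2 <- shell$bonds[b, "v2"]
  pos <- shell$positions
  mid <- (pos[v1, ] + pos[v2, ]) / 2
  cells <- lapply(shell$cells, function(cy) {
    cy[cy == v2] <- v1
    prev <- c(cy[length(cy)], cy[-length(cy)])
    cy[cy != prev]
  })
  if (any(vapply(cells, length, 1L) < 3L))
    stop("bond collapse would degenerate a triangular cell")
  pos[v1, ] <- mid
  keep <- setdiff(seq_len(nrow(pos)), v2)
  remap <- integer(nrow(pos))
  remap[keep] <- seq_along(keep)
  cells <- lapply(cells, function(cy) remap[cy])
  state$shell <- cellular_shell(pos[keep, , drop = FALSE], cells,
                                check = FALSE)
  state <- refresh_after_surgery(state)
  state
}

# try both threefold resolutions of fourfold vertex v; apply the better
# energy-decreasing one, or return NULL to stay merged
resolve_fourfold <- function(state, v, L_th) {
  shell <- state$shell
  ring <- shell$vertex_cells[[v]]  # (c0, c1, c2, c3) in cyclic order
  e0 <- topology_energy(state, shell)
  cand <- list(NULL, NULL)
  drops <- c(NA_real_, NA_real_)
  for (split in 1:2) {
    # opposite pair (ring[split], ring[split+2]) shares the new bond;
    # ring[split+1] keeps vertex va, ring[split+3] keeps vb
    sh2 <- try_split(shell, v, ring[c(split, split %% 4L + 1L,
                                      (split + 1L) %% 4L + 1L,
                                      (split + 2L) %% 4L + 1L)], L_th)
    if (is.null(sh2)) next
    cand[[split]] <- sh2
    drops[split] <- e0 - topology_energy(state, sh2)
  }
  ok <- !is.na(drops) & drops > 1e-12
  if (!any(ok)) return(NULL)
  if (all(ok) &&
      abs(drops[1] - drops[2]) <= 1e-9 * max(1, abs(drops[1])))
    return(NULL)  # tie between the two resolutions: stay merged
  pick <- which.max(replace(drops, !ok, -Inf))
  state$shell <- cand[[pick]]
  state$n_t1 <- state$n_t1 + 1L
  refresh_after_surgery(state)
}

topology_energy <- function(state, shell) {
  # candidate configurations are compared under the same (frozen) nematic
  q3 <- if (!is.null(state$nematic) && state$zeta != 0)
    nematic_q3(state$nematic) else NULL
  k <- shell_kernel(shell, state$params, q3 = q3, zeta = state$zeta)
  k$E_elastic + k$E_active
}

# split vertex v: cells quad = (ca, cb, cc, cd) cyclic; ca & cc share the
# new bond, cb keeps va (displaced toward cb), cd keeps vb
try_split <- function(shell, v, quad, L_th) {
  ctr <- shell_kernel(shell)$centers
  u <- ctr[quad[2], ] - ctr[quad[4], ]
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(NULL)
  u <- u / nu
  pos <- shell$positions
  va <- pos[v, ] + L_th * u
  vb <- pos[v, ] - L_th * u
  nv <- nrow(pos)
  pos2 <- rbind(pos, vb)  # new vertex id nv+1 = vb; v itself becomes va
  pos2[v, ] <- va
  for (order_try in 1:2) {
    cells <- shell$cells
    ins <- if (order_try == 1L) c(v, nv + 1L) else c(nv + 1L, v)
    for (ci in c(quad[1], quad[3])) {
      cy <- cells[[ci]]
      k <- which(cy == v)
      cells[[ci]] <- append(cy[-k], ins, after = k - 1L)
      ins <- rev(ins)  # opposite traversal in the opposite cell
    }
    cy <- cells[[quad[4]]]
    cy[cy == v] <- nv + 1L
    cells[[quad[4]]] <- cy
    sh2 <- tryCatch(cellular_shell(pos2, cells, check = FALSE),
                    error = function(e) NULL)
    if (!is.null(sh2) && enclosed_volume(sh2) > 0) {
      d <- validate_shell(sh2)
      if (d$ok) return(sh2)
    }
  }
  NULL
}

# rebuild caches after a surgery; per-cell fields persist, frames are
# refreshed from the new geometry normals
refresh_after_surgery <- function(state) {
  g <- shell_geometry(state$shell)
  if (!is.null(state$nematic)) {
    nem <- state$nematic
    nem <- transport_field_frames(nem, nem$normals, g$normals)
    state$nematic <- nem
  }
  state$normals <- g$normals
  state
}
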