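# Deformation quantification: logarithmic area-strain profiles by graph
# distance around a focus, peak-frame selection, event classification, and
# the triangle-based cell-shape anisotropy tensor.

#' Logarithmic area-strain profile by graph distance
#'
#' Per distance shell, the mean log cell area at the event peak minus the
#' mean log area before the event; algebraically identical to the mean of
#' `log(A_peak / A_before)` over the cells at that distance (both orders
#' are computed and cross-checked internally).
#'
#' @param areas_before,areas_peak positive per-cell areas (matched cells).
#' @param distances non-negative integer graph distances from the focus.
#' @param min_cells distances with fewer cells than this are flagged
#'   (`reliable = FALSE`), not dropped (default 3).
#' @return a `strain_profile`: data.frame with `distance`, `mean`, `sd`,
#'   `n`, `reliable`; attributes `core` (mean over distance <= 1),
#'   `per_cell` (per-cell log strains) and `regions` (core <= 3,
#'   intermediate 4-5, far >= 6).
#' @export
log_area_strain_profile <- function(areas_before, areas_peak, distances,
                                    min_cells = 3L) {
  n <- length(areas_before)
  if (length(areas_peak) != n || length(distances) != n)
    stop("unmatched cell sets")
  if (any(areas_before <= 0) || any(areas_peak <= 0))
    stop("non-positive cell area")
  strain <- log(areas_peak / areas_before)
  d <- as.integer(round(distances))
  agg <- function(f) tapply(strain, d, f)
  m1 <- tapply(log(areas_peak), d, mean) - tapply(log(areas_before), d, mean)
  m2 <- agg(mean)
  stopifnot(max(abs(m1 - m2)) < 1e-10)  # the two printed-equivalent forms
  out <- data.frame(distance = as.integer(names(m2)), mean = as.numeric(m2),
                    sd = as.numeric(agg(stats::sd)),
                    n = as.integer(agg(length)))
  out$reliable <- out$n >= min_cells
  region <- cut(out$distance, c(-1, 3, 5, Inf),
                labels = c("core", "intermediate", "far"))
  structure(out, class = c("strain_profile", "data.frame"),
            core = mean(strain[d <= 1]), per_cell = strain,
            distances = d, regions = region)
}

#' Peak frame of a stretching event
#'
#' The frame maximizing the total area of the cells within graph distance 3
#' of the focus; ties resolve to the earliest frame.
#'
#' @param area_series n_frames x n_cells matrix of cell areas.
#' @param distances per-cell graph distances from the focus.
#' @return frame index (1-based).
#' @export
find_peak_frame <- function(area_series, distances) {
  if (nrow(area_series) < 2L) stop("need at least 2 frames")
  core <- distances <= 3
  if (!any(core)) stop("empty core set")
  tot <- rowSums(area_series[, core, drop = FALSE])
  which.max(tot)  # which.max returns the earliest maximum
}

#' Classify a stretching event as large / small / none
#'
#' Large: some core cell (distance <= 1) exceeds a twofold area increase
#' (strictly); small: a coherent bump exists (core log strain > 0.1) but
#' no cell doubles; none otherwise.
#'
#' @param profile a [log_area_strain_profile()] result.
#' @return one of `"large"`, `"small"`, `"none"`.
#' @export
classify_event <- function(profile) {
  strain <- attr(profile, "per_cell")
  d <- attr(profile, "distances")
  core <- strain[d <= 1]
  if (length(core) && exp(max(core)) > 2) return("large")
  if (attr(profile, "core") > 0.1) return("small")
  "none"
}

#' Cell shape anisotropy tensor (triangle method)
#'
#' The cell is divided into fan triangles (center + adjacent vertex pairs);
#' each triangle is compared with an area-matched equilateral reference via
#' the linear map between them, whose left polar stretch gives the
#' triangle's Hencky (log) strain; the traceless part, area-weighted over
#' triangles and expressed in the cell tangent frame, is `Q`.  Regular
#' polygons give `Q = 0`; a pure rigid motion leaves `Q` unchanged; an
#' affine stretch `diag(e^s, e^-s)` gives `|Q| = s` with the principal
#' axis along x.
#'
#' @param geometry a `cell_geometry` from [build_cell_geometry()], or a
#'   shell plus `cell_id`.
#' @param shell optional `cellular_shell` when `geometry` is a cell id.
#' @return a `shape_tensor`: 2x2 traceless symmetric matrix with
#'   attributes `magnitude` (largest eigenvalue) and `axis` (angle of the
#'   principal axis in the tangent frame).
#' @export
cell_shape_tensor <- function(geometry, shell = NULL) {
  if (!inherits(geometry, "cell_geometry")) {
    stopifnot(!is.null(shell))
    geometry <- build_cell_geometry(shell, geometry)
  }
  if (is.null(shell)) stop("shell required to access the cell's vertices")
  vidx <- shell$cells[[geometry$cell_id]]
  V <- shell$positions[vidx, , drop = FALSE]
  m <- nrow(V)
  # 2D coordinates in the tangent frame, relative to the center
  rel <- sweep(V, 2, geometry$center)
  xy <- cbind(rel %*% geometry$e1, rel %*% geometry$e2)
  Qsum <- matrix(0, 2, 2)
  wsum <- 0
  excluded <- 0L
  for (k in seq_len(m)) {
    p1 <- xy[k, ]
    p2 <- xy[if (k == m) 1L else k + 1L, ]
    M <- cbind(p1, p2)
    A_t <- abs(det(M)) / 2
    if (A_t < 1e-12) { excluded <- excluded + 1L; next }
    # area-matched equilateral reference (vertices at the origin analog of
    # (0,0), (L,0), (L/2, L sqrt(3)/2) shifted so the first vertex is the
    # cell-center image)
    L <- sqrt(4 * A_t / sqrt(3))
    Mref <- cbind(c(L, 0), c(L / 2, L * sqrt(3) / 2))
    F <- M %*% solve(Mref)
    # left polar stretch: V = sqrt(F F^T)
    FFt <- F %*% t(F)
    e <- eigen(FFt, symmetric = TRUE)
    logV <- e$vectors %*% diag(0.5 * log(e$values)) %*% t(e$vectors)
    Qt <- logV - diag(2) * sum(diag(logV)) / 2
    Qsum <- Qsum + A_t * Qt
    wsum <- wsum + A_t
  }
  if (wsum == 0) stop("all triangles degenerate")
  Q <- Qsum / wsum
  structure(Q, class = "shape_tensor",
            magnitude = sqrt(Q[1, 1]^2 + Q[1, 2]^2),
            axis = atan2(Q[1, 2], Q[1, 1]) / 2,
            excluded = excluded)
}

#' Project an anisotropy tensor along a direction
#'
#' `d . Q d` for a unit in-plane direction `d`: positive when the cell is
#' elongated toward `d`, negative when compressed, zero at 45 degrees from
#' the principal axis.
#'
#' @param Q a 2x2 traceless symmetric tensor (e.g. [cell_shape_tensor()]).
#' @param direction length-2 in-plane direction (normalized internally;
#'   must be nonzero).
#' @return scalar projection.
#' @export
project_anisotropy <- function(Q, direction) {
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-14) stop("zero direction")
  d <- direction / nd
  as.numeric(t(d) %*% Q %*% d)
}
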