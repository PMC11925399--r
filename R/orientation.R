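# Fiber-orientation analysis of 2D intensity rasters: structure-tensor
# orientation extraction, doubled-angle smoothing, coherence, nematic
# order parameter, coherence-threshold masking and winding-number defect
# detection.
#
# Convention: pixel (i, j) sits at x = j, y = i (in pixels); angles are
# measured from the +x axis toward +y, mod pi.  Physical window sizes are
# in micrometres and convert through `pixel_size` (um/px, default 1).

# 1D convolution along rows/cols with edge replication
conv1d <- function(m, k, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") return(t(conv1d(t(m), k, "rows")))
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  pad <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * pad[(t - 1L) + seq_len(n), , drop = FALSE]
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

box_kernel <- function(w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L  # symmetric (odd) support
  rep(1 / w, w)
}

gaussian_smooth2 <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  conv1d(conv1d(m, k, "rows"), k, "cols")
}

box_smooth2 <- function(m, w) {
  k <- box_kernel(w)
  conv1d(conv1d(m, k, "rows"), k, "cols")
}

#' Raw fiber orientation field from intensity gradients
#'
#' Structure-tensor orientation: image gradients (central differences
#' after light pre-smoothing, sigma = 1 px) are box-averaged over a
#' `window`-sized neighborhood; the fiber orientation is the minor
#' eigenvector of the structure tensor (perpendicular to the dominant
#' gradient), mod pi.  Pixels with vanishing gradient energy are `NA`.
#'
#' @param raster numeric matrix (grayscale intensities).
#' @param window physical window size (um, default 6).
#' @param pixel_size um per pixel (default 1); the window must be at
#'   least 3 px after conversion.
#' @param pre_sigma pre-smoothing sigma in px (default 1).
#' @return matrix of angles in `[0, pi)` with `NA` at degenerate pixels;
#'   attribute `energy` holds the local gradient energy.
#' @export
raw_orientation_field <- function(raster, window = 6, pixel_size = 1,
                                  pre_sigma = 1) {
  wpx <- round(window / pixel_size)
  if (wpx < 3) stop("orientation window smaller than 3 px")
  sm <- gaussian_smooth2(raster, pre_sigma)
  n <- nrow(sm); m <- ncol(sm)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  gx[, 2:(m - 1)] <- (sm[, 3:m] - sm[, 1:(m - 2)]) / 2
  gy[2:(n - 1), ] <- (sm[3:n, ] - sm[1:(n - 2), ]) / 2
  J11 <- box_smooth2(gx * gx, wpx)
  J22 <- box_smooth2(gy * gy, wpx)
  J12 <- box_smooth2(gx * gy, wpx)
  energy <- J11 + J22
  # dominant gradient direction, then rotate by pi/2 for the fiber axis
  theta <- (0.5 * atan2(2 * J12, J11 - J22) + pi / 2) %% pi
  theta[energy < 1e-12 * max(energy, 1e-300)] <- NA_real_
  attr(theta, "energy") <- energy
  theta
}

#' Smooth an orientation field (doubled-angle Gaussian)
#'
#' Smoothing acts on `(cos 2 theta, sin 2 theta)` and the angle is
#' re-extracted, so mod-pi wraparound is handled correctly (89 deg and
#' 91 deg average to 90 deg, never 0).  `NA` pixels are excluded with
#' normalized weights.
#'
#' @param theta orientation matrix (radians mod pi, `NA` allowed).
#' @param sigma Gaussian sigma (um, default 4).
#' @param pixel_size um per pixel.
#' @return smoothed orientation matrix.
#' @export
smooth_orientation <- function(theta, sigma = 4, pixel_size = 1) {
  spx <- sigma / pixel_size
  ok <- !is.na(theta)
  c2 <- ifelse(ok, cos(2 * theta), 0)
  s2 <- ifelse(ok, sin(2 * theta), 0)
  w <- gaussian_smooth2(ok + 0, spx)
  cs <- gaussian_smooth2(c2, spx) / pmax(w, 1e-12)
  ss <- gaussian_smooth2(s2, spx) / pmax(w, 1e-12)
  out <- (atan2(ss, cs) / 2) %% pi
  out[w < 1e-6] <- NA_real_
  out
}

#' Coherence of the raw orientation field
#'
#' Per pixel, the mean over a square window of
#' `|cos(theta - theta_ij)|` over the raw orientations `theta_ij` in the
#' window.  The reference `theta` is the raw orientation at the window
#' center (the coherence is computed from the field before smoothing); a
#' smoothed reference field can be supplied instead.  Values: 1 for
#' perfectly consistent fields, 2/pi for i.i.d. random orientations.
#'
#' @param theta_raw raw orientation field ([raw_orientation_field()]).
#' @param theta reference orientation per pixel; default `NULL` uses
#'   `theta_raw` itself.
#' @param window averaging window (um, default 15).
#' @param pixel_size um per pixel.
#' @return coherence matrix in `[0, 1]`.
#' @export
coherence_map <- function(theta_raw, theta = NULL, window = 15,
                          pixel_size = 1) {
  if (is.null(theta)) theta <- theta_raw
  stopifnot(all(dim(theta_raw) == dim(theta)))
  wpx <- max(3L, round(window / pixel_size))
  r <- wpx %/% 2L
  n <- nrow(theta); m <- ncol(theta)
  acc <- matrix(0, n, m)
  cnt <- matrix(0, n, m)
  padi <- c(rep(1L, r), seq_len(n), rep(n, r))
  padj <- c(rep(1L, r), seq_len(m), rep(m, r))
  thr <- theta_raw[padi, padj, drop = FALSE]
  for (di in 0:(2 * r)) {
    for (dj in 0:(2 * r)) {
      blk <- thr[di + seq_len(n), dj + seq_len(m), drop = FALSE]
      v <- abs(cos(theta - blk))
      good <- !is.na(v)
      acc[good] <- acc[good] + v[good]
      cnt <- cnt + good
    }
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Nematic order parameter map
#'
#' `S = |windowed mean of (cos 2 theta, sin 2 theta)|`, computed from the
#' smoothed orientation: 1 for parallel alignment, minimal at defect
#' cores.
#'
#' @param theta smoothed orientation field.
#' @param window averaging window (um, default 25).
#' @param pixel_size um per pixel.
#' @return matrix of `S` in `[0, 1]`.
#' @export
order_parameter_map <- function(theta, window = 25, pixel_size = 1) {
  wpx <- max(3L, round(window / pixel_size))
  ok <- !is.na(theta)
  w <- box_smooth2(ok + 0, wpx)
  cs <- box_smooth2(ifelse(ok, cos(2 * theta), 0), wpx) / pmax(w, 1e-12)
  ss <- box_smooth2(ifelse(ok, sin(2 * theta), 0), wpx) / pmax(w, 1e-12)
  out <- sqrt(cs^2 + ss^2)
  out[w < 1e-6] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Detect topological defects in a 2D orientation field
#'
#' Winding of the (doubled) orientation around every elementary pixel
#' plaquette, halved and rounded to the nearest half-integer; nonzero
#' plaquettes are clustered (single linkage within `cluster_radius` px)
#' into defects with mean position and summed charge.
#'
#' @param theta orientation field (radians mod pi).
#' @param mask optional logical matrix; plaquettes touching masked-out or
#'   `NA` pixels are skipped.
#' @param cluster_radius clustering radius in px (default 12, about three times
#'   the default smoothing sigma: a smoothed +1 aster splits into two
#'   half-integer winding cores roughly that far apart).
#' @param margin border margin in px excluded from detection (default 8,
#'   about twice the smoothing sigma: windowed operators are unreliable
#'   in that band).
#' @return data.frame with `x`, `y` (charge-weighted pixel coordinates,
#'   col/row) and `charge`.
#' @export
detect_defects_2d <- function(theta, mask = NULL, cluster_radius = 12,
                              margin = 8) {
  n <- nrow(theta); m <- ncol(theta)
  ok <- !is.na(theta)
  if (!is.null(mask)) ok <- ok & mask
  if (margin > 0) {
    ok[seq_len(min(margin, n)), ] <- FALSE
    ok[n + 1 - seq_len(min(margin, n)), ] <- FALSE
    ok[, seq_len(min(margin, m))] <- FALSE
    ok[, m + 1 - seq_len(min(margin, m))] <- FALSE
  }
  t00 <- theta[1:(n - 1), 1:(m - 1)]
  t01 <- theta[1:(n - 1), 2:m]
  t11 <- theta[2:n, 2:m]
  t10 <- theta[2:n, 1:(m - 1)]
  wrap <- function(x) x - pi * round(x / pi)
  wsum <- wrap(t01 - t00) + wrap(t11 - t01) + wrap(t10 - t11) +
    wrap(t00 - t10)
  q <- round(wsum / pi) / 2
  valid <- ok[1:(n - 1), 1:(m - 1)] & ok[1:(n - 1), 2:m] &
    ok[2:n, 2:m] & ok[2:n, 1:(m - 1)]
  q[!valid] <- 0
  hit <- which(q != 0, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(x = numeric(0), y = numeric(0),
                      charge = numeric(0)))
  pts <- cbind(x = hit[, 2] + 0.5, y = hit[, 1] + 0.5)
  qs <- q[hit]
  close <- as.matrix(stats::dist(pts)) <= cluster_radius
  left <- seq_len(nrow(pts))
  out <- list()
  while (length(left)) {
    comp <- left[1]
    repeat {
      grow <- setdiff(left[colSums(close[comp, left, drop = FALSE]) > 0],
                      comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    w <- abs(qs[comp])
    out[[length(out) + 1L]] <- data.frame(
      x = sum(w * pts[comp, "x"]) / sum(w),
      y = sum(w * pts[comp, "y"]) / sum(w),
      charge = sum(qs[comp]))
    left <- setdiff(left, comp)
  }
  res <- do.call(rbind, out)
  res[res$charge != 0, , drop = FALSE]
}

#' Full orientation analysis of a fiber-intensity raster
#'
#' Runs the whole pipeline: raw structure-tensor orientation, doubled-angle
#' smoothing, coherence, order parameter, coherence-threshold mask and 2D
#' defect detection.
#'
#' @param raster grayscale intensity matrix.
#' @param pixel_size um per pixel (default 1).
#' @param coherence_threshold mask threshold (default 0.88).
#' @param orientation_window,smooth_sigma,coherence_window,order_window
#'   physical analysis scales in um (defaults 6, 4, 15, 25).
#' @return an `orientation_maps` list: `theta_raw`, `theta`, `coherence`,
#'   `S`, `mask`, `defects`, `pixel_size`.
#' @export
analyze_orientation <- function(raster, pixel_size = 1,
                                coherence_threshold = 0.88,
                                orientation_window = 6, smooth_sigma = 4,
                                coherence_window = 15, order_window = 25) {
  theta_raw <- raw_orientation_field(raster, orientation_window,
                                     pixel_size)
  theta <- smooth_orientation(theta_raw, smooth_sigma, pixel_size)
  coh <- coherence_map(theta_raw, window = coherence_window,
                       pixel_size = pixel_size)
  S <- order_parameter_map(theta, order_window, pixel_size)
  mask <- !is.na(coh) & coh >= coherence_threshold
  defects <- detect_defects_2d(theta)
  structure(list(theta_raw = theta_raw, theta = theta, coherence = coh,
                 S = S, mask = mask, defects = defects,
                 pixel_size = pixel_size,
                 coherence_threshold = coherence_threshold),
            class = "orientation_maps")
}
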