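# Synthetic fiber-texture rasters with known orientation ground truth:
# stripes, +1 asters and half-integer defect motifs rendered as short
# line segments drawn along the local orientation.

#' Render a synthetic fiber-intensity raster
#'
#' Stripes and asters are rendered as smooth periodic textures (sinusoid
#' perpendicular to the stripes; radial spokes for the aster); the
#' half-integer defect motifs are rendered as many short line segments
#' drawn along the local orientation (a cheap line-integral-convolution
#' stand-in).  Seeded Gaussian noise is added last.  The exact per-pixel
#' ground-truth orientation map is returned alongside.
#'
#' @param pattern `"stripes"`, `"aster"` (+1), `"half_plus"` (+1/2),
#'   `"half_minus"` (-1/2) or `"pair"` (two +1/2 defects).
#' @param size raster side in px (>= 64).
#' @param pixel_size um per pixel (metadata only; default 1).
#' @param angle stripe orientation (radians; default `pi/6` = 30 deg).
#' @param center defect center `(x, y)` in px (default: image center).
#' @param sep pair separation in px (pattern `"pair"`, default
#'   `size / 4`).
#' @param noise additive Gaussian noise s.d. relative to the signal s.d.
#'   (default 0).
#' @param seed RNG seed (segments + noise).
#' @param n_segments number of line segments (default `2 * size^2 / 9`).
#' @param seg_len segment length in px (default 9).
#' @return list with `image` (matrix in `[0, 1]` before noise),
#'   `orientation` (ground-truth angles mod pi), `pattern`, `pixel_size`,
#'   `center`.
#' @export
render_fiber_image <- function(pattern = c("stripes", "aster",
                                           "half_plus", "half_minus",
                                           "pair"),
                               size = 128, pixel_size = 1,
                               angle = pi / 6, center = NULL, sep = NULL,
                               noise = 0, seed = 1L, n_segments = NULL,
                               seg_len = 9) {
  pattern <- match.arg(pattern)
  if (size < 64) stop("raster size must be at least 64 px")
  if (is.null(center)) center <- c(size, size) / 2 + 0.5
  if (is.null(sep)) sep <- size / 4
  if (is.null(n_segments)) n_segments <- round(2 * size^2 / 9)
  orient_fun <- switch(pattern,
    stripes = function(x, y) rep(angle %% pi, length(x)),
    aster = function(x, y) atan2(y - center[2], x - center[1]) %% pi,
    half_plus = function(x, y)
      (0.5 * atan2(y - center[2], x - center[1])) %% pi,
    half_minus = function(x, y)
      (-0.5 * atan2(y - center[2], x - center[1])) %% pi,
    pair = function(x, y)
      (0.5 * atan2(y - center[2], x - center[1] + sep / 2) +
       0.5 * atan2(y - center[2], x - center[1] - sep / 2)) %% pi)
  seg <- with_seed(seed, {
    px <- stats::runif(n_segments, 1, size)
    py <- stats::runif(n_segments, 1, size)
    list(px = px, py = py,
         noise_mat = if (noise > 0)
           matrix(stats::rnorm(size * size), size, size) else NULL)
  })
  if (pattern == "stripes") {
    wavelength <- 8  # px between stripes
    xg <- matrix(rep(seq_len(size), each = size), size, size)  # x = col
    yg <- matrix(rep(seq_len(size), times = size), size, size) # y = row
    phase <- (-xg * sin(angle) + yg * cos(angle)) * 2 * pi / wavelength
    img <- 0.5 + 0.5 * sin(phase)
  } else if (pattern == "aster") {
    n_spokes <- 20  # resolvable spoke spacing down to r ~ 6 px
    xg <- matrix(rep(seq_len(size), each = size), size, size)
    yg <- matrix(rep(seq_len(size), times = size), size, size)
    az <- atan2(yg - center[2], xg - center[1])
    img <- sin(n_spokes * az / 2)^2
  } else {
    img <- matrix(0, size, size)
    th <- orient_fun(seg$px, seg$py)
    steps <- seq(-seg_len / 2, seg_len / 2, by = 0.5)
    for (s in steps) {
      xs <- seg$px + s * cos(th)
      ys <- seg$py + s * sin(th)
      i <- round(ys)
      j <- round(xs)
      okp <- i >= 1 & i <= size & j >= 1 & j <= size
      idx <- i[okp] + (j[okp] - 1L) * size
      tab <- tabulate(idx, nbins = size * size)
      img <- img + matrix(tab, size, size)
    }
    img <- gaussian_smooth2(img, 0.8)
    img <- img / max(img)
  }
  truth <- outer(seq_len(size), seq_len(size),
                 function(i, j) orient_fun(j, i))
  if (noise > 0)
    img <- img + noise * stats::sd(img) * seg$noise_mat
  list(image = img, orientation = truth, pattern = pattern,
       pixel_size = pixel_size, center = center)
}
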