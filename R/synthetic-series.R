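# Synthetic cell-area time series with a localized stretching event, for
# testing the strain-profile analysis in isolation (with known ground
# truth).

#' Generate a synthetic stretching-event area series
#'
#' Areas follow a baseline with one Gaussian-in-time bump whose per-cell
#' log amplitude is `amplitude` in the core (distance <= 1) and decays
#' exponentially with graph distance beyond it:
#' `s_d = amplitude * exp(-max(0, d - 1) / decay)`.  Multiplicative
#' log-normal noise emulates segmentation noise.
#'
#' @param n_cells number of cells.
#' @param n_frames number of frames.
#' @param distances per-cell graph distances from the event focus
#'   (length `n_cells`).
#' @param amplitude core log-strain amplitude (e.g. `log(2)`).
#' @param duration Gaussian bump width in frames (default 3).
#' @param peak_frame bump center (default mid-series).
#' @param noise log-normal noise s.d. (default 0).
#' @param seed RNG seed.
#' @param baseline baseline cell area (default 1).
#' @param decay distance decay constant in cells (default 1.5).
#' @return list with `areas` (n_frames x n_cells), and ground truth
#'   `truth`: `peak_frame`, `per_cell_strain`, `profile` (per-distance
#'   mean log strain at the peak).
#' @export
synthetic_event_series <- function(n_cells, n_frames, distances,
                                   amplitude, duration = 3,
                                   peak_frame = NULL, noise = 0,
                                   seed = 1L, baseline = 1,
                                   decay = 1.5) {
  stopifnot(length(distances) == n_cells)
  if (is.null(peak_frame)) peak_frame <- ceiling(n_frames / 2)
  d <- as.integer(distances)
  s_c <- amplitude * exp(-pmax(0, d - 1) / decay)
  tfac <- exp(-((seq_len(n_frames) - peak_frame)^2) / (2 * duration^2))
  log_areas <- log(baseline) + outer(tfac, s_c)
  if (noise > 0)
    log_areas <- log_areas + with_seed(seed, matrix(
      stats::rnorm(n_frames * n_cells, sd = noise), n_frames, n_cells))
  truth_profile <- tapply(s_c, d, mean)
  list(areas = exp(log_areas),
       truth = list(peak_frame = peak_frame, per_cell_strain = s_c,
                    profile = data.frame(
                      distance = as.integer(names(truth_profile)),
                      mean = as.numeric(truth_profile))))
}
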