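#' Rigid registration of an AOSLO stack to its first frame
#'
#' Estimates a per-frame integer-pixel rigid translation by FFT
#' cross-correlation against the first frame and shifts each frame back
#' (edge pixels replicated).  Integer-pixel correction leaves a residual
#' jitter of at most 0.5 px in each axis, below the scale of capillary
#' cross-sections at the default sampling.
#'
#' @param stack a \code{video_stack}.
#' @param max_shift_px largest plausible inter-frame displacement; the
#'   correlation peak is searched only within this window, which keeps the
#'   quasi-periodic photoreceptor mosaic (whose self-similarity creates
#'   lattice side-peaks) from capturing the registration.
#' @return the registered \code{video_stack}, with the estimated per-frame
#'   (row, col) shifts in attribute \code{"shifts"}.
#' @export
register_frames <- function(stack, max_shift_px = 10) {
  stopifnot(inherits(stack, "video_stack"))
  d <- dim(stack$frames)
  n <- d[1]; H <- d[2]; W <- d[3]
  ref <- stack$frames[1, , ]
  Fref <- Conj(fft(ref - mean(ref)))
  out <- stack
  shifts <- matrix(0, n, 2)
  m <- min(max_shift_px, floor(H / 2) - 1, floor(W / 2) - 1)
  win_r <- c(1:(m + 1), (H - m + 1):H)   # circular lags -m..m
  win_c <- c(1:(m + 1), (W - m + 1):W)
  for (f in 2:n) {
    img <- stack$frames[f, , ]
    cc <- Re(fft(fft(img - mean(img)) * Fref, inverse = TRUE))
    sub <- cc[win_r, win_c]
    pk <- arrayInd(which.max(sub), dim(sub))
    dr <- if (pk[1] <= m + 1) pk[1] - 1L else pk[1] - (2 * m + 2)
    dc <- if (pk[2] <= m + 1) pk[2] - 1L else pk[2] - (2 * m + 2)
    shifts[f, ] <- c(dr, dc)
    if (dr != 0 || dc != 0) {
      src_r <- pmin(pmax(seq_len(H) + dr, 1), H)
      src_c <- pmin(pmax(seq_len(W) + dc, 1), W)
      out$frames[f, , ] <- img[src_r, src_c]
    }
  }
  attr(out, "shifts") <- shifts
  out
}

#' Construct a perfusion map from an external image
#'
#' Wraps a non-negative 2-D ridge image (e.g. an externally computed
#' perfusion map) in the \code{perfusion_map} container used by
#' [trace_vessel()].
#'
#' @param map non-negative finite matrix.
#' @param px_per_deg pixel sampling density.
#' @param axial_length_mm axial length for metric scaling.
#' @param method short description of the map's origin.
#' @return a \code{perfusion_map}.
#' @export
perfusion_map <- function(map, px_per_deg, axial_length_mm,
                          method = "external") {
  map <- as.matrix(map)
  if (any(!is.finite(map)) || any(map < 0))
    stopf("perfusion map must be non-negative and finite")
  structure(list(map = map, method = method, fps = NA_real_,
                 field_deg = dim(map) / px_per_deg,
                 axial_length_mm = axial_length_mm,
                 px_per_deg = px_per_deg),
            class = "perfusion_map")
}

#' Motion-contrast perfusion map of an AOSLO stack
#'
#' Enhances perfused vessels by temporal statistics: each pixel scores the
#' temporal standard deviation of its intensity divided by its temporal mean
#' (plus a small \code{eps} guarding dark pixels), so pixels traversed by
#' moving blood cells stand out against the static photoreceptor background.
#' The map is normalised to [0, 1]; a temporally constant stack yields an
#' all-zero map.
#'
#' @param stack a \code{video_stack} with at least 8 frames (the temporal
#'   statistic is unstable below that).
#' @param eps stabiliser added to the temporal mean.
#' @param register if \code{TRUE} (default) run [register_frames()] first.
#' @return object of class \code{perfusion_map}: the \code{map} plus the
#'   acquisition metadata needed downstream.
#' @export
motion_contrast <- function(stack, eps = 1e-3, register = TRUE) {
  stopifnot(inherits(stack, "video_stack"))
  if (dim(stack$frames)[1] < 8) stopf("motion contrast needs >= 8 frames")
  if (register) stack <- register_frames(stack)
  n <- dim(stack$frames)[1]
  mu <- colMeans(stack$frames)            # frame axis is the first
  m2 <- colMeans(stack$frames^2)
  varr <- pmax(m2 - mu^2, 0) * n / (n - 1)
  mc <- sqrt(varr) / (mu + eps)
  mx <- max(mc)
  if (mx > 0) mc <- mc / mx
  structure(list(map = mc, method = "temporal sd / mean",
                 fps = stack$fps, field_deg = stack$field_deg,
                 axial_length_mm = stack$axial_length_mm,
                 px_per_deg = stack$px_per_deg),
            class = "perfusion_map")
}
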