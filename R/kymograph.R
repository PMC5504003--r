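#' Build the spatiotemporal (kymograph) image of a vessel
#'
#' Samples every frame of the stack along the traced vessel path at uniform
#' metric steps: row f of the kymograph is the bilinear-interpolated
#' intensity profile of frame f along the vessel, so moving blood columns
#' appear as slanted bands whose slope encodes velocity.
#'
#' @param stack a \code{video_stack} (register it first if it carries
#'   jitter; [measure_video()] does).
#' @param path a \code{vessel_path} from [trace_vessel()].
#' @param dx_um arc-length sampling step in micrometres; defaults to the
#'   pixel pitch implied by the path's metric scale.
#' @return object of class \code{kymograph}: \code{image} (n_frames x
#'   n_samples), \code{dt_s}, \code{dx_um}.
#' @export
build_kymograph <- function(stack, path, dx_um = NULL) {
  stopifnot(inherits(stack, "video_stack"), inherits(path, "vessel_path"))
  if (is.null(dx_um)) dx_um <- path$um_per_px
  if (dx_um <= 0) stopf("dx_um must be positive")
  d <- dim(stack$frames)
  H <- d[2]; W <- d[3]
  if (any(path$points[, 1] < 1 - 1e-6) || any(path$points[, 1] > H + 1e-6) ||
      any(path$points[, 2] < 1 - 1e-6) || any(path$points[, 2] > W + 1e-6))
    stopf("vessel path leaves frame bounds")
  arc <- path$arc_length_um
  s_new <- seq(0, arc[length(arc)], by = dx_um)
  r <- approx(arc, path$points[, 1], xout = s_new)$y
  c <- approx(arc, path$points[, 2], xout = s_new)$y
  # precompute bilinear corners once; reuse across frames
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  n <- d[1]
  img <- matrix(0, n, length(s_new))
  for (f in seq_len(n)) {
    m <- stack$frames[f, , ]
    img[f, ] <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      m[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  structure(list(image = img, dt_s = 1 / stack$fps, dx_um = dx_um),
            class = "kymograph")
}
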