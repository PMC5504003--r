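#' Configuration for the synthetic AOSLO capillary video generator
#'
#' Defaults emulate the acquisition protocol of a parafoveal AOSLO
#' examination: 2-second videos at 64 frames/s over a 1.4 x 2.8 degree field
#' focused on the photoreceptor layer, showing a single unbranched capillary
#' of the innermost parafoveal ring in which bright leukocyte plugs trailed
#' by dark erythrocyte aggregates move at capillary speeds (0.5-3 mm/s).
#'
#' @param n_frames number of frames (>= 2); default 128 = 2 s at 64 fps.
#' @param fps frame rate in frames/s (> 0).
#' @param field_deg field size, (height, width) in degrees.
#' @param px_per_deg pixel sampling density; the default 286 px/deg renders
#'   the full 1.4 x 2.8 degree field at roughly 400 x 800 px, i.e. about
#'   1 micrometre per pixel at emmetropic axial length.
#' @param axial_length_mm ocular axial length, used for angular-to-metric
#'   conversion.
#' @param vessel_waypoints n x 2 matrix of (row, col) pixel coordinates of
#'   the capillary centreline control points, ordered upstream to
#'   downstream; \code{NULL} draws a gently curved vessel spanning the field
#'   width.
#' @param true_velocity_mm_s ground-truth mean axial velocity (> 0).
#' @param pulsatility fractional sinusoidal velocity modulation amplitude in
#'   [0, 1); the instantaneous velocity is
#'   \code{v(t) = v * (1 + pulsatility * sin(2*pi*cardiac_hz*t))}.
#' @param cardiac_hz cardiac frequency of the pulsatile modulation (Hz).
#' @param plug_spacing_um mean leukocyte-to-leukocyte spacing along the
#'   vessel (micrometres).
#' @param plug_len_um length of the bright leukocyte plug.
#' @param tail_len_um length of the trailing dark erythrocyte aggregate.
#' @param vessel_sigma_px Gaussian cross-section radius of the rendered
#'   vessel (pixels); about 2.5 px for a ~7 micrometre capillary at the
#'   default sampling.
#' @param noise_sd additive Gaussian noise SD as a fraction of the mean
#'   background intensity.
#' @param jitter_px_sd per-frame rigid translational jitter SD (pixels).
#' @param seed RNG seed; identical configurations and seeds give
#'   bit-identical videos.
#' @return object of class \code{video_sim_config}.
#' @export
video_sim_config <- function(n_frames = 128L, fps = 64, field_deg = c(1.4, 2.8),
                             px_per_deg = 286, axial_length_mm = 24,
                             vessel_waypoints = NULL,
                             true_velocity_mm_s = 1.0, pulsatility = 0.1,
                             cardiac_hz = 1.2, plug_spacing_um = 100,
                             plug_len_um = 10, tail_len_um = 30,
                             vessel_sigma_px = 2.5, noise_sd = 0.05,
                             jitter_px_sd = 0.5, seed = 1L) {
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (fps <= 0) stopf("fps must be positive")
  if (true_velocity_mm_s <= 0) stopf("true_velocity_mm_s must be positive")
  if (pulsatility < 0 || pulsatility >= 1) stopf("pulsatility must lie in [0, 1)")
  dims <- c(round(field_deg[1] * px_per_deg), round(field_deg[2] * px_per_deg))
  if (is.null(vessel_waypoints)) {
    # gentle arc spanning the field width, vertically centred
    cc <- seq(6, dims[2] - 5, length.out = 9)
    rr <- dims[1] / 2 + 0.12 * dims[1] * sin(seq(0, pi, length.out = 9))
    vessel_waypoints <- cbind(rr, cc)
  }
  vessel_waypoints <- as.matrix(vessel_waypoints)
  if (nrow(vessel_waypoints) < 2) stopf("need at least 2 vessel waypoints")
  if (any(vessel_waypoints[, 1] < 1) || any(vessel_waypoints[, 1] > dims[1]) ||
      any(vessel_waypoints[, 2] < 1) || any(vessel_waypoints[, 2] > dims[2]))
    stopf("vessel waypoints outside frame bounds %d x %d", dims[1], dims[2])
  structure(list(n_frames = as.integer(n_frames), fps = fps,
                 field_deg = field_deg, px_per_deg = px_per_deg,
                 axial_length_mm = axial_length_mm, dims = dims,
                 vessel_waypoints = vessel_waypoints,
                 true_velocity_mm_s = true_velocity_mm_s,
                 pulsatility = pulsatility, cardiac_hz = cardiac_hz,
                 plug_spacing_um = plug_spacing_um, plug_len_um = plug_len_um,
                 tail_len_um = tail_len_um, vessel_sigma_px = vessel_sigma_px,
                 noise_sd = noise_sd, jitter_px_sd = jitter_px_sd,
                 seed = seed),
            class = "video_sim_config")
}

# densely resample a polyline at ~step px spacing; returns points and
# cumulative arc length in px
resample_polyline <- function(pts, step = 0.5) {
  seg <- sqrt(rowSums(diff(pts)^2))
  if (sum(seg) <= 0) stopf("zero-length centreline")
  arc <- c(0, cumsum(seg))
  s_new <- seq(0, arc[length(arc)], by = step)
  cbind(approx(arc, pts[, 1], xout = s_new)$y,
        approx(arc, pts[, 2], xout = s_new)$y)
}

# smoothstep shoulder: 0 below x0, 1 above x1, C1 ramp between
smoothstep <- function(x, x0, x1) {
  t <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  t * t * (3 - 2 * t)
}

# static photoreceptor-like background: quasi-regular bright-spot mosaic on a
# mid-grey base plus frozen speckle
make_background <- function(dims, spot_spacing = 4, spot_amp = 0.14,
                            base = 0.45) {
  H <- dims[1]; W <- dims[2]
  bg <- matrix(base, H, W)
  gr <- seq(1.5, H, by = spot_spacing)
  gc <- seq(1.5, W, by = spot_spacing)
  centers <- cbind(rep(gr, times = length(gc)), rep(gc, each = length(gr)))
  centers <- centers + matrix(runif(length(centers), -1, 1), ncol = 2)
  sig <- spot_spacing / 3.2
  rad <- ceiling(2.5 * sig)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  for (k in seq_len(nrow(off))) {
    r <- round(centers[, 1]) + off$dr[k]
    c <- round(centers[, 2]) + off$dc[k]
    keep <- r >= 1 & r <= H & c >= 1 & c <= W
    if (!any(keep)) next
    d2 <- (r[keep] - centers[keep, 1])^2 + (c[keep] - centers[keep, 2])^2
    idx <- cbind(r[keep], c[keep])
    bg[idx] <- bg[idx] + spot_amp * exp(-d2 / (2 * sig^2))
  }
  bg + matrix(rnorm(H * W, 0, 0.015), H, W)
}

# bilinear sample of matrix m at (row, col) positions; replicate edges
bilinear_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Simulate an AOSLO video of a single parafoveal capillary
#'
#' Renders a multi-frame grayscale stack in which bright leukocyte plugs,
#' each trailed by a dark erythrocyte aggregate, advance along a configured
#' capillary centreline over a static photoreceptor-like background, with
#' optional pulsatile velocity modulation, per-frame rigid jitter and
#' additive noise.  The exact per-frame arc-length position of every plug
#' front is returned as ground truth.
#'
#' @param cfg a [video_sim_config()].
#' @return list with components \code{stack} (class \code{video_stack}:
#'   \code{frames} array of dim (n_frames, rows, cols) with values in
#'   [0, 1], plus \code{fps}, \code{field_deg}, \code{axial_length_mm},
#'   \code{px_per_deg}) and \code{truth} (class \code{ground_truth}:
#'   \code{centreline} pixel coordinates, \code{arc_um}, \code{um_per_px},
#'   \code{per_frame_velocity_mm_s}, \code{particle_positions} matrix of
#'   plug-front arc positions in micrometres, particles x frames).
#' @export
simulate_capillary_video <- function(cfg = video_sim_config()) {
  stopifnot(inherits(cfg, "video_sim_config"))
  with_seed(cfg$seed, {
    H <- cfg$dims[1]; W <- cfg$dims[2]
    um_per_px <- mm_per_deg(cfg$axial_length_mm) / cfg$px_per_deg * 1000
    cl <- resample_polyline(cfg$vessel_waypoints, step = 0.5)
    arc_px <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
    arc_um <- arc_px * um_per_px
    L <- arc_um[length(arc_um)]

    bg <- make_background(cfg$dims)

    # pixels influenced by the vessel: for each, distance to centreline and
    # the arc-length of the nearest centreline sample
    rad <- ceiling(3 * cfg$vessel_sigma_px)
    off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    n_cl <- nrow(cl)
    pr <- rep(round(cl[, 1]), times = nrow(off)) +
      rep(off$dr, each = n_cl)
    pc <- rep(round(cl[, 2]), times = nrow(off)) +
      rep(off$dc, each = n_cl)
    ps <- rep(arc_um, times = nrow(off))
    d2 <- (pr - rep(cl[, 1], times = nrow(off)))^2 +
      (pc - rep(cl[, 2], times = nrow(off)))^2
    keep <- pr >= 1 & pr <= H & pc >= 1 & pc <= W & d2 <= (3 * cfg$vessel_sigma_px)^2
    pix <- data.frame(idx = (pc[keep] - 1) * H + pr[keep], s = ps[keep],
                      d2 = d2[keep])
    pix <- pix[order(pix$idx, pix$d2), ]
    pix <- pix[!duplicated(pix$idx), ]
    wgt <- exp(-pix$d2 / (2 * cfg$vessel_sigma_px^2))

    # kinematics: instantaneous velocity at each frame start, cumulative
    # displacement in micrometres
    dt <- 1 / cfg$fps
    t_f <- (seq_len(cfg$n_frames) - 1) * dt
    v_f <- cfg$true_velocity_mm_s *
      (1 + cfg$pulsatility * sin(2 * pi * cfg$cardiac_hz * t_f))
    disp_um <- c(0, cumsum(v_f * dt * 1000))[seq_len(cfg$n_frames)]
    travel <- disp_um[length(disp_um)]

    # plug train: fronts start upstream enough that plugs keep entering the
    # field over the whole recording; spacing jittered around the mean
    margin <- cfg$plug_len_um + cfg$tail_len_um + 10
    n_plugs <- ceiling((L + travel + 2 * margin) / cfg$plug_spacing_um) + 2
    gaps <- cfg$plug_spacing_um *
      pmax(0.4, 1 + 0.15 * rnorm(n_plugs))
    s0 <- (L + margin) - cumsum(gaps)
    particle_positions <- outer(s0, disp_um, "+")  # particles x frames

    shoulder <- 3  # um, smooth transition length
    base_lumen <- 0.35; plug_int <- 0.95; tail_int <- 0.08

    jit <- if (cfg$jitter_px_sd > 0)
      matrix(rnorm(2 * cfg$n_frames, 0, cfg$jitter_px_sd), ncol = 2)
    else matrix(0, cfg$n_frames, 2)
    jit[1, ] <- 0  # reference frame is unshifted

    noise_scale <- cfg$noise_sd * mean(bg)
    frames <- array(0, dim = c(cfg$n_frames, H, W))
    all_r <- rep(seq_len(H), times = W)
    all_c <- rep(seq_len(W), each = H)
    for (f in seq_len(cfg$n_frames)) {
      # vessel intensity profile along arc length at this frame
      prof <- rep(base_lumen, nrow(pix))
      fronts <- particle_positions[, f]
      vis <- which(fronts > -margin & fronts - cfg$plug_len_um -
                     cfg$tail_len_um - shoulder < L + margin)
      for (j in vis) {
        p <- fronts[j]
        # bright plug occupies [p - plug_len, p]
        w_plug <- smoothstep(pix$s, p - cfg$plug_len_um - shoulder,
                             p - cfg$plug_len_um) *
          (1 - smoothstep(pix$s, p, p + shoulder))
        # dark aggregate occupies [p - plug_len - tail_len, p - plug_len];
        # its anterior (downstream) end abuts the plug sharply
        w_tail <- smoothstep(pix$s, p - cfg$plug_len_um - cfg$tail_len_um -
                               shoulder,
                             p - cfg$plug_len_um - cfg$tail_len_um) *
          (1 - smoothstep(pix$s, p - cfg$plug_len_um - 0.5,
                          p - cfg$plug_len_um + 0.5))
        w_tail <- pmax(w_tail - w_plug, 0)
        prof <- prof + w_plug * (plug_int - base_lumen) +
          w_tail * (tail_int - base_lumen)
      }
      img <- bg
      img[pix$idx] <- (1 - wgt) * bg[pix$idx] + wgt * prof
      if (any(jit[f, ] != 0)) {
        img <- matrix(bilinear_sample(img, all_r + jit[f, 1],
                                      all_c + jit[f, 2]), H, W)
      }
      if (noise_scale > 0)
        img <- img + matrix(rnorm(H * W, 0, noise_scale), H, W)
      frames[f, , ] <- pmin(pmax(img, 0), 1)
    }

    stack <- structure(list(frames = frames, fps = cfg$fps,
                            field_deg = cfg$field_deg,
                            axial_length_mm = cfg$axial_length_mm,
                            px_per_deg = cfg$px_per_deg),
                       class = "video_stack")
    truth <- structure(list(centreline = cl, arc_um = arc_um,
                            um_per_px = um_per_px,
                            per_frame_velocity_mm_s = v_f,
                            particle_positions = particle_positions,
                            jitter_px = jit),
                       class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("AOSLO video stack: %d frames of %d x %d px, %.0f fps, %.1f x %.1f deg, AL %.2f mm\n",
              d[1], d[2], d[3], x$fps, x$field_deg[1], x$field_deg[2],
              x$axial_length_mm))
  invisible(x)
}
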