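# Small fixture builders shared across test files.  Everything is generated
# in code; no binary fixtures are stored.

# reduced field of view for fast pipeline tests: same pixel density, frame
# rate and optics as the full-size default, ~100 x 300 px
small_video_cfg <- function(...) {
  video_sim_config(field_deg = c(0.35, 1.05), ...)
}

# seed points for tracing: near the two ends of the ground-truth centreline
truth_seeds <- function(truth) {
  n <- nrow(truth$centreline)
  truth$centreline[c(3, n - 2), ]
}

# construct a clean kymograph with a plug/aggregate train advancing at
# u_um_per_frame; the geometry is the closed-form oracle for band tests.
# Bright plug: 10 um ahead of a 30 um dark aggregate; background 0.45.
# Plug spacing is deterministically irregular (golden-angle modulation):
# perfectly periodic trains are a stroboscopic degeneracy in which several
# velocities explain the same pattern, which no real capillary exhibits.
make_band_kymo <- function(u_um_per_frame, n_frames = 128, length_um = 300,
                           dx_um = 1, spacing_um = 100, fps = 64,
                           phase_um = 37, jitter_frac = 0.12) {
  s <- seq(0, length_um, by = dx_um)
  travel <- abs(u_um_per_frame) * (n_frames - 1)
  n_plugs <- ceiling((length_um + travel + 200) / spacing_um) + 2
  gaps <- spacing_um * (1 + jitter_frac * sin(2.399963 * seq_len(n_plugs)))
  fronts0 <- (length_um + 100) - cumsum(gaps) + phase_um
  img <- matrix(0.45, n_frames, length(s))
  for (f in seq_len(n_frames)) {
    fronts <- fronts0 + u_um_per_frame * (f - 1)
    row <- rep(0.45, length(s))
    for (p in fronts[fronts > -50 & fronts < length_um + 50]) {
      row[s > p - 10 & s <= p] <- 0.95                  # leukocyte plug
      row[s > p - 40 & s <= p - 10] <- 0.08             # erythrocyte tail
    }
    img[f, ] <- row
  }
  structure(list(image = img, dt_s = 1 / fps, dx_um = dx_um),
            class = "kymograph")
}

# binary dilation of a logical matrix by a square structuring element
dilate_mask <- function(mask, r) {
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (dr in -r:r) for (dc in -r:r) {
    rs <- pmin(pmax(seq_len(H) + dr, 1), H)
    cs <- pmin(pmax(seq_len(W) + dc, 1), W)
    out <- out | mask[rs, cs]
  }
  out
}

# 4-neighbour connected-component labelling of a logical matrix (oracle for
# structure-size checks; iterative label propagation)
label_components <- function(bw) {
  H <- nrow(bw); W <- ncol(bw)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(bw)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      r <- (v - 1L) %% H + 1L; c <- (v - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          w <- (cc - 1L) * H + rr
          if (bw[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
        }
      }
    }
  }
  lab
}

# hand-built band trace (for closed-form velocity identities)
manual_band_trace <- function(slopes_frames_per_um) {
  structure(list(bands = data.frame(slope_frames_per_um = slopes_frames_per_um,
                                    intercept_frames = 0,
                                    n_points = 10L, gof_mad_frames = 0),
                 points = list(), n_bands = length(slopes_frames_per_um),
                 edge_sign = 1),
            class = "band_trace")
}
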