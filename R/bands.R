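#' Detect erythrocyte-aggregate bands in a kymograph
#'
#' Moving blood columns trace slanted bands in the spatiotemporal image; the
#' anterior (downstream) end of each dark erythrocyte aggregate abuts the
#' bright leukocyte plug ahead of it and forms the sharpest intensity
#' transition, the feature conventionally traced by hand.  The detector:
#' \enumerate{
#'   \item removes the static background profile (per-column median over
#'     frames) and smooths each row;
#'   \item localises candidate edges per row as strong extrema of the
#'     spatial gradient (bright-to-dark sign chosen automatically -- it
#'     depends on the flow direction relative to the path orientation);
#'   \item finds the common band slope by a Hough-style orientation search:
#'     for each trial slope the candidates' row-intercepts are binned and
#'     the concentration of the histogram scored;
#'   \item clusters candidates by intercept at the best slope and fits each
#'     cluster with a robust least-absolute-deviation line.
#' }
#' An empty kymograph yields \code{n_bands = 0} (a flag, not an error).
#'
#' @param kymo a \code{kymograph}.
#' @param v_range_mm_s plausible speed range searched, in mm/s.
#' @param min_support minimum candidate points per band (>= 3).
#' @param grad_k threshold on the gradient magnitude, in robust SDs.
#' @param peel_halfwidth_um half-width (micrometres of arc length) of the
#'   intercept window assigned to one band during peeling; should be below
#'   half the plug spacing and above the edge-localisation noise.
#' @return object of class \code{band_trace}: \code{bands} data.frame with
#'   \code{slope_frames_per_um}, \code{intercept_frames}, \code{n_points},
#'   \code{gof_mad_frames}; \code{points} list of per-band inlier
#'   (frame, s_um) tables; \code{n_bands}; \code{edge_sign}.
#' @export
detect_bands <- function(kymo, v_range_mm_s = c(0.2, 8), min_support = 3,
                         grad_k = 6, peel_halfwidth_um = 12) {
  stopifnot(inherits(kymo, "kymograph"))
  D <- kymo$image
  n_f <- nrow(D); n_s <- ncol(D)
  empty <- structure(list(bands = data.frame(slope_frames_per_um = numeric(),
                                             intercept_frames = numeric(),
                                             n_points = integer(),
                                             gof_mad_frames = numeric()),
                          points = list(), n_bands = 0L, edge_sign = NA),
                     class = "band_trace")
  if (n_s < 5 || n_f < 3) return(empty)

  R <- sweep(D, 2, apply(D, 2, median))
  # smooth rows with a small Gaussian (~2 um), then spatial gradient per um
  sig_bins <- max(1, 2 / kymo$dx_um)
  kk <- seq(-ceiling(3 * sig_bins), ceiling(3 * sig_bins))
  kern <- exp(-kk^2 / (2 * sig_bins^2)); kern <- kern / sum(kern)
  S <- t(apply(R, 1, function(row)
    stats::filter(c(rev(row[seq_along(kk)]), row, rev(row)[seq_along(kk)]),
                  kern, sides = 2)[length(kk) + seq_along(row)]))
  G <- t(apply(S, 1, function(row)
    c(0, (row[-(1:2)] - row[seq_len(length(row) - 2)]) / 2, 0))) / kymo$dx_um

  thr <- grad_k * mad(as.vector(G), center = 0)
  gmax <- max(abs(G))
  # noise-free images have mad ~ 0; fall back to a fraction of the peak
  if (!is.finite(thr) || thr < 1e-3 * gmax) thr <- 0.25 * gmax
  if (!is.finite(thr) || thr <= 0) return(empty)
  cand_of_sign <- function(sgn) {
    g <- G * sgn                      # look for strong positive extrema
    inner <- g[, 2:(n_s - 1), drop = FALSE]
    is_pk <- inner > g[, 1:(n_s - 2), drop = FALSE] &
      inner >= g[, 3:n_s, drop = FALSE] & inner > thr
    idx <- which(is_pk, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(frame = idx[, 1], s_um = (idx[, 2] + 1 - 1) * kymo$dx_um,
               mag = inner[idx])
  }

  # All intercept computations run in arc-length units (micrometres): the
  # candidate localisation noise lives along s, so thresholds expressed in
  # micrometres are invariant to the band steepness.  A trial advance u
  # (um/frame, signed) maps candidate (frame, s) to intercept b = s - u*f.
  dt <- kymo$dt_s
  u_lim <- sort(v_range_mm_s * 1000 * dt)   # um advanced per frame
  u_vals <- exp(seq(log(u_lim[1]), log(u_lim[2]), length.out = 80))
  u_grid <- c(u_vals, -u_vals)              # both flow directions
  L_s <- (n_s - 1) * kymo$dx_um

  hough_score <- function(cand, u_trials, binwidth) {
    vapply(u_trials, function(u) {
      b <- cand$s_um - u * cand$frame
      tab <- tabulate(as.integer(floor((b - min(b)) / binwidth)) + 1L)
      sum(tab^2) / length(b)
    }, numeric(1))
  }

  # peel bands off one at a time at a fixed trial advance: take the
  # strongest intercept-histogram peak, fit its neighbourhood robustly,
  # remove, repeat.  A band is only accepted when its inliers trace a
  # near-continuous run of rows: true bands are traced frame after frame,
  # whereas "aliased" orientations (an artefact of the quasi-periodic plug
  # train) collect candidates only every few rows or as loose smears.
  peel_bands <- function(cand, u0) {
    b <- cand$s_um - u0 * cand$frame
    remaining <- rep(TRUE, nrow(cand))
    bands <- list(); pts <- list(); used <- integer()
    # a steep band crosses the field in few rows and pulsatile modulation
    # drifts its intercept by a fraction of the advance per row, so the
    # histogram resolution and capture window scale with |u0|
    bw <- max(2, 0.08 * abs(u0))
    halfwidth <- max(peel_halfwidth_um, 0.3 * abs(u0))
    for (iter in seq_len(100)) {
      if (sum(remaining) < min_support) break
      br <- b[remaining]
      bins <- floor((br - min(b)) / bw)
      tab <- tabulate(bins + 1L)
      peak <- which.max(tab)
      if (tab[peak] < min_support) break
      center <- min(b) + (peak - 0.5) * bw
      sel <- which(remaining & abs(b - center) <= halfwidth)
      remaining[sel] <- FALSE
      cc <- cand[sel, , drop = FALSE]
      if (nrow(cc) < min_support || length(unique(cc$frame)) < 3) next
      fit <- lad_fit(cc$frame, cc$s_um)     # s = a + u * frame
      resid <- cc$s_um - fit$a - fit$b * cc$frame
      keep <- abs(resid) <= pmax(2.5 * mad(resid, center = 0), 4)
      if (sum(keep) < min_support || length(unique(cc$frame[keep])) < 3) next
      fit <- lad_fit(cc$frame[keep], cc$s_um[keep])
      if (abs(fit$b) < 0.5 * abs(u0) || abs(fit$b) > 2 * abs(u0)) next
      resid <- cc$s_um[keep] - fit$a - fit$b * cc$frame[keep]
      gof <- mad(resid, center = 0)
      if (gof > 8) next
      rows <- unique(cc$frame[keep])
      if (length(rows) < 0.67 * (diff(range(rows)) + 1)) next
      if (diff(range(cc$s_um[keep])) < min(0.25 * L_s, 10 * kymo$dx_um)) next
      bands[[length(bands) + 1]] <-
        data.frame(slope_frames_per_um = 1 / fit$b,
                   intercept_frames = -fit$a / fit$b,
                   n_points = sum(keep), gof_mad_frames = gof / abs(fit$b))
      pts[[length(pts) + 1]] <- cc[keep, c("frame", "s_um")]
      used <- c(used, sel[keep])
    }
    list(bands = bands, pts = pts, used = used,
         support = sum(vapply(bands, function(x) x$n_points, numeric(1))))
  }

  # one orientation-search pass over a candidate pool: refine every local
  # maximum of the coarse Hough score at fine bin width, peel bands at the
  # highest-scoring refined orientations, return the orientation explaining
  # the most contiguous-band support
  n_half <- length(u_vals)
  search_pass <- function(cand, trials) {
    sc <- hough_score(cand, trials, binwidth = max(0.05 * L_s, 2))
    half <- sum(trials > 0)
    is_locmax <- vapply(seq_along(trials), function(i) {
      j <- if (trials[i] > 0) i else i - half
      lo <- if (j > 1) sc[i - 1] else -Inf
      hi <- if (j < half && i < length(trials)) sc[i + 1] else -Inf
      sc[i] >= lo && sc[i] >= hi
    }, logical(1))
    refined <- lapply(which(is_locmax), function(i) {
      fine <- trials[i] * seq(0.93, 1.07, length.out = 29)
      fsc <- hough_score(cand, fine, binwidth = 2)
      list(u = fine[which.max(fsc)], score = max(fsc))
    })
    if (!length(refined)) return(NULL)
    ru <- vapply(refined, `[[`, numeric(1), "u")
    rs <- vapply(refined, `[[`, numeric(1), "score")
    keep <- !duplicated(round(log(abs(ru)) / 0.02) * sign(ru))
    ru <- ru[keep]; rs <- rs[keep]
    best <- NULL
    for (i in order(-rs)[seq_len(min(10, length(ru)))]) {
      if (rs[i] < 1.2) next   # no coherent structure at this orientation
      peeled <- peel_bands(cand, ru[i])
      if (peeled$support == 0) next
      if (is.null(best) || peeled$support > best$support ||
          (peeled$support == best$support && rs[i] > best$score)) {
        best <- c(peeled, list(score = rs[i], u = ru[i]))
      }
    }
    best
  }

  # pulsatile flow spreads band slopes around the mean advance, and a single
  # orientation only collects the bands near its own speed; so peel in
  # passes -- accept the dominant orientation's bands, drop their
  # candidates, and re-search the remainder (same gradient sign and flow
  # direction, speeds within a factor ~1.8 of the first pass) until nothing
  # coherent remains
  bands <- list(); pts <- list()
  pool <- NULL; sel_dir <- NULL
  for (pass in seq_len(8)) {
    best <- NULL; best_sign <- NA
    if (pass == 1) {
      for (sgn in c(1, -1)) {
        cand <- cand_of_sign(sgn)
        if (is.null(cand) || nrow(cand) < min_support) next
        if (nrow(cand) > 5000) cand <- cand[order(-cand$mag)[1:5000], ]
        res <- search_pass(cand, u_grid)
        if (!is.null(res) && (is.null(best) || res$support > best$support)) {
          best <- res; best_sign <- sgn; pool_cand <- cand
        }
      }
      if (is.null(best)) return(empty)
      edge_sign <- best_sign
      u_first <- best$u
      pool <- pool_cand
    } else {
      if (nrow(pool) < max(4, min_support)) break
      trials <- u_grid[sign(u_grid) == sign(u_first) &
                         abs(u_grid) >= abs(u_first) / 1.8 &
                         abs(u_grid) <= abs(u_first) * 1.8]
      if (length(trials) < 2) break
      best <- search_pass(pool, trials)
      if (is.null(best) || best$support == 0) break
    }
    bands <- c(bands, best$bands)
    pts <- c(pts, best$pts)
    pool <- pool[-best$used, , drop = FALSE]
  }
  if (!length(bands)) return(empty)
  bands <- do.call(rbind, bands)
  best <- list(sign = edge_sign)
  # uniform sign within one kymograph: keep the majority direction, then
  # trim gross outliers relative to the median slope magnitude
  maj <- sign(median(sign(bands$slope_frames_per_um)))
  if (maj == 0) maj <- sign(bands$slope_frames_per_um[1])
  ok <- sign(bands$slope_frames_per_um) == maj
  med <- median(abs(bands$slope_frames_per_um[ok]))
  ok <- ok & abs(bands$slope_frames_per_um) >= 0.4 * med &
    abs(bands$slope_frames_per_um) <= 2.5 * med
  if (!any(ok)) return(empty)
  structure(list(bands = bands[ok, , drop = FALSE], points = pts[ok],
                 n_bands = sum(ok), edge_sign = best$sign),
            class = "band_trace")
}

# least-absolute-deviation straight line y = a + b x via IRLS
lad_fit <- function(x, y, iters = 15) {
  w <- rep(1, length(x))
  a <- 0; b <- 0
  for (i in seq_len(iters)) {
    sw <- sum(w)
    xb <- sum(w * x) / sw; yb <- sum(w * y) / sw
    vx <- sum(w * (x - xb)^2)
    b <- if (vx > 0) sum(w * (x - xb) * (y - yb)) / vx else 0
    a <- yb - b * xb
    r <- abs(y - a - b * x)
    w <- 1 / pmax(r, 1e-6)
  }
  list(a = a, b = b)
}

#' Estimate blood-flow velocity from detected kymograph bands
#'
#' The reciprocal of a band's slope (frames per micrometre) is the distance
#' the blood column advances per frame; divided by the frame interval it is
#' the flow speed.  Per-band speeds are averaged without weights; the
#' reported velocity is unsigned.
#'
#' @param bands a \code{band_trace}.
#' @param kymo the \code{kymograph} the bands were detected in (provides
#'   \code{dt_s}).
#' @return object of class \code{velocity_estimate}: \code{velocity_mm_s}
#'   (mean over bands; \code{NA} with \code{n_bands = 0} when nothing was
#'   measurable -- distinct from a zero velocity), \code{per_band_mm_s},
#'   \code{sd_mm_s}, \code{n_bands}.
#' @export
estimate_velocity <- function(bands, kymo) {
  stopifnot(inherits(bands, "band_trace"), inherits(kymo, "kymograph"))
  if (bands$n_bands == 0L) {
    return(structure(list(velocity_mm_s = NA_real_,
                          per_band_mm_s = numeric(0), sd_mm_s = NA_real_,
                          n_bands = 0L),
                     class = "velocity_estimate"))
  }
  per_band <- 1 / (abs(bands$bands$slope_frames_per_um) * kymo$dt_s) / 1000
  structure(list(velocity_mm_s = mean(per_band), per_band_mm_s = per_band,
                 sd_mm_s = if (length(per_band) > 1) sd(per_band) else NA_real_,
                 n_bands = bands$n_bands),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  if (x$n_bands == 0L) cat("pBFV: no measurable bands\n")
  else cat(sprintf("pBFV %.3f mm/s (SD %.3f, %d bands)\n", x$velocity_mm_s,
                   x$sd_mm_s, x$n_bands))
  invisible(x)
}

#' Full velocimetry pipeline for one AOSLO video
#'
#' Register -> motion-contrast perfusion map -> vessel trace through the
#' seed points -> kymograph -> band detection -> velocity estimate.
#'
#' @param stack a \code{video_stack}.
#' @param seed_points matrix of (row, col) seed coordinates on the target
#'   vessel, upstream first.
#' @param dx_um kymograph sampling step (default: pixel pitch).
#' @param ... passed to [detect_bands()].
#' @return list with \code{map}, \code{path}, \code{kymo}, \code{bands},
#'   \code{estimate}.
#' @export
measure_video <- function(stack, seed_points, dx_um = NULL, ...) {
  reg <- register_frames(stack)
  map <- motion_contrast(reg, register = FALSE)
  path <- trace_vessel(map, seed_points)
  kymo <- build_kymograph(reg, path, dx_um = dx_um)
  bands <- detect_bands(kymo, ...)
  est <- estimate_velocity(bands, kymo)
  list(map = map, path = path, kymo = kymo, bands = bands, estimate = est)
}
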