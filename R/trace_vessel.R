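#' Trace a capillary centreline through a motion-contrast map
#'
#' Finds a subpixel path through the supplied seed points that follows the
#' high-contrast ridge of a perfusion map.  Consecutive seed pairs are
#' connected by a minimum-cost path (8-neighbour lattice, cost inversely
#' proportional to map value, computed with igraph); the pixel path is then
#' refined to subpixel accuracy by intensity-weighted centroids along the
#' local normal, smoothed, and assigned metric arc length through
#' [deg_to_mm()].
#'
#' @param map a \code{perfusion_map} from [motion_contrast()].
#' @param seed_points matrix (>= 2 rows) of (row, col) pixel coordinates on
#'   the vessel, ordered upstream to downstream (point 1 = upstream end).
#' @param axial_length_mm axial length for metric scaling; defaults to the
#'   map's metadata.
#' @param seed_threshold minimum normalised map value at a seed; seeds on
#'   background are rejected.
#' @param margin_px half-width of the search corridor around the seeds.
#' @return object of class \code{vessel_path}: \code{points} (n x 2 subpixel
#'   row/col), \code{arc_length_um} (strictly increasing, from 0),
#'   \code{um_per_px}.
#' @export
trace_vessel <- function(map, seed_points, axial_length_mm = NULL,
                         seed_threshold = 0.1, margin_px = 20) {
  stopifnot(inherits(map, "perfusion_map"))
  if (is.null(axial_length_mm)) axial_length_mm <- map$axial_length_mm
  seed_points <- as.matrix(seed_points)
  if (nrow(seed_points) < 2) stopf("need at least 2 seed points")
  if (any(duplicated(round(seed_points))))
    stopf("seed points must be distinct")
  M <- map$map
  H <- nrow(M); W <- ncol(M)
  sr <- round(seed_points[, 1]); sc <- round(seed_points[, 2])
  if (any(sr < 1 | sr > H | sc < 1 | sc > W))
    stopf("seed point outside map bounds")
  v_at_seed <- M[cbind(sr, sc)]
  if (any(v_at_seed < seed_threshold))
    stopf("seed point on background (map value %.3f < %.3f)",
          min(v_at_seed), seed_threshold)

  # restrict the lattice to a corridor around the seeds
  r0 <- max(1, min(sr) - margin_px); r1 <- min(H, max(sr) + margin_px)
  c0 <- max(1, min(sc) - margin_px); c1 <- min(W, max(sc) + margin_px)
  sub <- M[r0:r1, c0:c1]
  nh <- nrow(sub); nw <- ncol(sub)
  id <- function(r, c) (c - 1L) * nh + r
  # 8-neighbour edges; weight = geometric length x mean inverse map value
  cost <- 1 / (sub + 0.01)
  edges <- list(); wts <- list()
  steps <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                c(1L, -1L, sqrt(2)))
  k <- 0
  for (st in steps) {
    dr <- st[1]; dc <- st[2]; len <- st[3]
    r_from <- if (dr >= 0) seq_len(nh - dr) else seq_len(nh + dr) - dr
    c_from <- if (dc >= 0) seq_len(nw - dc) else seq_len(nw + dc) - dc
    from <- as.vector(outer(r_from, c_from, id))
    to <- as.vector(outer(r_from + dr, c_from + dc, id))
    w <- len * (cost[cbind(rep(r_from, length(c_from)),
                           rep(c_from, each = length(r_from)))] +
                cost[cbind(rep(r_from + dr, length(c_from)),
                           rep(c_from + dc, each = length(r_from)))]) / 2
    k <- k + 1
    edges[[k]] <- rbind(from, to)
    wts[[k]] <- w
  }
  g <- igraph::make_graph(as.vector(do.call(cbind, edges)),
                          n = nh * nw, directed = FALSE)
  igraph::E(g)$weight <- unlist(wts)

  path_px <- NULL
  for (i in seq_len(nrow(seed_points) - 1)) {
    vfrom <- id(sr[i] - r0 + 1L, sc[i] - c0 + 1L)
    vto <- id(sr[i + 1] - r0 + 1L, sc[i + 1] - c0 + 1L)
    sp <- igraph::shortest_paths(g, from = vfrom, to = vto,
                                 output = "vpath")$vpath[[1]]
    v <- as.integer(sp)
    pts <- cbind((v - 1L) %% nh + 1L + r0 - 1L,
                 (v - 1L) %/% nh + 1L + c0 - 1L)
    path_px <- if (is.null(path_px)) pts else rbind(path_px, pts[-1, , drop = FALSE])
  }

  pts <- refine_subpixel(M, smooth_path(path_px))
  pts <- smooth_path(pts, k = 5)
  # drop consecutive duplicates, then metric arc length
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  um_per_px <- mm_per_deg(axial_length_mm) /
    (if (is.null(map$px_per_deg)) stopf("map lacks px_per_deg metadata")
     else map$px_per_deg) * 1000
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2)))) * um_per_px
  structure(list(points = pts, arc_length_um = arc, um_per_px = um_per_px,
                 axial_length_mm = axial_length_mm),
            class = "vessel_path")
}

# moving-average smoothing of a polyline, endpoints kept
smooth_path <- function(pts, k = 5) {
  if (nrow(pts) <= k) return(pts)
  sm <- apply(pts, 2, function(x) stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm[, 1]), ] <- pts[is.na(sm[, 1]), ]
  sm
}

# shift each path point to the intensity-weighted centroid along its normal
refine_subpixel <- function(M, pts, halfwidth = 3, step = 0.5, max_shift = 2) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  tang <- rbind(pts[2, ] - pts[1, ], (pts[-(1:2), , drop = FALSE] -
                pts[1:(n - 2), , drop = FALSE]) / 2,
                pts[n, ] - pts[n - 1, ])
  tl <- sqrt(rowSums(tang^2)); tl[tl == 0] <- 1
  nrm <- cbind(-tang[, 2] / tl, tang[, 1] / tl)
  offs <- seq(-halfwidth, halfwidth, by = step)
  prof <- sapply(offs, function(o)
    bilinear_sample(M, pts[, 1] + o * nrm[, 1], pts[, 2] + o * nrm[, 2]))
  w <- prof^2
  shift <- as.vector((w %*% offs) / pmax(rowSums(w), 1e-12))
  shift <- pmin(pmax(shift, -max_shift), max_shift)
  pts + shift * nrm
}
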