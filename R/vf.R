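#' The 24-2 standard automated perimetry point grid
#'
#' Returns the 54 test locations of the Humphrey 24-2 pattern in a fixed,
#' documented order (rows from superior to inferior, within a row nasal to
#' temporal).  Coordinates are degrees of visual field with +x temporal and
#' +y superior (right-eye convention); points are spaced 6 degrees apart.
#'
#' Conventions used throughout the package (defined here and only here):
#' \itemize{
#'   \item \emph{blind spot}: the two points at (15, +/-3), excluded from
#'     cluster analysis;
#'   \item \emph{edge points}: the outermost superior and inferior rows
#'     (y = +/-21) and the two nasal-most points (x = -27) -- clusters must
#'     consist of non-edge points;
#'   \item \emph{adjacency}: 8-neighbour, i.e. two points are adjacent when
#'     both coordinates differ by at most 6 degrees (and they are distinct);
#'   \item \emph{hemifield}: sign of y; clusters may not cross the horizontal
#'     meridian.
#' }
#'
#' @return data.frame with columns \code{x}, \code{y}, \code{blind_spot},
#'   \code{edge}, \code{hemifield} (+1 superior / -1 inferior); 54 rows.
#' @export
vf_grid_242 <- function() {
  rows <- list(c(21, 9), c(15, 15), c(9, 21), c(3, 27),
               c(-3, 27), c(-9, 21), c(-15, 15), c(-21, 9))
  pts <- do.call(rbind, lapply(rows, function(r) {
    y <- r[1]
    xmax <- if (abs(y) == 3) 21 else r[2]
    xmin <- -r[2]
    data.frame(x = seq(xmin, xmax, by = 6), y = y)
  }))
  pts$blind_spot <- pts$x == 15 & abs(pts$y) == 3
  pts$edge <- abs(pts$y) == 21 | pts$x == -27
  pts$hemifield <- sign(pts$y)
  rownames(pts) <- NULL
  pts
}

# 54x54 logical adjacency matrix under the 8-neighbour rule
vf_adjacency <- function(grid = vf_grid_242()) {
  dx <- abs(outer(grid$x, grid$x, "-"))
  dy <- abs(outer(grid$y, grid$y, "-"))
  adj <- dx <= 6 & dy <= 6 & (dx + dy > 0)
  adj
}

#' Construct a synthetic 24-2 visual-field test
#'
#' Builds a \code{vf_test} object carrying a 54-point pattern-deviation
#' probability map with exactly the requested depressed points, reliability
#' indices, and the glaucoma-hemifield-test / pattern-standard-deviation
#' flags.  Probability categories are coded 0 = not depressed (P >= 5%),
#' 1 = P < 5%, 2 = P < 2%, 3 = P < 1%, 4 = P < 0.5%.
#'
#' @param points \code{NULL} (fully normal map) or a data.frame with columns
#'   \code{x}, \code{y}, \code{level} giving the depressed locations; every
#'   (x, y) must be a 24-2 grid point and \code{level} in 1:4.
#' @param ght_outside_normal logical flag, glaucoma hemifield test outside
#'   normal limits (consumed as an input, never computed).
#' @param psd_prob_lt_5pct logical flag, PSD probability < 5\%.
#' @param fixation_loss,false_pos,false_neg reliability rates in [0, 1].
#' @return object of class \code{vf_test}.
#' @export
simulate_vf_test <- function(points = NULL, ght_outside_normal = FALSE,
                             psd_prob_lt_5pct = FALSE, fixation_loss = 0,
                             false_pos = 0, false_neg = 0) {
  grid <- vf_grid_242()
  pd <- integer(nrow(grid))
  if (!is.null(points) && nrow(points) > 0) {
    stopifnot(all(c("x", "y", "level") %in% names(points)))
    idx <- match(paste(points$x, points$y), paste(grid$x, grid$y))
    if (anyNA(idx))
      stopf("point (%s) is not on the 24-2 grid",
            paste(points$x[which(is.na(idx))[1]],
                  points$y[which(is.na(idx))[1]], sep = ", "))
    if (any(points$level < 1 | points$level > 4))
      stopf("level must be in 1:4")
    pd[idx] <- as.integer(points$level)
  }
  rates <- c(fixation_loss, false_pos, false_neg)
  if (any(rates < 0 | rates > 1)) stopf("reliability rates must lie in [0, 1]")
  structure(list(pd_prob = pd,
                 ght_outside_normal = isTRUE(ght_outside_normal),
                 psd_prob_lt_5pct = isTRUE(psd_prob_lt_5pct),
                 fixation_loss = fixation_loss, false_pos = false_pos,
                 false_neg = false_neg),
            class = "vf_test")
}

#' Classify a 24-2 visual field as glaucomatous, normal or unreliable
#'
#' Applies Anderson-Patella style criteria to a pattern-deviation probability
#' map.  The test is \code{"unreliable"} when fixation loss, false-positive
#' or false-negative rate exceeds 15\%.  Otherwise it is
#' \code{"glaucomatous"} when any of the following holds:
#' \itemize{
#'   \item glaucoma hemifield test outside normal limits;
#'   \item pattern standard deviation probability < 5\%;
#'   \item a cluster of three or more adjacent non-edge, non-blind-spot
#'     points, all within one hemifield (not crossing the horizontal
#'     meridian), all depressed at P < 5\% with at least one at P < 1\%.
#' }
#' Adjacency, edge points and hemifields follow the conventions of
#' [vf_grid_242()].
#'
#' @param vf a \code{vf_test}.
#' @return one of \code{"glaucomatous"}, \code{"normal"},
#'   \code{"unreliable"}.
#' @export
classify_vf_glaucomatous <- function(vf) {
  stopifnot(inherits(vf, "vf_test"))
  if (length(vf$pd_prob) != 54L) stopf("pd_prob must have exactly 54 points")
  if (vf$fixation_loss > 0.15 || vf$false_pos > 0.15 || vf$false_neg > 0.15)
    return("unreliable")
  if (vf$ght_outside_normal || vf$psd_prob_lt_5pct) return("glaucomatous")
  if (vf_has_cluster(vf$pd_prob)) return("glaucomatous") else return("normal")
}

# cluster rule: connected component (8-neighbour) of >=3 eligible depressed
# points within one hemifield containing at least one P<1% point
vf_has_cluster <- function(pd_prob, grid = vf_grid_242()) {
  adj <- vf_adjacency(grid)
  for (h in c(1, -1)) {
    elig <- which(pd_prob >= 1L & !grid$edge & !grid$blind_spot &
                    grid$hemifield == h)
    if (length(elig) < 3) next
    sub <- adj[elig, elig, drop = FALSE]
    comp <- components_from_adjacency(sub)
    for (k in seq_len(max(comp))) {
      members <- elig[comp == k]
      if (length(members) >= 3 && any(pd_prob[members] >= 3L)) return(TRUE)
    }
  }
  FALSE
}

# connected-component labels from a logical adjacency matrix (BFS)
components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}
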