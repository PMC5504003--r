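# Brute-force oracle for the visual-field cluster criterion.
#
# A qualifying cluster (connected set of >= 3 eligible depressed points, one
# at P < 1%) exists iff some *triple* of eligible depressed points is
# connected, lies in one hemifield and contains a P < 1% point: any larger
# component containing a P < 1% point q yields such a triple by taking q and
# two neighbours on a BFS tree from q.  The oracle therefore enumerates all
# triples of depressed points exhaustively, independent of the package's
# component labelling.
oracle_classify_vf <- function(vf) {
  grid <- vf_grid_242()
  if (vf$fixation_loss > 0.15 || vf$false_pos > 0.15 || vf$false_neg > 0.15)
    return("unreliable")
  if (vf$ght_outside_normal || vf$psd_prob_lt_5pct) return("glaucomatous")
  dep <- which(vf$pd_prob >= 1L & !grid$edge & !grid$blind_spot)
  if (length(dep) >= 3) {
    trips <- utils::combn(dep, 3)
    for (k in seq_len(ncol(trips))) {
      t3 <- trips[, k]
      if (length(unique(grid$hemifield[t3])) > 1) next
      if (!any(vf$pd_prob[t3] >= 3L)) next
      adj <- function(i, j) abs(grid$x[i] - grid$x[j]) <= 6 &&
        abs(grid$y[i] - grid$y[j]) <= 6
      n_adj <- adj(t3[1], t3[2]) + adj(t3[1], t3[3]) + adj(t3[2], t3[3])
      if (n_adj >= 2) return("glaucomatous")
    }
  }
  "normal"
}

# random 24-2 map generator covering edge points, meridian-crossing clusters
# and unreliable indices
random_vf <- function() {
  grid <- vf_grid_242()
  n_dep <- sample(0:12, 1)
  pts <- NULL
  if (n_dep > 0) {
    if (runif(1) < 0.5) {
      # clumped: grow from a random start to likely form clusters
      start <- sample(54, 1)
      idx <- start
      while (length(idx) < n_dep) {
        anchor <- idx[sample.int(length(idx), 1)]
        nb <- which(abs(grid$x - grid$x[anchor]) <= 6 &
                      abs(grid$y - grid$y[anchor]) <= 6)
        idx <- unique(c(idx, nb[sample.int(length(nb), 1)]))
      }
    } else {
      idx <- sample(54, n_dep)
    }
    pts <- data.frame(x = grid$x[idx], y = grid$y[idx],
                      level = sample(1:4, length(idx), replace = TRUE,
                                     prob = c(0.45, 0.2, 0.2, 0.15)))
  }
  simulate_vf_test(points = pts,
                   ght_outside_normal = runif(1) < 0.1,
                   psd_prob_lt_5pct = runif(1) < 0.1,
                   fixation_loss = sample(c(0, 0.1, 0.15, 0.2), 1,
                                          prob = c(0.55, 0.2, 0.1, 0.15)),
                   false_pos = sample(c(0, 0.16), 1, prob = c(0.9, 0.1)),
                   false_neg = sample(c(0, 0.3), 1, prob = c(0.9, 0.1)))
}
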