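# Shared fixture builders: analytic ROIs rasterized on a pixel grid, used
# to check the segregation statistics against closed-form geometry.

# Dense rasterization of a uniform disk of radius R split into the named
# two-channel arrangement. Returns an aggregate_roi.
make_disk_roi <- function(R = 100, arrangement = c("identical", "bisected", "engulfed"),
                          core_frac = 0.5, pad = 10) {
  arrangement <- match.arg(arrangement)
  n <- 2 * (R + pad) + 1
  ctr <- (n - 1) / 2
  rows <- matrix(0:(n - 1), n, n)
  cols <- t(rows)
  r2 <- (rows - ctr)^2 + (cols - ctr)^2
  disk <- r2 <= R^2
  if (arrangement == "identical") {
    red <- disk * 1; grn <- disk * 1
  } else if (arrangement == "bisected") {
    red <- (disk & cols < ctr) * 1
    grn <- (disk & cols >= ctr) * 1
  } else {
    core <- r2 <= (core_frac * R)^2
    red <- (disk & core) * 1
    grn <- (disk & !core) * 1
  }
  aggregate_roi(1L, disk, c(0L, 0L, n, n), list(red = red, green = grn))
}

# Independent loop-based implementation of the channel moments, used as
# the oracle for the vectorized implementation.
moments_loop_oracle <- function(roi) {
  w <- roi$intensities
  nr <- nrow(roi$mask); nc <- ncol(roi$mask)
  first <- function(m) {
    m <- m / sum(m)
    cr <- 0; cc <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      cr <- cr + m[r, c] * (r - 1)
      cc <- cc + m[r, c] * (c - 1)
    }
    c(cr, cc)
  }
  c_red <- first(w[[1]]); c_grn <- first(w[[2]])
  c_all <- (c_red + c_grn) / 2
  gyr <- function(m) {
    m <- m / sum(m)
    acc <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      acc <- acc + m[r, c] * ((r - 1 - c_all[1])^2 + (c - 1 - c_all[2])^2)
    }
    sqrt(acc)
  }
  list(centroid_red = c_red + roi$bbox[1:2], centroid_green = c_grn + roi$bbox[1:2],
       g_red = gyr(w[[1]]), g_green = gyr(w[[2]]))
}

# Exhaustive Li cross-entropy minimiser (midpoint of the optimal
# threshold interval), the oracle for the iterative implementation.
li_exhaustive_oracle <- function(x) {
  x <- as.numeric(x)
  shift <- if (min(x) <= 0) -min(x) + 1e-8 else 0
  xs <- x + shift
  lv <- sort(unique(xs))
  ce <- vapply(lv[-length(lv)], function(t) {
    lo <- xs[xs <= t]; hi <- xs[xs > t]
    -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
  }, 0)
  opt <- which.min(ce)
  (lv[opt] + lv[opt + 1]) / 2 - shift
}
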