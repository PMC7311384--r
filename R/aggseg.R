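#' Segmentation parameters for aggregate fields
#'
#' Bundles the tunables of the aggregate segmentation chain:
#' local-contrast normalisation, Gaussian smoothing, Li thresholding,
#' connected-component labelling and the minimum-object-size filter.
#'
#' @param contrast_block_radius_px half-width of the local-contrast window.
#' @param contrast_stdevs clamp for the local z-score (in local SD units).
#' @param blur_sigma_px Gaussian smoothing sigma (default 1, matching the
#'   usual sigma-1 blur applied before thresholding).
#' @param min_object_area_px components strictly smaller than this many
#'   pixels are discarded (default 1000).
#' @param combine_rule how the two channels are merged for detection:
#'   `"sum"` (default) or `"max"`.
#' @param connectivity 8 (default) or 4 for component labelling.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(contrast_block_radius_px = 127L,
                                contrast_stdevs = 3,
                                blur_sigma_px = 1,
                                min_object_area_px = 1000L,
                                combine_rule = c("sum", "max"),
                                connectivity = 8L) {
  combine_rule <- match.arg(combine_rule)
  stopifnot(contrast_block_radius_px >= 1, contrast_stdevs > 0,
            blur_sigma_px > 0, min_object_area_px >= 0,
            connectivity %in% c(4L, 8L))
  structure(list(contrast_block_radius_px = as.integer(contrast_block_radius_px),
                 contrast_stdevs = contrast_stdevs,
                 blur_sigma_px = blur_sigma_px,
                 min_object_area_px = as.integer(min_object_area_px),
                 combine_rule = combine_rule,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Local contrast normalisation
#'
#' Centres and scales every pixel by the mean and standard deviation of its
#' `(2r+1) x (2r+1)` neighbourhood (symmetric-reflection padding at the
#' edges), clamps the resulting local z-score at `+/- stdevs`, and maps it
#' affinely back onto `dtype_range`. Pixels in locally flat (zero-variance)
#' neighbourhoods map to mid-range.
#'
#' @param channel numeric matrix.
#' @param block_radius_px window half-width (>= 1).
#' @param stdevs clamp in local standard deviations (> 0).
#' @param dtype_range output intensity range; guessed from the input when NULL.
#' @return matrix of the same size, values spanning `dtype_range`.
#' @export
normalize_local_contrast <- function(channel, block_radius_px, stdevs,
                                     dtype_range = NULL) {
  stopifnot(is.matrix(channel), block_radius_px >= 1, stdevs > 0)
  if (is.null(dtype_range)) {
    dtype_range <- guess_dtype_range(channel)
  }
  r <- as.integer(block_radius_px)
  pad <- pad_reflect(channel, r)
  n <- (2 * r + 1)^2
  s1 <- box_sum(pad, r)
  s2 <- box_sum(pad * pad, r)
  mu <- s1 / n
  va <- pmax(s2 / n - mu * mu, 0)
  sd_ <- sqrt(va)
  z <- (channel - mu) / sd_
  z[sd_ == 0] <- 0
  z <- pmin(pmax(z, -stdevs), stdevs)
  lo <- dtype_range[1]; hi <- dtype_range[2]
  lo + (z + stdevs) / (2 * stdevs) * (hi - lo)
}

# Sliding (2r+1)^2 box sum of a padded matrix, returned at the original size.
# Cumulative-sum (integral image) implementation.
box_sum <- function(pad, r) {
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)  # note: transposed
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  nr <- nrow(pad) - 2 * r; nc <- ncol(pad) - 2 * r
  w <- 2 * r + 1
  rows <- seq_len(nr); cols <- seq_len(nc)
  ii[rows + w, cols + w, drop = FALSE] - ii[rows, cols + w, drop = FALSE] -
    ii[rows + w, cols, drop = FALSE] + ii[rows, cols, drop = FALSE]
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalised Gaussian kernel (radius
#' `ceiling(4 sigma)`), symmetric-reflection boundaries, so flat regions and
#' total interior intensity are conserved.
#'
#' @param channel numeric matrix.
#' @param sigma_px kernel sigma in pixels (> 0).
#' @return smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(channel, sigma_px) {
  stopifnot(is.matrix(channel), sigma_px > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  conv_1d_matrix <- function(n) {
    # boundary-folded banded convolution operator with symmetric reflection
    A <- matrix(0, n, n)
    refl <- function(j) {
      # reflect index j into 1..n (symmetric, edge-inclusive)
      j <- ((j - 1) %% (2 * n))
      j <- ifelse(j >= n, 2 * n - 1 - j, j)
      j + 1L
    }
    for (off in -r:r) {
      j <- refl(seq_len(n) + off)
      A[cbind(seq_len(n), j)] <- A[cbind(seq_len(n), j)] + k[off + r + 1]
    }
    A
  }
  Ar <- conv_1d_matrix(nrow(channel))
  Ac <- conv_1d_matrix(ncol(channel))
  Ar %*% channel %*% t(Ac)
}

#' Li minimum cross-entropy threshold
#'
#' Computes the threshold minimising the Li-Lee cross entropy between the
#' image and its binarised representation (each side replaced by its mean).
#' Implemented as the classic fixed-point iteration on the two class means,
#' `t <- (mu_lo - mu_hi) / (log(mu_lo) - log(mu_hi))`, started from the
#' global mean and iterated to a convergence tolerance of half a grey level.
#'
#' @param channel numeric matrix; must not be constant.
#' @param tol convergence tolerance. `NULL` (default) uses 0.5 for data on
#'   an integer grey scale (range > 2) and `range/512` for unit-scaled data.
#' @param max_iter iteration cap.
#' @return the threshold (on the intensity scale of the input).
#' @export
li_threshold <- function(channel, tol = NULL, max_iter = 200L) {
  x <- as.numeric(channel)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("li_threshold: image is constant; no threshold defined")
  if (is.null(tol)) {
    tol <- if (diff(rng) > 2) 0.5 else diff(rng) / 512
  }
  # the log update needs positive intensities: shift so the minimum sits
  # just above zero, threshold is shifted back on return
  shift <- if (rng[1] <= 0) -rng[1] + 1e-8 * diff(rng) + 1e-12 else 0
  x <- x + shift
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t_cur]; hi <- x[x > t_cur]
    if (length(lo) == 0L || length(hi) == 0L) break
    mu_lo <- mean(lo); mu_hi <- mean(hi)
    t_new <- (mu_lo - mu_hi) / (log(mu_lo) - log(mu_hi))
    if (!is.finite(t_new)) break
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  # The cross entropy is piecewise constant between data values, so the
  # continuous fixed point can sit a fraction of a grey level off the
  # discrete minimiser. Polish by evaluating the criterion at the nearby
  # partition boundaries and projecting the fixed point onto the best
  # partition's threshold interval.
  xs <- sort(x)
  cs <- cumsum(xs)
  n_tot <- length(xs); tot <- cs[n_tot]
  r <- rle(xs)
  lv <- r$values
  idx <- cumsum(r$lengths)            # index of the last pixel at each level
  win <- max(4 * tol, 3)
  cand <- which(lv >= t_cur - win & lv <= t_cur + win)
  cand <- cand[cand < length(lv)]     # a boundary needs pixels on both sides
  if (length(cand) > 0) {
    n_lo <- idx[cand]; s_lo <- cs[n_lo]
    ce <- -s_lo * log(s_lo / n_lo) - (tot - s_lo) * log((tot - s_lo) / (n_tot - n_lo))
    best <- cand[which.min(ce)]
    l0 <- lv[best]; l1 <- lv[best + 1L]
    if (t_cur < l0 || t_cur >= l1) {
      t_cur <- if (t_cur < l0) l0 else (l0 + l1) / 2
    }
  }
  t_cur - shift
}

#' Connected-component labelling
#'
#' Breadth-first labelling of a logical mask with 8- (default) or
#' 4-connectivity. Labels are assigned in raster-scan order of each
#' component's first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  if (length(todo) == 0L) return(lab)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8L) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  visited <- matrix(FALSE, nr, nc)
  visited[!mask] <- TRUE
  next_lab <- 0L
  for (seed in todo) {
    if (visited[seed]) next
    next_lab <- next_lab + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- next_lab
    while (length(frontier) > 0L) {
      r0 <- (frontier - 1L) %% nr + 1L
      c0 <- (frontier - 1L) %/% nr + 1L
      nbr <- integer(0)
      for (k in seq_along(dr)) {
        rr <- r0 + dr[k]; cc <- c0 + dc[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[!visited[nbr]]
      visited[nbr] <- TRUE
      lab[nbr] <- next_lab
      frontier <- nbr
    }
  }
  lab
}

#' Construct an aggregate ROI
#'
#' One segmented cluster: a mask over its bounding box plus the raw
#' per-channel intensities restricted to (zeroed outside) the mask.
#' `bbox` is 0-based half-open `(row0, col0, row1, col1)`.
#'
#' @param id integer ROI id.
#' @param mask logical matrix over the bounding box.
#' @param bbox integer vector `(row0, col0, row1, col1)`, half-open, 0-based.
#' @param intensities named list of numeric matrices (same size as `mask`),
#'   one per channel; values outside the mask are zeroed here.
#' @return an `aggregate_roi`.
#' @export
aggregate_roi <- function(id, mask, bbox, intensities) {
  stopifnot(is.matrix(mask), is.logical(mask), length(bbox) == 4L)
  stopifnot(nrow(mask) == bbox[3] - bbox[1], ncol(mask) == bbox[4] - bbox[2])
  intensities <- lapply(intensities, function(m) {
    stopifnot(all(dim(m) == dim(mask)))
    m[!mask] <- 0
    m
  })
  structure(list(id = as.integer(id), mask = mask, bbox = as.integer(bbox),
                 area_px = sum(mask), intensities = intensities),
            class = "aggregate_roi")
}

#' @export
print.aggregate_roi <- function(x, ...) {
  cat(sprintf("<aggregate_roi #%d> area %d px; bbox [%d,%d)x[%d,%d); channels: %s\n",
              x$id, x$area_px, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              paste(names(x$intensities), collapse = ", ")))
  invisible(x)
}

#' Segment a two-channel aggregate field into cluster ROIs
#'
#' The detection chain: combine the channels (`sum` or `max`), normalise
#' local contrast, Gaussian-smooth, threshold with Li's minimum
#' cross-entropy method, label connected components, and drop components
#' strictly smaller than `min_object_area_px`. ROIs carry the *raw* channel
#' intensities masked in — the contrast-normalised image is used for
#' detection only, so downstream moment statistics reflect true signal.
#' ROI ids are ordered by the `(row0, col0)` of their bounding boxes.
#'
#' @param image a 2-channel 2D `mc_image` (run [max_project()] on stacks).
#' @param params a [segmentation_params()] object.
#' @return list of [aggregate_roi()] objects (possibly empty).
#' @export
segment_aggregates <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "mc_image"), inherits(params, "segmentation_params"))
  if (length(dim(image$data)) != 3L) image <- max_project(image)
  if (dim(image$data)[1] != 2L) stop("segment_aggregates expects a 2-channel image")
  ch1 <- image$data[1, , ]; ch2 <- image$data[2, , ]
  combined <- if (params$combine_rule == "sum") ch1 + ch2 else pmax(ch1, ch2)
  rng <- c(0, max(image$dtype_range[2], max(combined)))
  r <- min(params$contrast_block_radius_px, nrow(combined) - 1L, ncol(combined) - 1L)
  nlc <- normalize_local_contrast(combined, r, params$contrast_stdevs, rng)
  sm <- gaussian_smooth(nlc, params$blur_sigma_px)
  thr <- li_threshold(sm)
  mask <- sm > thr
  lab <- label_components(mask, params$connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= params$min_object_area_px)
  if (length(keep) == 0L) return(list())
  # bounding boxes (1-based internal)
  info <- lapply(keep, function(l) {
    px <- which(lab == l)
    rr <- (px - 1L) %% nrow(lab) + 1L
    cc <- (px - 1L) %/% nrow(lab) + 1L
    list(label = l, r0 = min(rr), r1 = max(rr), c0 = min(cc), c1 = max(cc))
  })
  ord <- order(vapply(info, `[[`, 0, "r0"), vapply(info, `[[`, 0, "c0"))
  rois <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    b <- info[[ord[i]]]
    sub <- lab[b$r0:b$r1, b$c0:b$c1, drop = FALSE] == b$label
    rois[[i]] <- aggregate_roi(
      id = i, mask = sub,
      bbox = c(b$r0 - 1L, b$c0 - 1L, b$r1, b$c1),
      intensities = stats::setNames(
        list(ch1[b$r0:b$r1, b$c0:b$c1, drop = FALSE],
             ch2[b$r0:b$r1, b$c0:b$c1, drop = FALSE]),
        image$channel_names)
    )
  }
  rois
}

#' Match segmented ROIs to generator ground-truth clusters
#'
#' Associates each manifest cluster with the ROI whose mask covers the
#' cluster's true centre.
#'
#' @param rois list of [aggregate_roi()] from [segment_aggregates()].
#' @param truth manifest from [generate_aggregate_field()].
#' @return integer vector over clusters: matching ROI id, or NA if the
#'   centre is not inside any ROI.
#' @export
match_rois_to_truth <- function(rois, truth) {
  vapply(truth$clusters, function(cl) {
    r <- round(cl$center[1]); c <- round(cl$center[2])
    for (roi in rois) {
      b <- roi$bbox
      if (r >= b[1] && r < b[3] && c >= b[2] && c < b[4] &&
          roi$mask[r - b[1] + 1L, c - b[2] + 1L]) {
        return(roi$id)
      }
    }
    NA_integer_
  }, 0L)
}
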