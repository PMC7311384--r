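#' Binarise a boundary-stained channel
#'
#' Produces a logical mask where TRUE marks the bright boundary ridge of a
#' phalloidin-like stain. `method = "fixed"` makes the manual threshold of
#' the original workflow an explicit, logged parameter; `"otsu"` and
#' `"li"` are automatic replacements.
#'
#' @param channel numeric matrix.
#' @param method `"li"`, `"otsu"` or `"fixed"`.
#' @param fixed_value threshold for `method = "fixed"`.
#' @return logical matrix (TRUE = boundary).
#' @export
binarize_boundaries <- function(channel, method = c("li", "otsu", "fixed"),
                                fixed_value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(!is.null(fixed_value))
    return(channel > fixed_value)
  }
  rng <- range(channel)
  if (rng[1] == rng[2]) stop("binarize_boundaries: constant image with automatic method")
  thr <- switch(method,
    li = li_threshold(channel),
    otsu = {
      x01 <- (channel - rng[1]) / (rng[2] - rng[1])
      rng[1] + EBImage::otsu(EBImage::Image(x01), range = c(0, 1)) * (rng[2] - rng[1])
    })
  channel > thr
}

#' Despeckle (3x3 median filter)
#'
#' The 3x3 median filter performed by the eponymous noise-removal step,
#' with replicated edges.
#'
#' @param mask_or_gray numeric or logical matrix.
#' @return matrix of the same type shape (logical in, logical out).
#' @export
despeckle <- function(mask_or_gray) {
  was_logical <- is.logical(mask_or_gray)
  m <- mask_or_gray * 1
  nr <- nrow(m); nc <- ncol(m)
  # replicate-pad by 1
  p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  s <- vector("list", 9)
  idx <- 1
  for (dr in 0:2) for (dc in 0:2) {
    s[[idx]] <- p[dr + 1:nr, dc + 1:nc]
    idx <- idx + 1
  }
  out <- median9(s)
  if (was_logical) out > 0.5 else out
}

# Exact median of 9 equally-sized matrices via a pmin/pmax selection
# network: sort the three column triples, then take the median of the
# (max of minima, median of medians, min of maxima).
median9 <- function(s) {
  med3 <- function(x, y, z) pmax(pmin(pmax(x, y), z), pmin(x, y))
  sort3 <- function(x, y, z) {
    lo <- pmin(pmin(x, y), z)
    hi <- pmax(pmax(x, y), z)
    list(lo = lo, mid = med3(x, y, z), hi = hi)
  }
  t1 <- sort3(s[[1]], s[[2]], s[[3]])
  t2 <- sort3(s[[4]], s[[5]], s[[6]])
  t3 <- sort3(s[[7]], s[[8]], s[[9]])
  med3(pmax(pmax(t1$lo, t2$lo), t3$lo),
       med3(t1$mid, t2$mid, t3$mid),
       pmin(pmin(t1$hi, t2$hi), t3$hi))
}

#' Watershed segmentation of an epithelial boundary mask
#'
#' Distance-transform watershed on the non-boundary region: the Euclidean
#' distance map of the cell interiors is flooded from its regional maxima
#' (EBImage watershed, with the `ext` radius controlling the minimum seed
#' separation). Regions smaller than `merge_min_area` are merged into
#' their largest neighbour — the automatic counterpart of manual border
#' clean-up. Boundary pixels are labelled 0.
#'
#' @param boundary_mask logical matrix, TRUE = boundary.
#' @param min_seed_sep_px minimum separation of seed maxima (default 5).
#' @param merge_min_area regions below this area are merged away (default 30).
#' @return integer label matrix (0 = boundary, 1..n = cells).
#' @export
watershed_cells <- function(boundary_mask, min_seed_sep_px = 5L,
                            merge_min_area = 30L) {
  stopifnot(is.matrix(boundary_mask))
  interior <- !boundary_mask
  if (!any(interior)) {
    warning("watershed_cells: no enclosed region")
    return(matrix(0L, nrow(boundary_mask), ncol(boundary_mask)))
  }
  d <- matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(interior * 1))),
              nrow(boundary_mask))
  seeds <- seed_markers(d, min_seed_sep_px)
  if (max(seeds) == 0L) {
    warning("watershed_cells: no enclosed region")
    return(matrix(0L, nrow(boundary_mask), ncol(boundary_mask)))
  }
  w <- EBImage::propagate(EBImage::Image(d), EBImage::Image(seeds),
                          mask = EBImage::Image(interior), lambda = 1e-4)
  lab <- matrix(as.integer(EBImage::imageData(w)), nrow(boundary_mask))
  lab[boundary_mask] <- 0L
  lab <- merge_split_regions(lab)
  lab <- merge_small_regions(lab, merge_min_area)
  relabel_sequential(lab)
}

# Undo oversegmentation: two labels produced by splitting one enclosed
# region touch each other directly over a wide interface (true
# neighbouring cells are separated by boundary pixels, and leaks through
# small boundary gaps are narrow). Merge label pairs whose direct 4-contact
# exceeds `min_contact` pixels, transitively.
merge_split_regions <- function(lab, min_contact = 6L) {
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ])),
    cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  tab <- table(key)
  wide <- names(tab)[tab >= min_contact]
  if (length(wide) == 0L) return(lab)
  # union-find over the labels
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in wide) {
    ab <- as.integer(strsplit(k, " ")[[1]])
    ra <- find(ab[1]); rb <- find(ab[2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, 0L)
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

# Marker image for the seeded watershed: regional maxima of the distance
# map (pixels not exceeded within `sep` px), clustered so maxima closer
# than `sep` share one marker.
seed_markers <- function(d, sep) {
  nr <- nrow(d); nc <- ncol(d)
  r <- max(1L, as.integer(sep))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2 & !(offs$dr == 0 & offs$dc == 0), ]
  is_max <- d > 0
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    cur <- is_max[rs, cs, drop = FALSE]
    cur <- cur & (d[rs, cs, drop = FALSE] >= d[rs + dr, cs + dc, drop = FALSE])
    is_max[rs, cs] <- cur
  }
  if (!any(is_max)) return(matrix(0L, nr, nc))
  # maxima whose dilations (radius sep) touch belong to one marker
  dil <- is_max
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    dil[rs, cs] <- dil[rs, cs, drop = FALSE] | is_max[rs + dr, cs + dc, drop = FALSE]
  }
  comp <- label_components(dil, 8L)
  out <- matrix(0L, nr, nc)
  out[is_max] <- comp[is_max]
  out
}

# Merge labelled regions smaller than `min_area` into their largest
# neighbouring region (by shared dilated border); isolated small regions
# with no neighbour become 0.
merge_small_regions <- function(lab, min_area) {
  repeat {
    n <- max(lab)
    if (n == 0L) return(lab)
    areas <- tabulate(lab[lab > 0L], nbins = n)
    small <- which(areas > 0 & areas < min_area)
    if (length(small) == 0L) return(lab)
    changed <- FALSE
    for (s in small) {
      px <- which(lab == s)
      nb <- neighbor_labels(lab, px)
      nb <- nb[nb != 0L & nb != s]
      if (length(nb) == 0L) { lab[px] <- 0L; changed <- TRUE; next }
      tgt <- as.integer(names(which.max(table(nb))))
      # prefer the largest neighbouring region overall
      cand <- unique(nb)
      tgt <- cand[which.max(tabulate(lab[lab > 0L], nbins = max(lab))[cand])]
      lab[px] <- tgt
      changed <- TRUE
    }
    if (!changed) return(lab)
  }
}

# Labels adjacent (8-neighbourhood) to the given pixel set.
neighbor_labels <- function(lab, px) {
  nr <- nrow(lab); nc <- ncol(lab)
  r0 <- (px - 1L) %% nr + 1L
  c0 <- (px - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r0 + dr; cc <- c0 + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- c(out, lab[(cc[ok] - 1L) * nr + rr[ok]])
  }
  out
}

relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Per-cell morphometrics from a label map
#'
#' Area is the pixel count; the perimeter is a marching-squares boundary
#' estimate (each 2x2 pixel configuration contributes its iso-contour
#' segment length), which is accurate for smooth digital shapes;
#' circularity is `4 pi area / perimeter^2`, clamped at 1. Centroids are
#' 0-based `(row, col)`.
#'
#' @param labels integer label matrix (0 = boundary/background).
#' @return tibble: `label`, `area_px`, `perimeter_px`, `circularity`,
#'   `centroid_row`, `centroid_col`.
#' @export
cell_metrics <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  nr <- nrow(labels)
  res <- lapply(ids, function(i) {
    px <- which(labels == i)
    rr <- (px - 1L) %% nr + 1L
    cc <- (px - 1L) %/% nr + 1L
    sub <- matrix(FALSE, max(rr) - min(rr) + 3L, max(cc) - min(cc) + 3L)
    sub[cbind(rr - min(rr) + 2L, cc - min(cc) + 2L)] <- TRUE
    per <- marching_perimeter(sub)
    area <- length(px)
    tibble::tibble(label = i, area_px = area, perimeter_px = per,
                   circularity = min(1, 4 * pi * area / per^2),
                   centroid_row = mean(rr) - 1, centroid_col = mean(cc) - 1)
  })
  dplyr::bind_rows(res)
}

# Marching-squares perimeter of a padded logical mask. Straight boundary
# segments count 1; corner-cut (diagonal) segments are weighted 0.625
# rather than sqrt(2)/2, which removes the staircase overestimate on
# digitised smooth contours (2 pi r recovered within ~0.5% for r >= 30)
# while leaving axis-aligned rectangles at their exact perimeter.
marching_perimeter <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  a <- m[-nr, -nc]; b <- m[-nr, -1]; c_ <- m[-1, -nc]; d <- m[-1, -1]
  code <- a + 2 * b + 4 * c_ + 8 * d
  h <- 0.625
  len <- c(0, h, h, 1, h, 1, 2 * h, h, h, 2 * h, 1, h, 1, h, h, 0)
  sum(len[code + 1])
}

#' Detect junction points in a labelled tessellation
#'
#' A boundary pixel whose disk neighbourhood of radius `radius_px`
#' touches at least three distinct cells is a junction candidate;
#' connected candidates are clustered into one junction point. The
#' junction's arity is the largest per-pixel distinct-cell count within
#' the cluster (so two nearby three-way vertices that merge into one
#' cluster do not have their cell sets pooled); its incident cells are
#' those seen by the count-achieving pixel nearest the junction centre,
#' and its position is the centroid of the count-achieving pixels
#' (0-based). Clusters already showing `rosette_min_arity` cells in the
#' base window are re-measured with the window widened by 2 px: boundary
#' lines converging on a high-arity vertex blank a disk of radius about
#' `half-width / sin(wedge/2)` around it (plus ~1 px after a despeckle),
#' so the outermost incident cells of a rosette sit beyond the base
#' window while ordinary junctions do not need — and do not get — the
#' wider, more permissive pass. Junctions with
#' `arity >= rosette_min_arity` are flagged as rosettes. Two-cell
#' contacts are not junction points, but can be counted via
#' `include_two_cell = TRUE` (they then carry `arity = 2`), for margin
#' analyses.
#'
#' @param labels integer label matrix (0 = boundary).
#' @param radius_px base neighbourhood radius (default 4; it must exceed
#'   the carved boundary half-width but stay below the typical vertex
#'   spacing).
#' @param rosette_min_arity minimum cells per junction to call a rosette
#'   (default 5).
#' @param include_two_cell also report two-cell contact segments.
#' @return tibble: `row`, `col`, `arity`, `labels` (list-column),
#'   `is_rosette`.
#' @export
detect_junctions <- function(labels, radius_px = 4L, rosette_min_arity = 5L,
                             include_two_cell = FALSE) {
  nr <- nrow(labels); nc <- ncol(labels)
  bnd <- which(labels == 0L)
  if (length(bnd) == 0L) return(tibble::tibble())
  r <- as.integer(radius_px)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= (r + 0.5)^2, ]  # disk window
  r0 <- (bnd - 1L) %% nr + 1L
  c0 <- (bnd - 1L) %/% nr + 1L
  neigh <- matrix(0L, length(bnd), nrow(offs))
  for (k in seq_len(nrow(offs))) {
    rr <- r0 + offs$dr[k]; cc <- c0 + offs$dc[k]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    v <- integer(length(bnd))
    v[ok] <- labels[(cc[ok] - 1L) * nr + rr[ok]]
    neigh[, k] <- v
  }
  n_distinct <- apply(neigh, 1, function(x) length(unique(x[x > 0L])))
  cand <- n_distinct >= 3L
  if (!any(cand) && !include_two_cell) return(tibble::tibble())
  cmask <- matrix(FALSE, nr, nc)
  cmask[bnd[cand]] <- TRUE
  clab <- label_components(cmask, 8L)
  count_at <- function(pix, rad) {
    # distinct labels within a disk window of each given pixel
    o2 <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    o2 <- o2[o2$dr^2 + o2$dc^2 <= (rad + 0.5)^2, ]
    pr <- (pix - 1L) %% nr + 1L
    pc <- (pix - 1L) %/% nr + 1L
    m <- matrix(0L, length(pix), nrow(o2))
    for (k in seq_len(nrow(o2))) {
      rr <- pr + o2$dr[k]; cc <- pc + o2$dc[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      v <- integer(length(pix))
      v[ok] <- labels[(cc[ok] - 1L) * nr + rr[ok]]
      m[, k] <- v
    }
    m
  }
  out <- lapply(seq_len(max(clab)), function(j) {
    px <- which(clab == j)
    sel <- match(px, bnd)
    amax <- max(n_distinct[sel])
    at_max <- sel[n_distinct[sel] == amax]
    px_max <- bnd[at_max]
    neigh_j <- neigh
    if (amax >= rosette_min_arity) {
      # confirmed rosette: the boundary blob at a high-arity vertex is
      # wider than the base window, so resolve the exact arity with a
      # wider pass over this cluster's pixels only
      m2 <- count_at(px, r + 2L)
      nd2 <- apply(m2, 1, function(x) length(unique(x[x > 0L])))
      amax <- max(nd2)
      at_max <- which(nd2 == amax)
      px_max <- px[at_max]
      neigh_sub <- m2
    } else {
      neigh_sub <- neigh[sel, , drop = FALSE]
      at_max <- which(n_distinct[sel] == amax)
    }
    # incident set from the argmax pixel nearest the junction centre, so
    # arity always equals the number of incident cells
    ctr_r <- mean((px_max - 1L) %% nr); ctr_c <- mean((px_max - 1L) %/% nr)
    d2c <- ((px_max - 1L) %% nr - ctr_r)^2 + ((px_max - 1L) %/% nr - ctr_c)^2
    best <- at_max[which.min(d2c)]
    labs <- sort(unique(neigh_sub[best, ]))
    labs <- labs[labs > 0L]
    tibble::tibble(
      row = ctr_r,
      col = ctr_c,
      arity = amax,
      labels = list(labs)
    )
  })
  out <- dplyr::bind_rows(out)
  if (NROW(out) > 0) out <- out[out$arity >= 3L, , drop = FALSE]
  if (include_two_cell) {
    # two-cell contact segments: boundary stretches seeing exactly two
    # cells, split apart by the junction clusters that separate them
    mask2 <- matrix(FALSE, nr, nc)
    mask2[bnd[n_distinct == 2L]] <- TRUE
    mask2[cmask] <- FALSE
    seg <- label_components(mask2, 8L)
    if (max(seg) > 0) {
      segs <- lapply(seq_len(max(seg)), function(j) {
        px <- which(seg == j)
        sel <- match(px, bnd)
        labs <- sort(unique(as.vector(neigh[sel, , drop = FALSE])))
        labs <- labs[labs > 0L]
        tibble::tibble(
          row = mean((px - 1L) %% nr),
          col = mean((px - 1L) %/% nr),
          arity = 2L,
          labels = list(labs))
      })
      out <- dplyr::bind_rows(out, dplyr::bind_rows(segs))
    }
  }
  if (NROW(out) == 0) return(tibble::tibble())
  out$is_rosette <- out$arity >= rosette_min_arity
  out
}

#' Mitotic fraction of an epithelial sheet
#'
#' Thresholds the pHH3-like nuclear channel (Li), keeps components of at
#' least `nucleus_min_area_px` pixels, assigns each nucleus to the cell
#' whose label map region contains its centroid, and reports the
#' percentage of cells carrying at least one nucleus.
#'
#' @param labels integer label matrix of the cells.
#' @param phh3_channel numeric matrix, nuclear channel.
#' @param nucleus_min_area_px minimum nucleus component area (default 9).
#' @return percentage in `[0, 100]`.
#' @export
mitotic_fraction <- function(labels, phh3_channel, nucleus_min_area_px = 9L) {
  n_cells <- length(unique(labels[labels > 0L]))
  if (n_cells == 0L) stop("mitotic_fraction: empty label map")
  if (max(phh3_channel) == min(phh3_channel)) return(0)
  thr <- li_threshold(phh3_channel)
  mask <- phh3_channel > thr
  if (!any(mask)) return(0)
  comp <- label_components(mask, 8L)
  nr <- nrow(labels)
  hit <- integer(0)
  for (j in seq_len(max(comp))) {
    px <- which(comp == j)
    if (length(px) < nucleus_min_area_px) next
    cr <- round(mean((px - 1L) %% nr)) + 1L
    cc <- round(mean((px - 1L) %/% nr)) + 1L
    lb <- labels[cr, cc]
    if (lb == 0L) {
      # centroid fell on a boundary pixel: take the modal label around it
      nb <- neighbor_labels(labels, (cc - 1L) * nr + cr)
      nb <- nb[nb > 0L]
      if (length(nb) > 0) lb <- as.integer(names(which.max(table(nb))))
    }
    if (lb > 0L) hit <- c(hit, lb)
  }
  100 * length(unique(hit)) / n_cells
}

#' Morphometry summary of one tessellation
#'
#' @param labels integer label matrix.
#' @param phh3_channel optional nuclear channel for the mitotic percentage.
#' @param junction_radius_px,rosette_min_arity passed to [detect_junctions()].
#' @param nucleus_min_area_px passed to [mitotic_fraction()].
#' @return list: `n_cells`, `mean_area`, `mean_circularity`,
#'   `junction_arity_counts` (named), `rosette_count`, `mitotic_percent`
#'   (NA without a nuclear channel), plus the per-cell and junction tables.
#' @export
morphometry_summary <- function(labels, phh3_channel = NULL,
                                junction_radius_px = 4L,
                                rosette_min_arity = 5L,
                                nucleus_min_area_px = 9L) {
  cells <- cell_metrics(labels)
  jx <- detect_junctions(labels, junction_radius_px, rosette_min_arity)
  counts <- if (NROW(jx) > 0) table(jx$arity) else table(integer(0))
  list(
    n_cells = nrow(cells),
    mean_area = mean(cells$area_px),
    mean_circularity = mean(cells$circularity),
    junction_arity_counts = stats::setNames(as.integer(counts), names(counts)),
    rosette_count = if (NROW(jx) > 0) sum(jx$is_rosette) else 0L,
    mitotic_percent = if (is.null(phh3_channel)) NA_real_
                      else mitotic_fraction(labels, phh3_channel, nucleus_min_area_px),
    cells = cells,
    junctions = jx
  )
}
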