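#' Configuration for synthetic EVL tessellation images
#'
#' Describes a boundary-stained epithelial mosaic: a Voronoi tessellation
#' of `n_cells` seeds (optionally Lloyd-relaxed towards a centroidal
#' tessellation), rendered with bright cell boundaries on a dimmer
#' interior, emulating phalloidin-stained enveloping-layer (EVL) cells.
#' Rosettes — junctions where 5 or more cells meet — are injected by
#' collapsing edges of the Voronoi vertex graph until the requested arity
#' is reached, so the ground truth contains exactly the requested
#' configurations. A fraction of cells can be flagged mitotic and rendered
#' as bright nuclear blobs in a second (pHH3-like) channel.
#'
#' @param n_cells number of cells (>= 4).
#' @param domain `"rectangle"` (full square image) or `"disk"`.
#' @param domain_size_px image side length in pixels.
#' @param lloyd_iterations Lloyd relaxation sweeps (>= 0).
#' @param boundary_width_px rendered boundary thickness (> 0).
#' @param boundary_intensity,interior_intensity intensity of boundary
#'   ridges and cell interiors (`interior < boundary`).
#' @param noise_sd additive Gaussian noise sigma.
#' @param rosette_injections integer vector of target junction arities
#'   (each between 5 and 8).
#' @param mitotic_fraction fraction of cells flagged mitotic; the count is
#'   rounded to the nearest integer, ties upward.
#' @param seed RNG seed.
#' @return a `tessellation_config`.
#' @export
tessellation_config <- function(n_cells = 100L,
                                domain = c("rectangle", "disk"),
                                domain_size_px = 512L,
                                lloyd_iterations = 2L,
                                boundary_width_px = 2,
                                boundary_intensity = 200,
                                interior_intensity = 60,
                                noise_sd = 4,
                                rosette_injections = integer(0),
                                mitotic_fraction = 0,
                                seed = 1L) {
  domain <- match.arg(domain)
  stopifnot(n_cells >= 4, domain_size_px >= 32, lloyd_iterations >= 0,
            boundary_width_px > 0, interior_intensity < boundary_intensity,
            noise_sd >= 0, mitotic_fraction >= 0, mitotic_fraction <= 1)
  rosette_injections <- as.integer(rosette_injections)
  if (length(rosette_injections) > 0 &&
      (any(rosette_injections < 5L) || any(rosette_injections > 8L))) {
    stop("rosette injection arities must be between 5 and 8")
  }
  structure(as.list(environment()), class = "tessellation_config")
}

#' Generate a synthetic EVL tessellation image with ground truth
#'
#' @param config a [tessellation_config()].
#' @return list with `image` (2-channel `mc_image`: "phalloidin", "phh3")
#'   and `truth`: `label_map` (integer matrix, 0 = boundary/background,
#'   1..n = cells), `cells` (tibble: label, area_px, centroid, is_mitotic),
#'   `junctions` (tibble: row, col, arity, incident labels as list-col,
#'   injected flag), `seed`, `config`.
#' @export
generate_tessellation <- function(config) {
  stopifnot(inherits(config, "tessellation_config"))
  set.seed(config$seed)
  n <- config$n_cells
  L <- config$domain_size_px
  if (config$domain == "rectangle") {
    seeds <- cbind(stats::runif(n, 0.02 * L, 0.98 * L),
                   stats::runif(n, 0.02 * L, 0.98 * L))
  } else {
    rr <- 0.45 * L * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    seeds <- cbind(L / 2 + rr * cos(th), L / 2 + rr * sin(th))
  }
  if (config$lloyd_iterations > 0) {
    seeds <- discrete_lloyd(seeds, L, config$lloyd_iterations,
                            disk = config$domain == "disk")
  }
  vg <- voronoi_vertex_graph(seeds, L)
  vg <- inject_rosettes(vg, config$rosette_injections, L, n)
  label_map <- rasterize_tessellation(vg, seeds, L)
  if (config$domain == "disk") {
    ctr <- L / 2
    px <- pixel_center_grid(L)
    outside <- (px$row - ctr)^2 + (px$col - ctr)^2 > (0.5 * L)^2
    label_map[outside] <- 0L
  }
  # carve boundaries of the requested width
  bmask <- boundary_pixels(label_map, config$boundary_width_px)
  interior_map <- label_map
  interior_map[bmask] <- 0L
  present <- sort(unique(interior_map[interior_map > 0L]))
  if (length(present) != n) {
    stop(sprintf("tessellation degenerate: %d of %d cells survive rasterization; increase domain_size_px or reduce n_cells",
                 length(present), n))
  }
  # per-cell ground truth
  areas <- tabulate(interior_map[interior_map > 0L], nbins = n)
  cr <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    px <- which(interior_map == i)
    cr[i] <- mean((px - 1L) %% nrow(interior_map))
    cc[i] <- mean((px - 1L) %/% nrow(interior_map))
  }
  n_mit <- floor(config$mitotic_fraction * n + 0.5)  # round, ties up
  mit <- rep(FALSE, n)
  if (n_mit > 0) mit[sample.int(n, n_mit)] <- TRUE
  cells <- tibble::tibble(label = seq_len(n), area_px = areas,
                          centroid_row = cr, centroid_col = cc,
                          is_mitotic = mit)
  # junction ground truth: graph vertices with >= 3 real incident cells,
  # interior to the domain
  jx <- vg$pos[, 1]; jy <- vg$pos[, 2]
  arity <- vapply(vg$cells, length, 0L)
  inside <- jx > 1 & jx < L - 1 & jy > 1 & jy < L - 1
  if (config$domain == "disk") {
    inside <- inside & ((jx - L / 2)^2 + (jy - L / 2)^2 < (0.5 * L - 1)^2)
  }
  keep <- which(arity >= 3L & inside)
  junctions <- tibble::tibble(
    row = jx[keep], col = jy[keep], arity = arity[keep],
    labels = lapply(keep, function(i) sort(vg$cells[[i]])),
    injected = vg$injected[keep]
  )
  # render
  ch1 <- matrix(config$interior_intensity, L, L)
  ch1[bmask] <- config$boundary_intensity
  ch1[label_map == 0L & !bmask] <- 0
  ch2 <- matrix(0, L, L)
  if (any(mit)) {
    sig_n <- sqrt(mean(areas) / pi) * 0.22   # nuclei well inside their cells
    for (i in which(mit)) {
      rows <- pmax(1, floor(cr[i] - 3 * sig_n)):pmin(L, ceiling(cr[i] + 3 * sig_n))
      cols <- pmax(1, floor(cc[i] - 3 * sig_n)):pmin(L, ceiling(cc[i] + 3 * sig_n))
      ch2[rows, cols] <- ch2[rows, cols] + config$boundary_intensity *
        outer(exp(-((rows - 1 - cr[i])^2) / (2 * sig_n^2)),
              exp(-((cols - 1 - cc[i])^2) / (2 * sig_n^2)))
    }
  }
  if (config$noise_sd > 0) {
    ch1 <- ch1 + stats::rnorm(length(ch1), 0, config$noise_sd)
    ch2 <- ch2 + stats::rnorm(length(ch2), 0, config$noise_sd)
  }
  img <- array(0, dim = c(2L, L, L))
  img[1, , ] <- pmin(pmax(ch1, 0), 255)
  img[2, , ] <- pmin(pmax(ch2, 0), 255)
  list(
    image = mc_image(round(img), c("phalloidin", "phh3"), dtype_range = c(0, 255)),
    truth = list(label_map = interior_map, cells = cells, junctions = junctions,
                 seed = config$seed, config = config)
  )
}

pixel_center_grid <- function(L) {
  list(row = matrix(seq_len(L) - 0.5, L, L),
       col = matrix(seq_len(L) - 0.5, L, L, byrow = TRUE))
}

# Lloyd relaxation on a subsampled pixel grid.
discrete_lloyd <- function(seeds, L, iters, disk = FALSE) {
  step <- max(1, L / 128)
  g <- seq(step / 2, L - step / 2, by = step)
  pts <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  if (disk) {
    pts <- pts[(pts[, 1] - L / 2)^2 + (pts[, 2] - L / 2)^2 <= (0.48 * L)^2, ]
  }
  for (it in seq_len(iters)) {
    d2 <- outer(rowSums(pts^2), rep(1, nrow(seeds))) -
      2 * pts %*% t(seeds) +
      outer(rep(1, nrow(pts)), rowSums(seeds^2))
    nearest <- max.col(-d2, ties.method = "first")
    for (i in seq_len(nrow(seeds))) {
      sel <- nearest == i
      if (any(sel)) seeds[i, ] <- colMeans(pts[sel, , drop = FALSE])
    }
  }
  seeds
}

# Voronoi vertex graph of seeds in [0, L]^2, closed at the domain border by
# mirroring the seeds across the four edges. Vertices are circumcentres of
# locally Delaunay seed triples (found among k-nearest neighbours) whose
# circumcircle is empty; two vertices are adjacent when they share two
# seeds. Returns positions, per-vertex incident *real* cell indices, the
# full seed triple sets, and the adjacency list.
voronoi_vertex_graph <- function(seeds, L, k = 14L) {
  n <- nrow(seeds)
  mirror <- rbind(
    cbind(-seeds[, 1], seeds[, 2]),
    cbind(2 * L - seeds[, 1], seeds[, 2]),
    cbind(seeds[, 1], -seeds[, 2]),
    cbind(seeds[, 1], 2 * L - seeds[, 2])
  )
  all_s <- rbind(seeds, mirror)
  N <- nrow(all_s)
  k <- min(k, N - 1)
  d2 <- as.matrix(stats::dist(all_s))^2
  # candidate triples around every real seed (deduplicated afterwards)
  tri_mat <- NULL
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    cmb <- utils::combn(nb, 2)
    block <- t(apply(rbind(i, cmb), 2, sort))
    tri_mat <- rbind(tri_mat, block)
  }
  tri_mat <- tri_mat[!duplicated(tri_mat), , drop = FALSE]
  tri <- lapply(seq_len(nrow(tri_mat)), function(j) tri_mat[j, ])
  pos <- matrix(NA_real_, 0, 2)
  vseeds <- list()
  for (t3 in tri) {
    A <- all_s[t3[1], ]; B <- all_s[t3[2], ]; C <- all_s[t3[3], ]
    M <- rbind(B - A, C - A)
    det_ <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (abs(det_) < 1e-9) next
    # circumcentre: solve 2 (B-A).x = |B|^2-|A|^2 and 2 (C-A).x = |C|^2-|A|^2
    ctr <- solve(2 * M, c(sum(B^2) - sum(A^2), sum(C^2) - sum(A^2)))
    r2 <- sum((ctr - A)^2)
    dd <- (all_s[, 1] - ctr[1])^2 + (all_s[, 2] - ctr[2])^2
    dd[t3] <- Inf
    if (min(dd) > r2 - 1e-7) {
      pos <- rbind(pos, ctr)
      vseeds[[length(vseeds) + 1L]] <- t3
    }
  }
  # merge near-coincident vertices (cocircular degeneracies)
  if (nrow(pos) > 1) {
    merged <- rep(FALSE, nrow(pos))
    for (i in seq_len(nrow(pos) - 1)) {
      if (merged[i]) next
      for (j in (i + 1):nrow(pos)) {
        if (!merged[j] && sum((pos[i, ] - pos[j, ])^2) < 1e-8) {
          vseeds[[i]] <- sort(unique(c(vseeds[[i]], vseeds[[j]])))
          merged[j] <- TRUE
        }
      }
    }
    pos <- pos[!merged, , drop = FALSE]
    vseeds <- vseeds[!merged]
  }
  nv <- nrow(pos)
  adj <- vector("list", nv)
  for (i in seq_len(nv)) adj[[i]] <- integer(0)
  if (nv > 1) {
    for (i in seq_len(nv - 1)) {
      for (j in (i + 1):nv) {
        if (length(intersect(vseeds[[i]], vseeds[[j]])) >= 2L) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  out <- list(pos = pos,
              seeds = vseeds,                                # indices into all seeds
              cells = lapply(vseeds, function(s) s[s <= n]), # real cells only
              adj = adj,
              injected = rep(FALSE, nv),
              alive = rep(TRUE, nv),
              n_real = n)
  attr(out, "seed_xy") <- seeds
  out
}

# Collapse edges of the vertex graph to create junctions of the requested
# arities. Each requested rosette starts from an interior degree-3 vertex
# and repeatedly merges the nearest eligible adjacent vertex until the
# number of distinct incident cells reaches the target. A merge is only
# eligible if it does not overshoot the target and if every incident
# cell's wedge at the merged position stays wide enough to reach pixels
# near the junction (at least half the balanced wedge angle) — narrow
# wedges would make the rosette geometrically undetectable at pixel
# resolution. Each injection is attempted from several start vertices
# (on a scratch copy, committed on success) before failing.
inject_rosettes <- function(vg, arities, L, n) {
  if (length(arities) == 0) return(vg)
  lo <- 0.2 * L; hi <- 0.8 * L
  seeds_xy <- attr(vg, "seed_xy")
  used_near <- matrix(NA_real_, 0, 2)
  min_wedge_at <- function(p, cells) {
    ang <- sort(atan2(seeds_xy[cells, 2] - p[2], seeds_xy[cells, 1] - p[1]))
    min(diff(c(ang, ang[1] + 2 * pi)))
  }
  for (ii in seq_along(arities)) {
    target <- arities[ii]
    interior_ok <- function(g, v) {
      g$alive[v] &&
        all(g$seeds[[v]] <= n) &&
        g$pos[v, 1] > lo && g$pos[v, 1] < hi &&
        g$pos[v, 2] > lo && g$pos[v, 2] < hi
    }
    attempt <- function(g, v, target) {
      while (length(g$cells[[v]]) < target) {
        nbrs <- g$adj[[v]]
        nbrs <- nbrs[vapply(nbrs, function(w) interior_ok(g, w), TRUE) &
                       !g$injected[nbrs]]
        if (length(nbrs) > 0) {
          info <- lapply(nbrs, function(w) {
            cl <- sort(unique(c(g$cells[[v]], g$cells[[w]])))
            p <- (g$pos[v, ] + g$pos[w, ]) / 2
            list(w = w, cells = cl, pos = p,
                 gain = length(cl) - length(g$cells[[v]]),
                 wedge = min_wedge_at(p, cl))
          })
          keep <- vapply(info, function(x) {
            x$gain > 0 && length(x$cells) <= target &&
              x$wedge >= 0.5 * 2 * pi / length(x$cells)
          }, TRUE)
          info <- info[keep]
        } else info <- list()
        if (length(info) == 0) return(NULL)
        dd <- vapply(info, function(x) sum((g$pos[x$w, ] - g$pos[v, ])^2), 0)
        ch <- info[[which.min(dd)]]
        w <- ch$w
        g$pos[v, ] <- ch$pos
        g$seeds[[v]] <- sort(unique(c(g$seeds[[v]], g$seeds[[w]])))
        g$cells[[v]] <- ch$cells
        g$adj[[v]] <- setdiff(unique(c(g$adj[[v]], g$adj[[w]])), c(v, w))
        for (x in g$adj[[w]]) {
          g$adj[[x]] <- setdiff(unique(c(g$adj[[x]], v)), w)
        }
        g$alive[w] <- FALSE
        g$adj[[w]] <- integer(0)
        g$cells[[w]] <- integer(0)
        g$seeds[[w]] <- integer(0)
      }
      g$injected[v] <- TRUE
      g
    }
    cand <- which(vapply(seq_len(nrow(vg$pos)),
                         function(v) interior_ok(vg, v), TRUE) & !vg$injected)
    if (nrow(used_near) > 0 && length(cand) > 0) {
      dmin <- apply(used_near, 1, function(p) {
        sqrt((vg$pos[cand, 1] - p[1])^2 + (vg$pos[cand, 2] - p[2])^2)
      })
      dmin <- if (is.matrix(dmin)) apply(dmin, 1, min) else dmin
      cand <- cand[dmin > 0.15 * L]
    }
    if (length(cand) == 0) {
      stop(sprintf("rosette injection %d (arity %d) infeasible: no interior vertex available", ii, target))
    }
    cand <- cand[sample.int(length(cand))]
    done <- NULL
    for (v in cand[seq_len(min(20L, length(cand)))]) {
      done <- attempt(vg, v, target)
      if (!is.null(done)) { vg <- done; break }
    }
    if (is.null(done)) {
      stop(sprintf("rosette injection %d (arity %d) infeasible: local adjacency exhausted", ii, target))
    }
    used_near <- rbind(used_near, vg$pos[v, ])
  }
  # drop dead vertices
  keep <- which(vg$alive)
  remap <- stats::setNames(seq_along(keep), keep)
  vg$pos <- vg$pos[keep, , drop = FALSE]
  vg$seeds <- vg$seeds[keep]
  vg$cells <- vg$cells[keep]
  vg$adj <- lapply(vg$adj[keep], function(a) unname(remap[as.character(a)]))
  vg$injected <- vg$injected[keep]
  vg$alive <- rep(TRUE, length(keep))
  vg
}

# Rasterize the (possibly edge-collapsed) tessellation: every cell's
# polygon is its incident vertices ordered by angle around the seed;
# pixels are assigned by even-odd point-in-polygon over the polygon's
# bounding box, and any pixels left unassigned fall back to nearest-seed.
rasterize_tessellation <- function(vg, seeds, L) {
  n <- nrow(seeds)
  lab <- matrix(0L, L, L)
  for (i in seq_len(n)) {
    vs <- which(vapply(vg$cells, function(cl) i %in% cl, TRUE))
    if (length(vs) < 3) next
    P <- vg$pos[vs, , drop = FALSE]
    o <- order(atan2(P[, 2] - seeds[i, 2], P[, 1] - seeds[i, 1]))
    P <- P[o, , drop = FALSE]
    r0 <- max(1L, floor(min(P[, 1]) + 0.5)); r1 <- min(L, ceiling(max(P[, 1]) + 0.5))
    c0 <- max(1L, floor(min(P[, 2]) + 0.5)); c1 <- min(L, ceiling(max(P[, 2]) + 0.5))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    py <- rep(rows - 0.5, times = length(cols))
    px <- rep(cols - 0.5, each = length(rows))
    inside <- point_in_polygon(py, px, P[, 1], P[, 2])
    sub <- lab[rows, cols]
    sub[inside & sub == 0L] <- i
    lab[rows, cols] <- sub
  }
  # fill gaps by nearest seed
  miss <- which(lab == 0L)
  if (length(miss) > 0) {
    mr <- (miss - 1L) %% L + 0.5
    mc <- (miss - 1L) %/% L + 0.5
    CH <- 20000L
    for (s in seq(1, length(miss), by = CH)) {
      e <- min(length(miss), s + CH - 1L)
      d2 <- outer(mr[s:e]^2 + mc[s:e]^2, rep(1, n)) -
        2 * cbind(mr[s:e], mc[s:e]) %*% t(seeds) +
        outer(rep(1, e - s + 1L), rowSums(seeds^2))
      lab[miss[s:e]] <- max.col(-d2, ties.method = "first")
    }
  }
  lab
}

# Even-odd point-in-polygon test, vectorized over query points.
point_in_polygon <- function(qy, qx, vy, vx) {
  nv <- length(vy)
  inside <- rep(FALSE, length(qy))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vx[i] > qx) != (vx[j] > qx)) &
      (qy < (vy[j] - vy[i]) * (qx - vx[i]) / (vx[j] - vx[i]) + vy[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Pixels lying on a boundary between differently-labelled regions (or next
# to unlabeled background), to the requested total boundary width.
boundary_pixels <- function(lab, width) {
  L1 <- nrow(lab); L2 <- ncol(lab)
  r <- max(1L, as.integer(round(width / 2)))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= (r + 0.25)^2 & !(offs$dr == 0 & offs$dc == 0), ]
  b <- matrix(FALSE, L1, L2)
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rs <- max(1, 1 - dr):min(L1, L1 - dr)
    cs <- max(1, 1 - dc):min(L2, L2 - dc)
    shifted <- lab[rs + dr, cs + dc, drop = FALSE]
    here <- lab[rs, cs, drop = FALSE]
    diffm <- shifted != here
    bb <- b[rs, cs, drop = FALSE]
    b[rs, cs] <- bb | diffm
  }
  b
}
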