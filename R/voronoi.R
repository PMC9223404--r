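# Bounded Voronoi tessellation by half-plane clipping.
#
# Each site's cell starts as the bounding rectangle and is clipped by the
# perpendicular bisector against other sites, nearest first; a site farther
# than twice the current maximal vertex distance cannot cut the cell, which
# bounds the work per site.  Shared polygon corners computed independently
# by neighbouring cells coincide only up to round-off, so they are merged
# with a union-find pass over a spatial hash grid before the mesh is built.

clip_halfplane <- function(px, py, m, nrm) {
  val <- (px - m[1]) * nrm[1] + (py - m[2]) * nrm[2]
  keep <- val <= 0
  if (all(keep)) return(list(x = px, y = py))
  if (!any(keep)) return(list(x = numeric(0), y = numeric(0)))
  n <- length(px)
  nx <- numeric(2 * n); ny <- numeric(2 * n); cnt <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (keep[k]) {
      cnt <- cnt + 1L; nx[cnt] <- px[k]; ny[cnt] <- py[k]
    }
    if (keep[k] != keep[k2]) {
      t <- val[k] / (val[k] - val[k2])
      cnt <- cnt + 1L
      nx[cnt] <- px[k] + t * (px[k2] - px[k])
      ny[cnt] <- py[k] + t * (py[k2] - py[k])
    }
  }
  list(x = nx[seq_len(cnt)], y = ny[seq_len(cnt)])
}

voronoi_polygons <- function(pts, xlim, ylim) {
  n <- nrow(pts)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    px <- c(xlim[1], xlim[2], xlim[2], xlim[1])
    py <- c(ylim[1], ylim[1], ylim[2], ylim[2])
    p <- pts[i, ]
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    for (j in ord) {
      R2 <- max((px - p[1])^2 + (py - p[2])^2)
      if (d2[j] > 4 * R2) break
      m <- (p + pts[j, ]) / 2
      res <- clip_halfplane(px, py, m, pts[j, ] - p)
      px <- res$x; py <- res$y
      if (length(px) < 3) {
        abort("degenerate Voronoi cell", class = "epimech_degenerate_error")
      }
    }
    polys[[i]] <- cbind(px, py)
  }
  polys
}

# Merge near-coincident points (within tol) via union-find on a hash grid.
# Returns list(pos = merged coordinates, map = index into pos per input row).
merge_points <- function(xy, tol) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gx <- floor(xy[, 1] / tol); gy <- floor(xy[, 2] / tol)
  key <- paste(gx, gy)
  bins <- split(seq_len(n), key)
  binkey <- function(a, b) paste(a, b)
  for (cell in bins) {
    i0 <- cell[1]
    # link all points in this bin and the 8 neighbours within tol of i0's group
    for (dxx in -1:1) for (dyy in -1:1) {
      nb <- bins[[binkey(gx[i0] + dxx, gy[i0] + dyy)]]
      if (is.null(nb)) next
      for (i in cell) for (k in nb) {
        if (k <= i) next
        if (abs(xy[i, 1] - xy[k, 1]) <= tol && abs(xy[i, 2] - xy[k, 2]) <= tol) {
          ri <- find(i); rk <- find(k)
          if (ri != rk) parent[rk] <- ri
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  uroot <- unique(root)
  map <- match(root, uroot)
  pos <- cbind(rowsum(xy[, 1], map)[, 1], rowsum(xy[, 2], map)[, 1]) /
    as.vector(table(factor(map, levels = seq_along(uroot))))
  list(pos = pos, map = map)
}

# Voronoi mesh of random centroids in a rectangle with mean cell area A0.
voronoi_mesh <- function(n_rows, n_cols, A0) {
  s <- sqrt(A0)
  W <- n_cols * s; H <- n_rows * s
  n <- n_rows * n_cols
  for (attempt in 1:10) {
    pts <- cbind(runif(n, 0, W), runif(n, 0, H))
    dmin <- min(stats::dist(pts))
    if (dmin > 1e-7 * s) break
    if (attempt == 10) abort("could not place distinct centroids",
                             class = "epimech_degenerate_error")
  }
  polys <- voronoi_polygons(pts, c(0, W), c(0, H))
  xy <- do.call(rbind, polys)
  mp <- merge_points(xy, tol = 1e-8 * s)
  offsets <- c(0L, cumsum(vapply(polys, nrow, 0L)))
  loops <- lapply(seq_len(n), function(i) {
    ids <- mp$map[(offsets[i] + 1L):offsets[i + 1L]]
    ids[ids != c(ids[-1], ids[1])] # drop collapsed (consecutive duplicate) points
  })
  list(pos = mp$pos, loops = loops)
}
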