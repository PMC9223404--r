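# Internal flattened mesh representation.
#
# Heavy code paths (simulation steps, balance-system assembly) work on plain
# matrices and index vectors rather than tibbles.  The canonical topology is
# the set of counterclockwise cell loops; junctions are the unique undirected
# edges appearing in the loops (plus any isolated junction rows a tissue
# table may carry).

# key for an undirected vertex-pair (rows a, b of the position matrix)
edge_key <- function(a, b, V) pmin(a, b) * (V + 1) + pmax(a, b)

# Flatten loops into parallel entry vectors and derive adjacency.
# pos: V x 2 matrix; loops: list of integer vectors (rows into pos);
# jends: optional J x 2 matrix of prescribed junction endpoints (rows into
#   pos) -- used when a tissue supplies its own junction table.
flat_from_loops <- function(pos, loops, jends = NULL) {
  V <- nrow(pos)
  nv <- lengths(loops)
  C <- length(loops)
  if (C > 0 && any(nv < 3)) {
    abort("every cell needs at least 3 vertices", class = "epimech_validation_error")
  }
  loop_v <- as.integer(unlist(loops, use.names = FALSE))
  loop_cell <- rep.int(seq_len(C), nv)
  ends <- c(0L, cumsum(nv))
  off <- seq_along(loop_v) - rep.int(ends[-length(ends)], nv) # 1..nv within cell
  loop_next <- ifelse(off == nv[loop_cell], seq_along(loop_v) - nv[loop_cell] + 1L,
                      seq_along(loop_v) + 1L)
  loop_prev <- ifelse(off == 1L, seq_along(loop_v) + nv[loop_cell] - 1L,
                      seq_along(loop_v) - 1L)
  a <- loop_v; b <- loop_v[loop_next]
  if (any(a == b)) abort("cell loop repeats consecutive vertices",
                         class = "epimech_validation_error")
  key <- edge_key(a, b, V)
  if (is.null(jends)) {
    first <- !duplicated(key)
    jends <- cbind(a[first], b[first])
    jkey <- key[first]
  } else {
    jkey <- edge_key(jends[, 1], jends[, 2], V)
    if (anyDuplicated(jkey)) abort("duplicate junctions between the same vertex pair",
                                   class = "epimech_validation_error")
  }
  loop_j <- match(key, jkey)
  if (anyNA(loop_j)) {
    abort("cell loop edge has no corresponding junction",
          class = "epimech_validation_error")
  }
  J <- nrow(jends)
  jn_cells <- tabulate(loop_j, nbins = J)
  if (any(jn_cells > 2)) {
    abort("junction adjacent to more than two cells",
          class = "epimech_validation_error")
  }
  # junction -> adjacent cell indices (NA padded)
  jcells <- matrix(NA_integer_, J, 2)
  ord <- order(loop_j)
  pos_in_j <- sequence(jn_cells) # after ordering by junction
  jcells[cbind(loop_j[ord], pos_in_j)] <- loop_cell[ord]
  degree <- tabulate(c(jends[, 1], jends[, 2]), nbins = V)
  boundary_j <- jn_cells < 2L
  boundary_v <- logical(V)
  boundary_v[c(jends[boundary_j, 1], jends[boundary_j, 2])] <- TRUE
  list(V = V, J = J, C = C, pos = pos, ej = jends,
       loop_v = loop_v, loop_cell = loop_cell, loop_next = loop_next,
       loop_prev = loop_prev, loop_j = loop_j, cell_nv = nv,
       jn_cells = jn_cells, jcells = jcells, degree = degree,
       boundary_j = boundary_j, boundary_v = boundary_v, loops = loops)
}

# geometry derived from positions for a fixed topology
flat_geometry <- function(fm, pos = fm$pos) {
  d <- pos[fm$ej[, 2], , drop = FALSE] - pos[fm$ej[, 1], , drop = FALSE]
  l <- sqrt(d[, 1]^2 + d[, 2]^2)
  th <- atan2(d[, 2], d[, 1]) %% pi
  if (fm$C > 0) {
    xs <- pos[fm$loop_v, 1]; ys <- pos[fm$loop_v, 2]
    nxt <- fm$loop_next
    cross <- xs * pos[fm$loop_v[nxt], 2] - pos[fm$loop_v[nxt], 1] * ys
    A <- unname(rowsum(cross, fm$loop_cell)[, 1]) / 2
    perim <- unname(rowsum(l[fm$loop_j], fm$loop_cell)[, 1])
  } else {
    A <- numeric(0); perim <- numeric(0)
  }
  list(d = d, l = l, th = th, A = A, perim = perim)
}

# Build the flattened mesh for a tissue object, verifying consistency.
mesh_data <- function(tis, strict = TRUE) {
  v <- tis$vertices
  pos <- cbind(v$x, v$y)
  loops <- lapply(tis$cells$vertex_loop, function(lp) {
    idx <- match(lp, v$id)
    if (anyNA(idx)) abort(sprintf("cell loop vertex id %s does not resolve",
                                  lp[is.na(idx)][1]),
                          class = "epimech_validation_error")
    if (anyDuplicated(idx)) abort("cell loop repeats a vertex",
                                  class = "epimech_validation_error")
    idx
  })
  jends <- if (nrow(tis$junctions) > 0) {
    cbind(match(tis$junctions$v1, v$id), match(tis$junctions$v2, v$id))
  } else {
    matrix(integer(0), 0, 2)
  }
  if (anyNA(jends)) abort("junction endpoint id does not resolve",
                          class = "epimech_validation_error")
  fm <- flat_from_loops(pos, loops, jends)
  fm$frame <- v$frame_boundary
  fm$boundary_v <- fm$boundary_v | fm$frame
  g <- flat_geometry(fm)
  fm$jlen <- g$l; fm$jangle <- g$th; fm$carea <- g$A; fm$cperim <- g$perim
  if (strict) {
    if (fm$C > 0 && any(g$A <= 0)) {
      abort("cell loop is not a positively oriented simple polygon",
            class = "epimech_validation_error")
    }
    if (any(!fm$boundary_v & fm$degree < 3L)) {
      abort("interior vertex with degree < 3", class = "epimech_validation_error")
    }
  }
  fm
}

# Convert a simulator state (positions + loops) back into a tissue object.
# Drops vertices that belong to no loop (none arise in practice) and assigns
# fresh 0-based ids.
state_to_tissue <- function(pos, loops, provenance = "simulated") {
  fm <- flat_from_loops(pos, loops)
  vertices <- tibble(id = seq_len(fm$V) - 1L, x = pos[, 1], y = pos[, 2],
                     frame_boundary = FALSE)
  junctions <- tibble(id = seq_len(fm$J) - 1L,
                      v1 = fm$ej[, 1] - 1L, v2 = fm$ej[, 2] - 1L)
  cells <- tibble(id = seq_along(loops) - 1L,
                  vertex_loop = lapply(loops, function(i) as.integer(i - 1L)))
  tissue(vertices, junctions, cells, provenance = provenance)
}
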