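#' Construct a polygonal tissue
#'
#' A `tissue` is the geometric substrate of all estimation and simulation in
#' this package: a two-dimensional sheet of cells represented as polygons,
#' described by three tables. `vertices` holds point coordinates (in the
#' plane of the adherens junctions), `junctions` holds the straight edges
#' connecting vertex pairs, and `cells` holds counterclockwise vertex loops.
#' Junction/cell adjacency is derived from the loops, not stored.
#'
#' @param vertices Data frame with columns `id`, `x`, `y` and optionally
#'   `frame_boundary` (logical; marks vertices touching the image frame in
#'   segmented data).
#' @param junctions Data frame with columns `id`, `v1`, `v2` (vertex ids).
#' @param cells Data frame with columns `id` and `vertex_loop` (a list
#'   column of integer vectors, each a simple polygon with >= 3 vertices).
#'   Clockwise loops are reversed on construction so all loops are
#'   counterclockwise.
#' @param pixel_scale Physical length of one pixel (kept as metadata).
#' @param provenance `"simulated"` or `"segmented"`.
#' @param A0 For simulated tissues, the generating model's target cell
#'   area (kept as metadata; used by [preprocess_tissue()] to set the
#'   junction-length threshold).
#' @param validate Run [validate_tissue()] (default `TRUE`).
#' @return An object of class `tissue`: a list of tibbles
#'   (`vertices`, `junctions`, `cells`) plus `meta`.
#' @examples
#' tis <- unit_square_tissue()
#' cell_geometry(tis) # area 1, perimeter 4
#' @export
tissue <- function(vertices, junctions, cells, pixel_scale = 1,
                   provenance = c("simulated", "segmented"),
                   A0 = NULL, validate = TRUE) {
  provenance <- match.arg(provenance)
  vertices <- as_tibble(as.data.frame(vertices))
  junctions <- as_tibble(as.data.frame(junctions))
  cells <- as_tibble(cells)
  if (!"frame_boundary" %in% names(vertices)) {
    vertices$frame_boundary <- FALSE
  }
  vertices$frame_boundary[is.na(vertices$frame_boundary)] <- FALSE
  vertices <- vertices[, c("id", "x", "y", "frame_boundary")]
  junctions <- junctions[, c("id", "v1", "v2")]
  if (!"vertex_loop" %in% names(cells)) {
    abort("cells must have a 'vertex_loop' list column", class = "epimech_parse_error")
  }
  cells <- cells[, c("id", "vertex_loop")]
  cells$vertex_loop <- lapply(cells$vertex_loop, as.integer)
  vertices$id <- as.integer(vertices$id)
  junctions$id <- as.integer(junctions$id)
  junctions$v1 <- as.integer(junctions$v1)
  junctions$v2 <- as.integer(junctions$v2)
  cells$id <- as.integer(cells$id)

  tis <- structure(list(vertices = vertices, junctions = junctions,
                        cells = cells,
                        meta = list(pixel_scale = pixel_scale,
                                    provenance = provenance, A0 = A0)),
                   class = "tissue")
  # normalize loop orientation to counterclockwise
  if (nrow(cells) > 0) {
    idx <- match_ids(cells$vertex_loop, vertices$id, "cell loop vertex")
    areas <- vapply(idx, function(i) shoelace(vertices$x[i], vertices$y[i]), 0)
    flip <- which(areas < 0)
    for (i in flip) tis$cells$vertex_loop[[i]] <- rev(tis$cells$vertex_loop[[i]])
  }
  if (validate) validate_tissue(tis)
  tis
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("<tissue> %d vertices, %d junctions, %d cells (%s)\n",
              nrow(x$vertices), nrow(x$junctions), nrow(x$cells),
              x$meta$provenance))
  invisible(x)
}

shoelace <- function(x, y) {
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

match_ids <- function(ids, table, what) {
  if (is.list(ids)) return(lapply(ids, match_ids, table = table, what = what))
  idx <- match(ids, table)
  if (anyNA(idx)) {
    bad <- ids[is.na(idx)][1]
    abort(sprintf("%s id %s does not resolve", what, bad),
          class = "epimech_validation_error")
  }
  idx
}

#' Validate tissue invariants
#'
#' Checks id uniqueness and finiteness of coordinates, that junction
#' endpoints are distinct and resolvable, that every cell loop has at least
#' three distinct vertices with positive (counterclockwise) area, that every
#' loop edge corresponds to exactly one junction, that no junction borders
#' more than two cells, and that interior vertices (those not incident to a
#' boundary junction and not frame-flagged) have degree >= 3.
#'
#' @param tis A [tissue()].
#' @return `tis`, invisibly; errors of class `epimech_validation_error`
#'   otherwise.
#' @export
validate_tissue <- function(tis) {
  v <- tis$vertices; j <- tis$junctions; cl <- tis$cells
  if (anyDuplicated(v$id)) abort("duplicate vertex ids", class = "epimech_validation_error")
  if (anyDuplicated(j$id)) abort("duplicate junction ids", class = "epimech_validation_error")
  if (anyDuplicated(cl$id)) abort("duplicate cell ids", class = "epimech_validation_error")
  if (!all(is.finite(v$x)) || !all(is.finite(v$y))) {
    abort("vertex coordinates must be finite", class = "epimech_validation_error")
  }
  if (nrow(j) > 0) {
    match_ids(j$v1, v$id, "junction endpoint")
    match_ids(j$v2, v$id, "junction endpoint")
    if (any(j$v1 == j$v2)) abort("junction endpoints must be distinct",
                                 class = "epimech_validation_error")
  }
  mesh_data(tis) # builds adjacency; errors on inconsistency
  invisible(tis)
}

#' Junction lengths and orientations
#'
#' Euclidean length \eqn{l_{ij}} and orientation \eqn{\theta_{ij}} of each
#' junction. Orientation is measured from the +x axis and folded to
#' `[0, pi)` (a junction and its reverse have the same angle); every model
#' term uses \eqn{\cos 2(\theta-\varphi)} or \eqn{\sin 2\theta}, which are
#' pi-periodic.
#'
#' @param tis A [tissue()].
#' @param junction_id Optional vector of junction ids to restrict to.
#' @return Tibble with columns `id`, `length`, `angle`, `n_cells`.
#' @examples
#' junction_geometry(unit_square_tissue())
#' @export
junction_geometry <- function(tis, junction_id = NULL) {
  md <- mesh_data(tis, strict = FALSE)
  out <- tibble(id = tis$junctions$id,
                length = md$jlen, angle = md$jangle,
                n_cells = md$jn_cells)
  if (!is.null(junction_id)) {
    idx <- match(junction_id, out$id)
    if (anyNA(idx)) abort("unknown junction id", class = "epimech_key_error")
    out <- out[idx, ]
  }
  out
}

#' Cell areas and perimeters
#'
#' Shoelace area \eqn{A_i} and contour length \eqn{L_i} (the sum of the
#' cell's junction lengths) for each cell.
#'
#' @inheritParams junction_geometry
#' @param cell_id Optional vector of cell ids to restrict to.
#' @return Tibble with columns `id`, `area`, `perimeter`, `n_vertices`.
#' @export
cell_geometry <- function(tis, cell_id = NULL) {
  md <- mesh_data(tis, strict = FALSE)
  out <- tibble(id = tis$cells$id, area = md$carea, perimeter = md$cperim,
                n_vertices = md$cell_nv)
  if (!is.null(cell_id)) {
    idx <- match(cell_id, out$id)
    if (anyNA(idx)) abort("unknown cell id", class = "epimech_key_error")
    out <- out[idx, ]
  }
  out
}

#' Classify vertices as interior or boundary
#'
#' A vertex is `boundary` if it is incident to at least one boundary
#' junction (a junction bordering fewer than two cells) or carries the
#' `frame_boundary` flag supplied by the reader; otherwise it is
#' `interior`. Only interior vertices contribute force-balance equations.
#'
#' @inheritParams junction_geometry
#' @return Tibble with columns `id` and `class` (`"interior"` /
#'   `"boundary"`).
#' @examples
#' classify_vertices(unit_square_tissue()) # all boundary
#' @export
classify_vertices <- function(tis) {
  md <- mesh_data(tis, strict = FALSE)
  tibble(id = tis$vertices$id,
         class = ifelse(md$boundary_v, "boundary", "interior"))
}

#' Single unit-square test tissue
#'
#' One cell spanning the unit square: 4 vertices, 4 junctions, area 1,
#' perimeter 4. A minimal fixture used in examples and tests.
#'
#' @return A [tissue()].
#' @export
unit_square_tissue <- function() {
  tissue(
    vertices = data.frame(id = 0:3, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
    junctions = data.frame(id = 0:3, v1 = c(0, 1, 2, 3), v2 = c(1, 2, 3, 0)),
    cells = tibble(id = 0L, vertex_loop = list(0:3))
  )
}
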