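#' Read and write tissues in the interchange formats
#'
#' Two plain-text formats are supported, both carrying the same content:
#'
#' * **json** -- a single file with top-level keys `vertices`
#'   (`id`, `x`, `y`, optional `frame_boundary`), `junctions`
#'   (`id`, `v1`, `v2`), `cells` (`id`, `vertex_loop` array), and `meta`
#'   (`pixel_scale`, `provenance`). This is the format one would produce
#'   from a skeletonized segmentation of adherens-junction images.
#' * **csv** -- a directory holding `vertices.csv`, `junctions.csv` and
#'   `cells.csv` with the same columns (`vertex_loop` is `|`-separated),
#'   plus an optional `meta.csv`.
#'
#' Coordinates are written with 17 significant digits so that
#' `read_tissue(write_tissue(t, p))` reproduces the geometry bit-exactly.
#' Clockwise cell loops are reversed on load; all loaded tissues are
#' validated.
#'
#' @param path File (json) or directory (csv) path.
#' @param format `"auto"` (by extension), `"json"`, or `"csv"`.
#' @param tis A [tissue()].
#' @return `read_tissue()`: a [tissue()]. `write_tissue()`: `path`,
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_tissue(unit_square_tissue(), p)
#' read_tissue(p)
#' @export
read_tissue <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "csv" else "json"
  if (format == "json") {
    if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path),
                                  class = "epimech_io_error")
    raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                    error = function(e) abort(
                      sprintf("could not parse '%s': %s", path, conditionMessage(e)),
                      class = "epimech_parse_error"))
    vertices <- io_table(raw$vertices, c("id", "x", "y"))
    junctions <- io_table(raw$junctions, c("id", "v1", "v2"))
    cells <- raw$cells
    if (is.null(cells) || length(cells) == 0 || NROW(cells) == 0) {
      cells <- tibble(id = integer(0), vertex_loop = list())
    } else {
      cells <- tibble(id = cells$id,
                      vertex_loop = lapply(cells$vertex_loop, as.integer))
    }
    meta <- raw$meta
  } else {
    rd <- function(f) {
      fp <- file.path(path, f)
      if (!file.exists(fp)) abort(sprintf("file '%s' does not exist", fp),
                                  class = "epimech_io_error")
      utils::read.csv(fp)
    }
    vertices <- io_table(rd("vertices.csv"), c("id", "x", "y"))
    junctions <- io_table(rd("junctions.csv"), c("id", "v1", "v2"))
    cdf <- rd("cells.csv")
    cells <- tibble(id = as.integer(cdf$id),
                    vertex_loop = lapply(strsplit(as.character(cdf$vertex_loop),
                                                  "|", fixed = TRUE),
                                         as.integer))
    meta <- NULL
    if (file.exists(file.path(path, "meta.csv"))) {
      meta <- as.list(utils::read.csv(file.path(path, "meta.csv")))
    }
  }
  tissue(vertices, junctions, cells,
         pixel_scale = meta$pixel_scale %||% 1,
         provenance = meta$provenance %||% "segmented",
         A0 = meta$A0)
}

io_table <- function(df, cols) {
  if (is.null(df) || NROW(df) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
          class = "epimech_parse_error")
  }
  df
}

#' @rdname read_tissue
#' @export
write_tissue <- function(tis, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  }
  if (format == "json") {
    payload <- list(
      vertices = tis$vertices,
      junctions = tis$junctions,
      cells = list(id = tis$cells$id, vertex_loop = tis$cells$vertex_loop),
      meta = tis$meta
    )
    # keep cells as records with array-valued loops
    payload$cells <- lapply(seq_len(nrow(tis$cells)), function(i) {
      list(id = tis$cells$id[i], vertex_loop = tis$cells$vertex_loop[[i]])
    })
    json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                             digits = I(17), null = "null")
    ok <- tryCatch({ writeLines(json, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("cannot write to '%s'", path), class = "epimech_io_error")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    num <- function(x) formatC(x, digits = 17, format = "g")
    v <- tis$vertices; v$x <- num(v$x); v$y <- num(v$y)
    utils::write.csv(v, file.path(path, "vertices.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(tis$junctions, file.path(path, "junctions.csv"),
                     row.names = FALSE, quote = FALSE)
    cdf <- data.frame(id = tis$cells$id,
                      vertex_loop = vapply(tis$cells$vertex_loop, paste,
                                           "", collapse = "|"))
    utils::write.csv(cdf, file.path(path, "cells.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(as.data.frame(tis$meta), file.path(path, "meta.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
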