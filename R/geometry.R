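#' Area and perimeter of a simple polygon
#'
#' Computes the enclosed area (shoelace formula, absolute value of the signed
#' area) and the perimeter (sum of consecutive edge lengths, including the
#' closing edge) of a polygonal ring.
#'
#' @param coords A numeric matrix (or data frame) with two columns, the x and
#'   y coordinates of the ring in order. The closing edge from the last to the
#'   first point is implied.
#' @return A one-row tibble with columns `area` and `perimeter`.
#' @examples
#' polygon_metrics(rbind(c(0, 0), c(1, 0), c(0, 1)))
#' @export
polygon_metrics <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) {
    abort("a polygon needs at least 3 vertices", class = "extrudr_invalid_polygon")
  }
  if (ncol(coords) != 2 || !all(is.finite(coords))) {
    abort("`coords` must be a finite 2-column matrix", class = "extrudr_invalid_polygon")
  }
  x <- coords[, 1]; y <- coords[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  area <- abs(sum(x * ys - xs * y)) / 2
  perimeter <- sum(sqrt((xs - x)^2 + (ys - y)^2))
  if (area <= 0) {
    abort("degenerate polygon with zero area", class = "extrudr_degenerate_polygon")
  }
  tibble(area = area, perimeter = perimeter)
}

#' Circularity of a shape
#'
#' Circularity is defined as `4 * pi * area / perimeter^2`. It equals 1 for a
#' circle and is below 1 for any simple polygon; it is invariant under
#' uniform rescaling of the shape.
#'
#' @param area,perimeter Positive scalars (vectorised).
#' @return Dimensionless circularity values.
#' @examples
#' circularity(1, 4) # unit square: pi / 4
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    abort("`area` and `perimeter` must be positive and finite",
          class = "extrudr_domain_error")
  }
  4 * pi * area / perimeter^2
}

#' Construct a tissue mesh
#'
#' A `tissue_mesh` is a polygonal tessellation: vertex positions, per-cell
#' vertex rings (counter-clockwise), and per-cell mechanical state (resting
#' area, perimeter contractility, tracked flag). Edges and their boundary
#' flags are derived from the face rings: an edge bordering a single face is
#' a tissue-boundary edge.
#'
#' @param vertices Numeric matrix with columns x, y (one row per vertex).
#' @param faces List of integer vectors; each is an ordered, counter-clockwise
#'   ring of vertex indices.
#' @param resting_area Per-face resting area \eqn{A^{(0)}} (default 1).
#' @param contractility Per-face dimensionless contractility (default 0.02).
#' @param tracked Logical per-face flag (default all `FALSE`).
#' @param validate Check mesh invariants on construction (default `TRUE`)?
#' @return An object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(vertices, faces,
                        resting_area = rep(1, length(faces)),
                        contractility = rep(0.02, length(faces)),
                        tracked = rep(FALSE, length(faces)),
                        validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  faces <- lapply(faces, as.integer)
  mesh <- structure(
    list(vertices = vertices, faces = faces,
         resting_area = as.double(resting_area),
         contractility = as.double(contractility),
         tracked = as.logical(tracked)),
    class = "tissue_mesh")
  # enforce the counter-clockwise orientation convention
  for (f in seq_along(mesh$faces)) {
    ring <- mesh$faces[[f]]
    if (signed_area(vertices[ring, , drop = FALSE]) < 0) {
      mesh$faces[[f]] <- rev(ring)
    }
  }
  if (validate) {
    v <- validate_mesh(mesh)
    if (nrow(v) > 0) {
      abort(paste0("invalid mesh: ", paste(unique(v$violation), collapse = "; ")),
            class = "extrudr_invalid_mesh")
    }
  }
  mesh
}

signed_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @export
print.tissue_mesh <- function(x, ...) {
  e <- mesh_edges(x)
  cat(sprintf("<tissue_mesh> %d cells, %d vertices, %d edges (%d boundary), %d tracked\n",
              length(x$faces), nrow(x$vertices), nrow(e), sum(e$boundary),
              sum(x$tracked)))
  invisible(x)
}

#' Edge table of a mesh
#'
#' @param mesh A `tissue_mesh`.
#' @return A tibble with columns `v1`, `v2` (vertex indices, `v1 < v2`),
#'   `boundary` (does the edge border a single face?) and `n_faces`.
#' @export
mesh_edges <- function(mesh) {
  rings <- mesh$faces
  a <- unlist(lapply(rings, function(r) r))
  b <- unlist(lapply(rings, function(r) c(r[-1], r[1])))
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  cnt <- table(key)
  first <- !duplicated(key)
  tibble(v1 = lo[first], v2 = hi[first],
         n_faces = as.integer(cnt[key[first]])) |>
    dplyr::mutate(boundary = .data$n_faces == 1L) |>
    dplyr::arrange(.data$v1, .data$v2)
}

#' Per-cell shape observables of a mesh
#'
#' @param x A `tissue_mesh`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `cell`, `area`, `perimeter`,
#'   `circularity`, `resting_area`, `contractility`, `tracked`, `n_vertices`.
#' @export
tidy.tissue_mesh <- function(x, ...) {
  m <- purrr::map_dfr(x$faces, function(ring) {
    polygon_metrics(x$vertices[ring, , drop = FALSE])
  })
  tibble(cell = seq_along(x$faces),
         area = m$area, perimeter = m$perimeter,
         circularity = circularity(m$area, m$perimeter),
         resting_area = x$resting_area,
         contractility = x$contractility,
         tracked = x$tracked,
         n_vertices = lengths(x$faces))
}

#' @export
glance.tissue_mesh <- function(x, ...) {
  td <- tidy(x)
  e <- mesh_edges(x)
  tibble(n_cells = nrow(td), n_vertices = nrow(x$vertices), n_edges = nrow(e),
         n_boundary_edges = sum(e$boundary),
         mean_area = mean(td$area), mean_perimeter = mean(td$perimeter),
         mean_circularity = mean(td$circularity))
}

#' @export
autoplot.tissue_mesh <- function(object, fill = "circularity", ...) {
  td <- tidy(object)
  poly <- purrr::map_dfr(seq_along(object$faces), function(f) {
    ring <- object$faces[[f]]
    tibble(cell = f, x = object$vertices[ring, 1], y = object$vertices[ring, 2])
  }) |>
    dplyr::left_join(td, by = "cell")
  ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y, group = .data$cell,
                                     fill = .data[[fill]])) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Validate a tissue mesh
#'
#' Checks every mesh invariant: each face is a simple, positively oriented
#' polygon with at least 3 vertices and non-negative resting area; every edge
#' borders one (boundary) or two (internal) faces; and the Euler relation
#' V - E + F = 1 holds for a disk-topology tissue.
#'
#' @param mesh A `tissue_mesh`.
#' @return A tibble of violations (zero rows for a valid mesh) with columns
#'   `element` (what is at fault) and `violation`.
#' @export
validate_mesh <- function(mesh) {
  out <- list()
  add <- function(element, violation) {
    out[[length(out) + 1]] <<- tibble(element = element, violation = violation)
  }
  nv <- nrow(mesh$vertices)
  for (f in seq_along(mesh$faces)) {
    ring <- mesh$faces[[f]]
    lab <- paste0("face ", f)
    if (length(ring) < 3) { add(lab, "fewer than 3 vertices"); next }
    if (any(ring < 1 | ring > nv)) { add(lab, "vertex index out of range"); next }
    if (anyDuplicated(ring)) add(lab, "repeated vertex in ring")
    coords <- mesh$vertices[ring, , drop = FALSE]
    if (signed_area(coords) <= 1e-12) add(lab, "non-positive signed area")
    if (!cpp_ring_simple(coords)) add(lab, "non-simple polygon")
    if (mesh$resting_area[f] < 0) add(lab, "negative resting area")
  }
  e <- mesh_edges(mesh)
  bad <- e$n_faces > 2L
  if (any(bad)) {
    for (i in which(bad)) {
      add(paste0("edge ", e$v1[i], "-", e$v2[i]),
          sprintf("bordered by %d faces", e$n_faces[i]))
    }
  }
  euler <- nv - nrow(e) + length(mesh$faces)
  if (euler != 1L) add("mesh", sprintf("Euler relation V - E + F = %d != 1", euler))
  if (length(out) == 0) {
    tibble(element = character(), violation = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Write a mesh snapshot to a versioned JSON file
#'
#' The snapshot format (`"tissue-mesh/1"`) stores vertices, edges with their
#' boundary flags, and faces with their rings and per-cell mechanical state.
#' Round-tripping through [read_mesh()] is lossless to full double precision.
#'
#' @param mesh A `tissue_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  e <- mesh_edges(mesh)
  obj <- list(
    format = "tissue-mesh/1",
    vertices = data.frame(id = seq_len(nrow(mesh$vertices)),
                          x = mesh$vertices[, 1], y = mesh$vertices[, 2]),
    edges = data.frame(v1 = e$v1, v2 = e$v2, boundary = e$boundary),
    faces = lapply(seq_along(mesh$faces), function(f) {
      list(id = f, ring = mesh$faces[[f]],
           resting_area = mesh$resting_area[f],
           contractility = mesh$contractility[f],
           tracked = mesh$tracked[f])
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mesh snapshot written by [write_mesh()]
#'
#' @param path Path to a `"tissue-mesh/1"` JSON snapshot.
#' @return A `tissue_mesh`.
#' @export
read_mesh <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "tissue-mesh/1")) {
    abort(sprintf("unknown mesh format '%s'", obj$format %||% "<missing>"),
          class = "extrudr_parse_error")
  }
  faces <- obj$faces
  tissue_mesh(
    vertices = cbind(obj$vertices$x, obj$vertices$y),
    faces = lapply(faces$ring, as.integer),
    resting_area = faces$resting_area,
    contractility = faces$contractility,
    tracked = faces$tracked)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
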