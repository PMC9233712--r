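# Hand-built meshes and an R-level reference energy, independent of the
# compiled implementation.

# single square cell with unit side
square_mesh <- function(resting_area = 1, contractility = 0.02) {
  tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4),
              resting_area = resting_area, contractility = contractility)
}

# single regular hexagon; side chosen so the area is `area`
hexagon_mesh <- function(area = 1, contractility = 0.02, resting_area = 1) {
  side <- sqrt(2 * area / (3 * sqrt(3)))  # circumradius equals the side
  th <- pi / 6 + seq(0, 5) * pi / 3
  tissue_mesh(cbind(side * cos(th), side * sin(th)),
              list(1:6), resting_area = resting_area,
              contractility = contractility)
}

# four cells around a short central edge: the classic T1 fixture.
# Central edge (v1, v2) of length `gap` is shared by the left and right
# cells; the top cell touches only v1, the bottom cell only v2.
quartet_mesh <- function(gap = 0.15) {
  h <- gap / 2
  v <- rbind(c(0, h),        # 1: top end of the central edge
             c(0, -h),       # 2: bottom end
             c(-0.7, 0.7),   # 3
             c(0.7, 0.7),    # 4
             c(0.7, -0.7),   # 5
             c(-0.7, -0.7),  # 6
             c(0, 1),        # 7 top apex
             c(0, -1),       # 8 bottom apex
             c(-1, 0),       # 9 left apex
             c(1, 0))        # 10 right apex
  faces <- list(
    c(3, 1, 4, 7),     # top cell (touches v1 only)
    c(6, 8, 5, 2),     # bottom cell (touches v2 only)
    c(3, 9, 6, 2, 1),  # left cell (central edge 1-2)
    c(4, 1, 2, 5, 10)) # right cell (central edge 2-1)
  tissue_mesh(v, faces)
}

# reference tissue energy written against the formulas directly
ref_energy <- function(mesh, params = model_params()) {
  areas <- vapply(mesh$faces, function(r) {
    abs(signed_area_ref(mesh$vertices[r, , drop = FALSE]))
  }, 0)
  perims <- vapply(mesh$faces, function(r) {
    xy <- mesh$vertices[r, , drop = FALSE]
    nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
    sum(sqrt(rowSums((nxt - xy)^2)))
  }, 0)
  elastic <- ifelse(mesh$resting_area >= params$a0_min,
                    0.5 * (areas / mesh$resting_area - 1)^2,
                    0.5 * (areas - mesh$resting_area)^2)
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e$v1, , drop = FALSE] -
                         mesh$vertices[e$v2, , drop = FALSE])^2))
  tension <- params$line_tension_tilde *
    ifelse(e$boundary, params$boundary_tension_factor, 1)
  sum(elastic) + sum(tension * len) +
    sum(mesh$contractility / 2 * perims^2)
}

signed_area_ref <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# face adjacency pairs (which faces share an internal edge)
face_adjacency <- function(mesh) {
  a <- unlist(mesh$faces)
  b <- unlist(lapply(mesh$faces, function(r) c(r[-1], r[1])))
  f <- rep(seq_along(mesh$faces), lengths(mesh$faces))
  key <- paste(pmin(a, b), pmax(a, b))
  pairs <- split(f, key)
  do.call(rbind, lapply(pairs[lengths(pairs) == 2],
                        function(p) sort(p)))
}
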