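#' Build a disordered initial tissue
#'
#' Seeds `n_cells` uniform random points in a disk, builds their Voronoi
#' tessellation (clipped to the disk by reflecting every seed across the disk
#' boundary, so that boundary cells close along the circle), applies a number
#' of Lloyd relaxation steps, and rescales coordinates so that the mean cell
#' area equals `initial_area_ratio` times the resting area. All cells start
#' with resting area 1 and the contractility from `params`.
#'
#' @param n_cells Number of cells (>= 3).
#' @param seed Integer seed; the construction is deterministic per seed.
#' @param initial_area_ratio Mean initial cell area in units of the resting
#'   area (default 3.7, the pre-stretch implied by the reported initial
#'   perimeter and circularity of the tracked cells; see [sim_config()]).
#' @param lloyd_steps Number of Lloyd (centroidal Voronoi) relaxation steps
#'   (default 3): more steps give a more ordered, higher-circularity packing.
#' @param params A [model_params()] object (supplies the initial
#'   contractility).
#' @return A `tissue_mesh` with `n_cells` faces and disk topology.
#' @export
build_initial_tissue <- function(n_cells, seed, initial_area_ratio = 3.7,
                                 lloyd_steps = 3, params = model_params()) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 3) {
    abort("`n_cells` must be at least 3", class = "extrudr_parameter_error")
  }
  set.seed(seed)
  R <- sqrt(n_cells / pi)  # unit mean area before rescaling
  r <- R * sqrt(runif(n_cells))
  th <- 2 * pi * runif(n_cells)
  pts <- cbind(r * cos(th), r * sin(th))
  for (step in seq_len(lloyd_steps)) {
    cells <- voronoi_cells(pts, R)
    pts <- t(vapply(cells$coords, polygon_centroid, numeric(2)))
  }
  cells <- voronoi_cells(pts, R)

  # vertex per Delaunay triangle (circumcenter), shared across adjacent cells;
  # merge circumcenters of (near-)cocircular quadruples
  used <- sort(unique(unlist(cells$rings)))
  cc <- cells$circumcenters
  key <- paste(round(cc[used, 1] / 1e-9), round(cc[used, 2] / 1e-9))
  canon <- used[match(key, key)]
  remap <- integer(max(used))
  remap[used] <- match(canon, used[!duplicated(key)])
  keep <- used[!duplicated(key)]
  vertices <- cc[keep, , drop = FALSE]
  faces <- lapply(cells$rings, function(ring) {
    ids <- remap[ring]
    prev <- c(ids[length(ids)], ids[-length(ids)])
    ids[ids != prev]  # drop consecutive duplicates (merged circumcenters)
  })

  mesh <- tissue_mesh(vertices, faces,
                      resting_area = rep(1, n_cells),
                      contractility = rep(params$contractility_tilde, n_cells),
                      tracked = rep(FALSE, n_cells))
  areas <- tidy(mesh)$area
  scale <- sqrt(initial_area_ratio / mean(areas))
  mesh$vertices <- mesh$vertices * scale
  mesh
}

# Voronoi cells of `pts` inside a disk of radius R: every point is reflected
# across the circle so that all real cells are bounded and adjacent cells
# share exact circumcenter vertices.
voronoi_cells <- function(pts, R) {
  n <- nrow(pts)
  nrm <- sqrt(rowSums(pts^2))
  dir <- pts / pmax(nrm, 1e-12)
  mirror <- dir * (2 * R - nrm)
  all_pts <- rbind(pts, mirror)
  d <- cpp_delaunay(all_pts[, 1], all_pts[, 2])
  tmat <- d$triangles
  cc <- d$circumcenters
  inc <- split(rep(seq_len(nrow(tmat)), 3), as.vector(tmat))
  rings <- vector("list", n)
  coords <- vector("list", n)
  for (s in seq_len(n)) {
    tris <- inc[[as.character(s)]]
    if (is.null(tris) || length(tris) < 3) {
      abort("degenerate Voronoi cell; try a different seed",
            class = "extrudr_construction_error")
    }
    ang <- atan2(cc[tris, 2] - pts[s, 2], cc[tris, 1] - pts[s, 1])
    ord <- order(ang)
    rings[[s]] <- tris[ord]
    coords[[s]] <- cc[tris[ord], , drop = FALSE]
  }
  list(rings = rings, coords = coords, circumcenters = cc)
}

polygon_centroid <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Select interior cells to track
#'
#' Marks `n` cells as tracked, each at least `min_boundary_distance`
#' cell-adjacency steps away from any boundary cell (a boundary cell is one
#' with an edge on the tissue margin), drawn uniformly at random.
#'
#' @param mesh A `tissue_mesh`.
#' @param n Number of cells to track.
#' @param seed Integer seed (deterministic selection per seed).
#' @param min_boundary_distance Minimum graph distance from the boundary, in
#'   cell-adjacency steps (default 3).
#' @return The mesh with `tracked` flags set; the selected face ids are in
#'   `attr(, "selected")` and equal `which(mesh$tracked)`.
#' @export
select_tracked_cells <- function(mesh, n, seed, min_boundary_distance = 3) {
  n <- as.integer(n)
  if (n == 0) {
    attr(mesh, "selected") <- integer()
    return(mesh)
  }
  dist <- boundary_distance(mesh)
  eligible <- which(dist >= min_boundary_distance)
  if (length(eligible) < n) {
    abort(sprintf(
      "only %d cells lie >= %d steps from the boundary (requested %d)",
      length(eligible), min_boundary_distance, n),
      class = "extrudr_selection_error")
  }
  set.seed(seed)
  sel <- eligible[sample.int(length(eligible), n)]
  mesh$tracked[sel] <- TRUE
  attr(mesh, "selected") <- sort(sel)
  mesh
}

# graph distance of every face from the boundary faces (boundary = 0)
boundary_distance <- function(mesh) {
  nf <- length(mesh$faces)
  a <- unlist(mesh$faces)
  b <- unlist(lapply(mesh$faces, function(r) c(r[-1], r[1])))
  f <- rep(seq_len(nf), lengths(mesh$faces))
  key <- paste(pmin(a, b), pmax(a, b))
  by_edge <- split(f, key)
  adj <- vector("list", nf)
  boundary <- logical(nf)
  for (fs in by_edge) {
    if (length(fs) == 1) boundary[fs] <- TRUE
    if (length(fs) == 2) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  dist <- rep(NA_integer_, nf)
  queue <- which(boundary)
  dist[queue] <- 0L
  while (length(queue) > 0) {
    f <- queue[1]; queue <- queue[-1]
    for (g in adj[[f]]) {
      if (is.na(dist[g])) {
        dist[g] <- dist[f] + 1L
        queue <- c(queue, g)
      }
    }
  }
  dist[is.na(dist)] <- nf  # isolated from boundary (cannot happen on a disk)
  dist
}
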