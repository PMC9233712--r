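test_that("polygon metrics match closed-form geometry", {
  tri <- polygon_metrics(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(tri$area, 0.5)
  expect_equal(tri$perimeter, 2 + sqrt(2))

  sq <- polygon_metrics(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)

  th <- seq(0, 5) * pi / 3
  hex <- polygon_metrics(cbind(cos(th), sin(th)))  # regular, side 1
  expect_equal(hex$area, 3 * sqrt(3) / 2)
  expect_equal(hex$perimeter, 6)

  expect_error(polygon_metrics(rbind(c(0, 0), c(1, 1))),
               class = "extrudr_invalid_polygon")
  expect_error(polygon_metrics(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "extrudr_degenerate_polygon")
})

test_that("circularity has its closed-form values and is scale invariant", {
  r <- 2.3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(1, 4), pi / 4)
  expect_equal(circularity(3 * sqrt(3) / 2, 6), pi * sqrt(3) / 6)
  expect_error(circularity(-1, 2), class = "extrudr_domain_error")
  expect_error(circularity(1, 0), class = "extrudr_domain_error")

  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    th <- sort(runif(n, 0, 2 * pi))
    rad <- runif(n, 0.5, 1.5)
    xy <- cbind(rad * cos(th), rad * sin(th))  # star-convex: simple
    k <- runif(1, 0.1, 10)
    m1 <- polygon_metrics(xy)
    m2 <- polygon_metrics(xy * k)
    expect_lte(circularity(m1$area, m1$perimeter), 1)
    expect_equal(circularity(m1$area, m1$perimeter),
                 circularity(m2$area, m2$perimeter), tolerance = 1e-12)
  }
})

test_that("tissue_mesh enforces counter-clockwise orientation", {
  m <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(c(4, 3, 2, 1)))
  expect_gt(signed_area_ref(m$vertices[m$faces[[1]], ]), 0)
})

test_that("validate_mesh reports the specific violations", {
  expect_equal(nrow(validate_mesh(square_mesh())), 0)

  # bowtie: self-crossing ring
  bow <- tissue_mesh(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                     list(1:4), validate = FALSE)
  v <- validate_mesh(bow)
  expect_true(any(grepl("non-simple", v$violation)))

  # an edge referenced by three faces
  tri3 <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(0.5, 1), c(0.5, -1),
                            c(1.5, 0.5)),
                      list(c(1, 2, 3), c(1, 4, 2), c(1, 2, 5)),
                      validate = FALSE)
  v <- validate_mesh(tri3)
  expect_true(any(grepl("bordered by 3 faces", v$violation)))
})

test_that("mesh JSON snapshots round-trip losslessly", {
  m <- build_initial_tissue(40, seed = 7)
  m$tracked[c(3, 11)] <- TRUE
  m$contractility[5] <- 0.123456789012345
  path <- withr::local_tempfile(fileext = ".json")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$resting_area, m$resting_area, tolerance = 1e-12)
  expect_equal(m2$contractility, m$contractility, tolerance = 1e-12)
  expect_identical(m2$tracked, m$tracked)
  expect_error(read_mesh(withr::local_tempfile(lines = '{"format":"x"}')),
               class = "extrudr_parse_error")
})

test_that("built tissues satisfy every mesh invariant", {
  for (n in c(50, 150)) {
    m <- build_initial_tissue(n, seed = n)
    expect_length(m$faces, n)
    expect_equal(nrow(validate_mesh(m)), 0)
    e <- mesh_edges(m)
    expect_setequal(unique(e$n_faces), c(1L, 2L))
    expect_identical(nrow(m$vertices) - nrow(e) + length(m$faces), 1L)
  }
  expect_error(build_initial_tissue(2, seed = 1),
               class = "extrudr_parameter_error")
})

test_that("tissue construction is bitwise reproducible per seed", {
  a <- build_initial_tissue(80, seed = 123)
  b <- build_initial_tissue(80, seed = 123)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  c2 <- build_initial_tissue(80, seed = 124)
  expect_false(identical(a$vertices, c2$vertices))
})

test_that("the initial area scale is set by initial_area_ratio", {
  m <- build_initial_tissue(60, seed = 3, initial_area_ratio = 2.5)
  expect_equal(mean(tidy(m)$area), 2.5, tolerance = 1e-9)
})

test_that("tracked-cell selection respects the boundary distance", {
  m <- build_initial_tissue(200, seed = 9)
  m2 <- select_tracked_cells(m, 10, seed = 1, min_boundary_distance = 2)
  sel <- which(m2$tracked)
  expect_length(sel, 10)
  expect_identical(attr(m2, "selected"), sel)

  # no selected face touches the boundary, nor do its neighbours
  e <- mesh_edges(m)
  adj <- face_adjacency(m)
  boundary_faces <- unique(unlist(lapply(seq_along(m$faces), function(f) {
    ring <- m$faces[[f]]
    keys <- paste(pmin(ring, c(ring[-1], ring[1])),
                  pmax(ring, c(ring[-1], ring[1])))
    bkeys <- paste(e$v1[e$boundary], e$v2[e$boundary])
    if (any(keys %in% bkeys)) f else NULL
  })))
  expect_length(intersect(sel, boundary_faces), 0)
  nb <- unique(c(adj[adj[, 1] %in% sel, 2], adj[adj[, 2] %in% sel, 1]))
  expect_length(intersect(nb, boundary_faces), 0)

  # deterministic and empty-selection behaviour
  m3 <- select_tracked_cells(m, 10, seed = 1, min_boundary_distance = 2)
  expect_identical(which(m3$tracked), sel)
  m0 <- select_tracked_cells(m, 0, seed = 1)
  expect_length(which(m0$tracked), 0)

  expect_error(select_tracked_cells(m, 10, seed = 1,
                                    min_boundary_distance = 50),
               class = "extrudr_selection_error")
})
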