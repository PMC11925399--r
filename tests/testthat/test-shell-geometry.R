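test_that("cell geometry matches closed forms on planar fixtures", {
  sq <- cell_patch(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                   list(1:4))
  g <- build_cell_geometry(sq, 1)
  expect_equal(g$center, c(0.5, 0.5, 0))
  expect_equal(g$area, 1)
  expect_equal(g$normal, c(0, 0, 1))

  tr <- regular_polygon_patch(3, edge = 1)
  expect_equal(build_cell_geometry(tr, 1)$area, sqrt(3) / 4,
               tolerance = 1e-12)
})

test_that("non-planar cell area equals the per-triangle cross-product oracle", {
  quad <- cell_patch(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0.2),
                           c(0, 1, 0)), list(1:4))
  g <- build_cell_geometry(quad, 1)
  # independent oracle: explicit fan through the vertex mean
  V <- quad$positions
  ctr <- colMeans(V)
  oracle <- 0
  for (k in 1:4) {
    a <- V[k, ] - ctr
    b <- V[k %% 4 + 1, ] - ctr
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    oracle <- oracle + 0.5 * sqrt(sum(cr^2))
  }
  expect_equal(g$area, oracle, tolerance = 1e-14)
})

test_that("enclosed volume is exact and translation invariant", {
  sh <- cube_shell()
  expect_equal(enclosed_volume(sh), 1, tolerance = 1e-14)
  sh$positions <- sh$positions +
    matrix(c(10, -3, 7), nrow(sh$positions), 3, byrow = TRUE)
  expect_equal(enclosed_volume(sh), 1, tolerance = 1e-12)

  ic <- icosahedron_shell()
  # divergence-theorem oracle on the same triangles: V = (1/3) sum_t
  # A_t * (centroid . n_t)
  oracle <- 0
  for (f in ic$cells) {
    V <- ic$positions[f, ]
    cr <- c((V[2, 2] - V[1, 2]) * (V[3, 3] - V[1, 3]) -
              (V[2, 3] - V[1, 3]) * (V[3, 2] - V[1, 2]),
            (V[2, 3] - V[1, 3]) * (V[3, 1] - V[1, 1]) -
              (V[2, 1] - V[1, 1]) * (V[3, 3] - V[1, 3]),
            (V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
              (V[2, 2] - V[1, 2]) * (V[3, 1] - V[1, 1]))
    oracle <- oracle + sum(colMeans(V) * cr / 2) / 3
  }
  expect_equal(enclosed_volume(ic), oracle, tolerance = 1e-12)
})

test_that("dihedral angles match the independent normals oracle", {
  sh <- cube_shell()
  g <- shell_geometry(sh)
  expect_equal(unname(g$dihedrals), rep(pi / 2, 12), tolerance = 1e-12)

  flat <- cell_patch(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                           c(0, 1, 0), c(2, 0, 0), c(2, 1, 0)),
                     list(c(1, 2, 3, 4), c(2, 5, 6, 3)))
  k <- shell_geometry(flat)
  shared <- which(flat$bonds[, "c1"] != flat$bonds[, "c2"])
  expect_equal(k$dihedrals[shared], 0, tolerance = 1e-12)

  ic <- icosahedron_shell()
  gi <- shell_geometry(ic)
  b1 <- 1L
  c1 <- ic$bonds[b1, "c1"]; c2 <- ic$bonds[b1, "c2"]
  oracle <- acos(sum(gi$normals[c1, ] * gi$normals[c2, ]))
  expect_equal(dihedral_angle(ic, b1), oracle, tolerance = 1e-12)
})

test_that("graph distances are BFS distances", {
  sh <- cube_shell()
  expect_equal(graph_distances(sh, 1), c(0L, 2L, 1L, 1L, 1L, 1L))
  expect_equal(graph_distances(sh, seq_along(sh$cells)),
               rep(0L, 6))
  expect_error(graph_distances(sh, integer(0)), "empty")

  sh2 <- generate_sphere_shell(200, seed = 5)
  d <- graph_distances(sh2, 7)
  # independent oracle: igraph shortest paths on the adjacency graph
  edges <- t(sh2$bonds[, c("c1", "c2")])
  g <- igraph::make_graph(as.vector(edges), directed = FALSE)
  oracle <- as.integer(igraph::distances(g, v = 7)[1, ])
  expect_equal(d, oracle)
})

test_that("graph distances satisfy the triangle inequality on samples", {
  sh <- generate_sphere_shell(120, seed = 3)
  set.seed(11)
  for (i in 1:25) {
    abc <- sample(length(sh$cells), 3)
    dab <- graph_distances(sh, abc[1])[abc[2]]
    dbc <- graph_distances(sh, abc[2])[abc[3]]
    dac <- graph_distances(sh, abc[1])[abc[3]]
    expect_lte(dac, dab + dbc)
  }
})

test_that("tangent projection removes the normal component and is idempotent", {
  sq <- cell_patch(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                   list(1:4))
  g <- build_cell_geometry(sq, 1)
  expect_equal(tangent_project(g$normal, g), c(0, 0), tolerance = 1e-14)
  expect_equal(tangent_project(c(1, 1, 1), g), c(1, 1),
               tolerance = 1e-12)
  v <- c(0.3, -0.7, 0)
  p1 <- tangent_project(v, g)
  expect_equal(sqrt(sum(p1^2)), sqrt(sum(v^2)), tolerance = 1e-12)
})

test_that("validate_shell reports closure and orientation failures", {
  sh <- cube_shell()
  d <- validate_shell(sh)
  expect_true(d$ok)
  expect_identical(d$euler, 2L)

  open <- structure(list(positions = sh$positions,
                         cells = sh$cells[-1]),
                    class = "cellular_shell")
  d2 <- validate_shell(open)
  expect_false(d2$ok)
  expect_false(d2$closed)

  rev1 <- structure(list(positions = sh$positions,
                         cells = c(list(rev(sh$cells[[1]])),
                                   sh$cells[-1])),
                    class = "cellular_shell")
  d3 <- validate_shell(rev1)
  expect_false(d3$ok)
  expect_false(d3$oriented)
  expect_error(validate_shell(rev1, strict = TRUE))
})

test_that("generated sphere volumes approach the continuum sphere", {
  sh <- generate_sphere_shell(500, seed = 2, radius = 1)
  expect_lt(abs(enclosed_volume(sh) - 4 * pi / 3) / (4 * pi / 3), 0.02)
})
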