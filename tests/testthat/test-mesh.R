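test_that("icosphere subdivision gives the expected vertex and face counts", {
  m0 <- build_ellipsoid_mesh(c(1, 1, 1), 0)
  expect_equal(m0$n_vertices, 12L)
  expect_equal(m0$n_faces, 20L)
  m2 <- build_ellipsoid_mesh(c(1, 1, 1), 2)
  expect_equal(m2$n_vertices, 10 * 4^2 + 2)  # 162
  expect_equal(m2$n_faces, 20 * 4^2)
})

test_that("ellipsoid vertices satisfy the quadric equation", {
  m <- build_ellipsoid_mesh(c(1, 1, 2), 1)
  v <- m$vertices
  q <- v[, 1]^2 + v[, 2]^2 + (v[, 3] / 2)^2
  expect_lt(max(abs(q - 1)), 1e-9)
})

test_that("invalid mesh construction is rejected", {
  expect_error(build_ellipsoid_mesh(c(1, -1, 1), 1), "positive")
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(tri_mesh(v, rbind(c(1, 2, 2))), "degenerate")
})

test_that("barycentric node areas match hand evaluation and conserve area", {
  m <- two_triangle_mesh()
  a <- node_areas(m)
  # shared hypotenuse nodes (2, 3) touch both faces: 2 * (1/2) / 3 = 1/3
  expect_equal(a, c(1 / 6, 1 / 3, 1 / 3, 1 / 6))
  expect_equal(sum(a), 1)
  # conservation on a generic mesh
  m2 <- build_ellipsoid_mesh(c(40, 35, 50), 2)
  expect_lt(abs(sum(node_areas(m2)) - sum(ecgibench:::face_areas(m2))) /
              sum(ecgibench:::face_areas(m2)), 1e-9)
  # icosahedron symmetry
  ai <- node_areas(build_ellipsoid_mesh(c(1, 1, 1), 0))
  expect_lt(diff(range(ai)), 1e-12)
  # incident-sum convention triple-counts
  expect_equal(node_areas(m, "incident"), 3 * a)
})

test_that("geodesic distances are Dijkstra distances on the edge graph", {
  m <- test_atria()
  expect_equal(geodesic_distance(m, 5, 5), 0)
  # metric axioms on random triples
  set.seed(11)
  idx <- sample(m$n_vertices, 12)
  D <- geodesic_distance(m)
  expect_equal(D, t(D))
  for (i in 1:10) {
    abc <- sample(idx, 3)
    expect_lte(D[abc[1], abc[3]], D[abc[1], abc[2]] + D[abc[2], abc[3]] + 1e-9)
  }
  # agreement with an independent Floyd-Warshall on a small mesh
  ms <- build_ellipsoid_mesh(c(10, 10, 10), 0)
  expect_equal(geodesic_distance(ms), brute_force_geodesics(ms),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("one-ring cycles are ordered, closed and orientation-aware", {
  ico <- build_ellipsoid_mesh(c(1, 1, 1), 0)
  r <- one_ring_cycle(ico, 1)
  expect_length(r, 5)
  expect_setequal(r, setdiff(unique(as.vector(
    ico$faces[rowSums(ico$faces == 1) > 0, ])), 1))
  m <- test_atria()
  deg <- table(as.vector(m$faces))
  v <- 50
  expect_length(one_ring_cycle(m, v), as.integer(deg[as.character(v)]))
  # reversing orientation reverses the cycle
  flipped <- tri_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  rf <- one_ring_cycle(flipped, 1)
  # the reversed cycle visits the same neighbors in opposite cyclic order
  expect_setequal(rf, r)
  pos <- match(r, rf)
  step <- diff(pos) %% length(r)
  expect_true(all(step == step[1]) && step[1] == length(r) - 1)
})

test_that("one-ring cycles traverse each incident ring edge exactly once", {
  m <- test_atria()
  for (v in c(1, 42, 100)) {
    r <- one_ring_cycle(m, v)
    edges <- paste(r, c(r[-1], r[1]))
    expect_equal(anyDuplicated(edges), 0L)
  }
})

test_that("boundary nodes are flagged as open fans", {
  m <- two_triangle_mesh()
  expect_warning(r <- one_ring_cycle(m, 1), "open fan")
  expect_null(r)
})

test_that("OFF and PLY round-trip the mesh exactly", {
  m <- build_ellipsoid_mesh(c(1, 1, 1), 0)
  for (ext in c("off", "ply")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mesh(m, f)
    m2 <- read_mesh(f)
    expect_equal(m2$vertices, m$vertices)
    expect_equal(m2$faces, m$faces)
    unlink(f)
  }
})

test_that("malformed mesh files are rejected with informative errors", {
  f <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 2 0", "0 0 0", "1 0 0", "0 1 0"), f)
  expect_error(read_mesh(f), "truncated")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), f)
  expect_error(read_ply_quad <- read_mesh(f, format = "ply"), "triangles")
  unlink(f)
})
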