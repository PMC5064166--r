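# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

test_atria <- function() cached("atria", default_atrial_mesh("tiny"))
test_torso <- function() cached("torso", default_torso_mesh("tiny"))

test_transfer <- function() {
  cached("A", apply_wct_reference(kernel_transfer_matrix(test_atria(),
                                                         test_torso())))
}

test_phantom <- function(kind = "SAF", seed = 1L) {
  cached(paste0("phantom_", kind, "_", seed),
         simulate_pattern(test_atria(), activity_pattern(kind, seed = seed),
                          duration_s = 8, fs = 500))
}

# Two unit right triangles sharing the hypotenuse: (0,0), (1,0), (0,1), (1,1)
two_triangle_mesh <- function() {
  tri_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
    faces = rbind(c(1, 2, 3), c(2, 4, 3)),
    validate = FALSE   # open surface: orientation check expects closedness
  )
}

# Open triangulated disk: a center vertex fanned to rings of boundary
# vertices. Boundary nodes have open fans, so singularity detection skips
# them; the only closed one-rings are interior.
disk_mesh <- function(n_rings = 3, n_sector = 12, radius = 10) {
  verts <- matrix(0, 1, 3)
  ring_ids <- list()
  for (r in seq_len(n_rings)) {
    ang <- 2 * pi * (seq_len(n_sector) - 1) / n_sector
    ring <- cbind(cos(ang), sin(ang), 0) * (radius * r / n_rings)
    ring_ids[[r]] <- nrow(verts) + seq_len(n_sector)
    verts <- rbind(verts, ring)
  }
  faces <- NULL
  inner <- ring_ids[[1]]
  for (j in seq_len(n_sector)) {
    jn <- j %% n_sector + 1L
    faces <- rbind(faces, c(1L, inner[j], inner[jn]))
  }
  for (r in seq_len(n_rings - 1)) {
    a <- ring_ids[[r]]; b <- ring_ids[[r + 1]]
    for (j in seq_len(n_sector)) {
      jn <- j %% n_sector + 1L
      faces <- rbind(faces, c(a[j], b[j], b[jn]), c(a[j], b[jn], a[jn]))
    }
  }
  tri_mesh(verts, faces, validate = FALSE)
}

# azimuthal (vortex) phase field about a point in the z = 0 plane
vortex_phase <- function(mesh, center, times, rate_hz = 7, chirality = 1) {
  theta <- atan2(mesh$vertices[, 2] - center[2], mesh$vertices[, 1] - center[1])
  wrap <- function(x) { y <- (x + pi) %% (2 * pi) - pi; y[y == -pi] <- pi; y }
  wrap(outer(rep(1, mesh$n_vertices), 2 * pi * rate_hz * times) -
         chirality * theta)
}

# independent all-pairs shortest path (Floyd-Warshall) on mesh edges
brute_force_geodesics <- function(mesh) {
  n <- mesh$n_vertices
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  e <- mesh_edges(mesh)
  for (i in seq_len(nrow(e))) {
    d[e$from[i], e$to[i]] <- e$length[i]
    d[e$to[i], e$from[i]] <- e$length[i]
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}
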