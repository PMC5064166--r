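#' Triangulated surface meshes
#'
#' `tri_mesh()` builds a validated triangulated closed-surface mesh, the
#' spatial carrier for every operator in the package: node areas weight the
#' singularity-location metrics, the edge graph carries Dijkstra geodesics,
#' and ordered one-ring cycles drive phase-singularity detection.
#'
#' @param vertices numeric matrix, N x 3, coordinates in mm.
#' @param faces integer matrix, F x 3, 1-based vertex indices per triangle,
#'   counter-clockwise when viewed from outside.
#' @param validate logical; check face indices, degeneracy, connectivity and
#'   orientation consistency.
#' @return an object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `n_vertices`, `n_faces`.
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an F x 3 matrix")
  n <- nrow(vertices)
  if (validate) {
    if (any(faces < 1L) || any(faces > n)) {
      stop("face indices out of range [1, ", n, "]")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen)) stop("degenerate faces (repeated vertex): ",
                         paste(which(degen)[1:min(3, sum(degen))], collapse = ", "))
    # directed edges: consistent orientation means each undirected interior
    # edge appears once in each direction
    de <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    key <- paste(de[, 1], de[, 2])
    if (anyDuplicated(key)) stop("inconsistent orientation: a directed edge appears twice")
    g <- mesh_graph(list(vertices = vertices, faces = faces))
    if (igraph::components(g)$no > 1L) stop("edge graph is not connected")
  }
  structure(
    list(vertices = vertices, faces = faces,
         n_vertices = n, n_faces = nrow(faces)),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", x$n_vertices, " vertices, ", x$n_faces, " faces, area ",
      format(sum(face_areas(x)), digits = 6), " mm^2\n", sep = "")
  invisible(x)
}

#' Undirected edge list of a mesh (unique, with Euclidean lengths in mm)
#' @param mesh a `tri_mesh` (or list with `vertices`, `faces`)
#' @return data frame with columns `from`, `to`, `length`
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  data.frame(from = e[, 1], to = e[, 2], length = d)
}

mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(as.matrix(e[, 1:2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- e$length
  g
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-node surface areas
#'
#' Barycentric convention: each node receives one third of the area of every
#' incident face, so node areas sum exactly to the total surface area. The
#' raw incident-face sum (which triple-counts area across a triangle's three
#' vertices) is available with `convention = "incident"`.
#'
#' @param mesh a `tri_mesh`
#' @param convention `"barycentric"` (default) or `"incident"`
#' @return numeric vector of length N (mm^2)
#' @export
node_areas <- function(mesh, convention = c("barycentric", "incident")) {
  convention <- match.arg(convention)
  fa <- face_areas(mesh)
  idx <- as.vector(mesh$faces)
  s <- as.vector(rowsum(rep(fa, 3L), idx, reorder = TRUE))
  out <- numeric(mesh$n_vertices)
  out[sort(unique(idx))] <- s
  if (convention == "barycentric") out / 3 else out
}

#' Geodesic (Dijkstra) distance between mesh nodes
#'
#' Shortest-path distance along mesh edges with Euclidean edge lengths as
#' weights. This graph geodesic is the distance used by the mode-distance
#' metric and by rotor-region construction; exact polyhedral geodesics are
#' deliberately not computed.
#'
#' @param mesh a `tri_mesh`
#' @param src,dst node indices (1-based). `dst = NULL` returns distances from
#'   `src` to all nodes; `src = NULL` too returns the full N x N matrix.
#' @return distance(s) in mm; `Inf` (with a warning) for disconnected pairs.
#' @export
geodesic_distance <- function(mesh, src = NULL, dst = NULL) {
  g <- mesh_graph(mesh)
  n <- mesh$n_vertices
  if (is.null(src)) {
    d <- igraph::distances(g, algorithm = "dijkstra")
  } else if (is.null(dst)) {
    stopifnot(all(src >= 1L), all(src <= n))
    d <- igraph::distances(g, v = src, algorithm = "dijkstra")
  } else {
    stopifnot(all(src >= 1L), all(src <= n), all(dst >= 1L), all(dst <= n))
    d <- igraph::distances(g, v = src, to = dst, algorithm = "dijkstra")
    if (length(src) == 1L && length(dst) == 1L) d <- unname(d[1, 1])
    else if (length(src) == 1L) d <- d[1, ]
  }
  if (any(!is.finite(d))) warning("mesh contains disconnected node pairs; returning Inf")
  d
}

#' Ordered one-ring neighborhood of a node
#'
#' Returns the cyclic sequence of neighbors of `node`, ordered consistently
#' with face orientation (counter-clockwise seen from outside). Each face
#' `(v, a, b)` incident to `v` contributes the directed ring edge `a -> b`;
#' chaining these edges closes the fan. Phase-singularity detection sums
#' wrapped phase differences along this cycle.
#'
#' @param mesh a `tri_mesh`
#' @param node node index
#' @return integer vector of neighbor indices (cyclic; last connects to
#'   first), or `NULL` with a warning for a boundary node (open fan).
#' @export
one_ring_cycle <- function(mesh, node) {
  f <- mesh$faces
  inc <- which(f[, 1] == node | f[, 2] == node | f[, 3] == node)
  if (length(inc) == 0L) {
    warning("node ", node, " has no incident faces"); return(NULL)
  }
  # directed opposite edge a -> b for each incident face, CCW about the node
  seg <- matrix(0L, length(inc), 2L)
  for (i in seq_along(inc)) {
    tri <- f[inc[i], ]
    k <- which(tri == node)
    seg[i, ] <- tri[c(k %% 3L + 1L, (k + 1L) %% 3L + 1L)]
  }
  nxt <- seg[, 2]
  names(nxt) <- seg[, 1]
  cyc <- integer(length(inc))
  cyc[1] <- seg[1, 1]
  for (i in seq_len(length(inc) - 1L)) {
    nx <- nxt[as.character(cyc[i])]
    if (is.na(nx)) { warning("node ", node, " has an open fan (boundary node)"); return(NULL) }
    cyc[i + 1L] <- nx
  }
  if (nxt[as.character(cyc[length(cyc)])] != cyc[1]) {
    warning("node ", node, " has an open fan (boundary node)"); return(NULL)
  }
  cyc
}

one_ring_cycles <- function(mesh) {
  # bulk variant: open fans (boundary nodes) silently yield NULL and are
  # skipped by singularity detection
  suppressWarnings(
    lapply(seq_len(mesh$n_vertices), function(v) one_ring_cycle(mesh, v))
  )
}

#' Ellipsoid mesh by icosphere subdivision
#'
#' Subdivides an icosahedron `level` times (each level splits every triangle
#' into four, re-projecting onto the unit sphere), then scales anisotropically
#' by the semi-axes. The result is a closed, consistently oriented surface
#' with `10 * 4^level + 2` vertices, used as a synthetic stand-in for atrial
#' and torso geometry.
#'
#' @param semi_axes numeric length-3, semi-axis lengths in mm (all > 0)
#' @param subdivision_level non-negative integer
#' @param center numeric length-3 translation (mm), default origin
#' @return a `tri_mesh`
#' @export
build_ellipsoid_mesh <- function(semi_axes = c(1, 1, 1), subdivision_level = 0L,
                                 center = c(0, 0, 0)) {
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    stop("`semi_axes` must be 3 positive lengths")
  }
  if (subdivision_level < 0) stop("`subdivision_level` must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(subdivision_level)) {
    nv <- nrow(v)
    edge_mid <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- (verts[a, ] + verts[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      idx <- nrow(verts)
      edge_mid[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(i - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      nf[(i - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      nf[(i - 1L) * 4L + 3L, ] <- c(cc, ca, bc)
      nf[(i - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- nf
  }
  v <- sweep(v, 2L, semi_axes, `*`)
  v <- sweep(v, 2L, center, `+`)
  tri_mesh(v, f)
}

#' Outward unit vertex normals (area-weighted average of face normals)
#' @param mesh a `tri_mesh`
#' @return N x 3 matrix
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # area-weighted already
  n <- matrix(0, mesh$n_vertices, 3L)
  idx <- as.vector(f)
  for (k in 1:3) {
    acc <- rowsum(rep(fn[, k], 3L), idx, reorder = TRUE)
    n[as.integer(rownames(acc)), k] <- acc
  }
  n / sqrt(rowSums(n^2))
}
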