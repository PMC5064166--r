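#' Read a triangulated mesh from OFF or ascii PLY
#'
#' File vertex indices are 0-based (the native convention of both formats)
#' and converted to 1-based on read; `write_mesh()` converts back, so a
#' write/read round trip is the identity on vertices and faces.
#'
#' @param path file path; format inferred from the extension (`.off`, `.ply`)
#'   unless `format` is given.
#' @param format `"off"`, `"ply"` or `NULL` (infer)
#' @return a `tri_mesh`
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  switch(format,
    off = read_off(path),
    ply = read_ply(path),
    stop("unsupported mesh format: ", format)
  )
}

#' Write a mesh to OFF or ascii PLY
#' @param mesh a `tri_mesh`
#' @param path output path
#' @param format `"off"`, `"ply"` or `NULL` (infer from extension)
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
    off = write_off(mesh, path),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format: ", format)
  )
  invisible(path)
}

strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  ln <- which(nzchar(trimws(lines)))
  list(lines = trimws(lines[ln]), src = ln)
}

parse_fields <- function(line) {
  as.numeric(strsplit(line, "[[:space:]]+")[[1]])
}

read_off <- function(path) {
  raw <- readLines(path, warn = FALSE)
  cl <- strip_comments(raw)
  lines <- cl$lines; src <- cl$src
  if (length(lines) < 2L || toupper(lines[1]) != "OFF") {
    stop("not an OFF file (missing OFF header): ", path)
  }
  counts <- parse_fields(lines[2])
  if (length(counts) < 2L || any(is.na(counts[1:2]))) {
    stop("malformed OFF count line at line ", src[2])
  }
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) {
    stop("OFF file truncated: expected ", nv, " vertices and ", nf,
         " faces, found ", length(lines) - 2L, " data lines")
  }
  v <- t(vapply(lines[3:(2 + nv)], parse_fields, numeric(3)))
  dimnames(v) <- NULL
  f <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    fl <- parse_fields(lines[2 + nv + i])
    if (fl[1] != 3) stop("non-triangular face (", fl[1], " vertices) at line ",
                         src[2 + nv + i], "; only triangles are supported")
    if (length(fl) < 4L) stop("malformed face at line ", src[2 + nv + i])
    f[i, ] <- as.integer(fl[2:4]) + 1L
  }
  tri_mesh(v, f)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(mesh$n_vertices, mesh$n_faces, 0), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

read_ply <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 1L || trimws(raw[1]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(trimws(raw) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header has no end_header")
  hdr <- trimws(raw[seq_len(hdr_end)])
  if (!any(grepl("^format[[:space:]]+ascii", hdr))) {
    stop("only ascii PLY is supported")
  }
  nv <- as.integer(sub("^element[[:space:]]+vertex[[:space:]]+", "",
                       grep("^element[[:space:]]+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element[[:space:]]+face[[:space:]]+", "",
                       grep("^element[[:space:]]+face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header missing vertex/face elements")
  body <- trimws(raw[(hdr_end + 1L):length(raw)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stop("PLY file truncated")
  v <- t(vapply(body[seq_len(nv)], function(l) parse_fields(l)[1:3], numeric(3)))
  dimnames(v) <- NULL
  f <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    fl <- parse_fields(body[nv + i])
    if (fl[1] != 3) stop("PLY face ", i, " has ", fl[1],
                         " vertices; only triangles are supported")
    f[i, ] <- as.integer(fl[2:4]) + 1L
  }
  tri_mesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", mesh$n_vertices),
               "property double x", "property double y", "property double z",
               paste("element face", mesh$n_faces),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

#' Write / read a potential field as CSV with a JSON sidecar
#'
#' The node x time value matrix goes to `<path>` as headerless CSV (one row
#' per node); sampling metadata (`fs`, `t0`) goes to `<path>.json`.
#'
#' @param field a `potential_field`
#' @param path CSV path
#' @export
write_potential_field <- function(field, path) {
  utils::write.table(field$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = field$fs, t0 = field$t0,
                            n_nodes = nrow(field$values),
                            n_samples = ncol(field$values)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potential_field
#' @export
read_potential_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  potential_field(vals, fs = meta$fs, t0 = meta$t0)
}

#' Write / read a transfer matrix in MatrixMarket dense array format
#' @param A a `transfer_matrix` or plain matrix
#' @param path output path (conventionally `.mtx`)
#' @export
write_transfer_matrix <- function(A, path) {
  M <- if (inherits(A, "transfer_matrix")) A$entries else A
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix array real general", con)
  if (inherits(A, "transfer_matrix")) {
    writeLines(paste0("% referenced: ", A$referenced), con)
  }
  writeLines(paste(nrow(M), ncol(M)), con)
  writeLines(format(as.vector(M), digits = 17, trim = TRUE), con)
}

#' @rdname write_transfer_matrix
#' @export
read_transfer_matrix <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (!grepl("^%%MatrixMarket matrix array real", raw[1])) {
    stop("expected MatrixMarket dense array header in ", path)
  }
  referenced <- any(grepl("^% referenced: TRUE", raw))
  body <- raw[!grepl("^%", raw)]
  dims <- parse_fields(body[1])
  vals <- as.numeric(body[-1])
  if (length(vals) != dims[1] * dims[2]) stop("MatrixMarket entry count mismatch")
  transfer_matrix(matrix(vals, dims[1], dims[2]), referenced = referenced)
}
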