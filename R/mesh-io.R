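#' Triangulated surface mesh
#'
#' Container for a triangulated surface in mm units, as exported from
#' micro-CT segmentations of the scala tympani lumen or produced by
#' [loft()]. Faces index into the vertex table; winding is made
#' consistent/outward by the lofting step, and watertightness is a
#' queryable property ([is_watertight()]) rather than an invariant, since
#' print-prepared models deliberately carry open boundaries.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param name optional label carried through I/O.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @examples
#' m <- triangle_mesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)))
#' mesh_surface_area(m)
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) < 3 || nrow(faces) < 1) {
    stop("validation error: empty mesh (need >= 3 vertices and >= 1 face)")
  }
  if (ncol(faces) != 3) stop("faces must be an m x 3 matrix")
  if (any(!is.finite(vertices))) stop("validation error: non-finite vertex coordinates")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("validation error: face index out of range")
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)[1]),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  watertight: %s", is_watertight(x)))
  if (is_watertight(x)) cat(sprintf(", enclosed volume %.4f mm^3", mesh_volume(x)))
  cat("\n")
  invisible(x)
}

# signed volume by the divergence theorem (sum of signed tetrahedra)
.signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; the absolute value is
#' returned so the result does not depend on global winding.
#'
#' @param mesh a [triangle_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) abs(.signed_volume(mesh))

#' Total surface area of a mesh
#' @param mesh a [triangle_mesh()].
#' @return area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# directed edge table: one row per half-edge (from, to)
.half_edges <- function(faces) {
  rbind(cbind(faces[, 1], faces[, 2]),
        cbind(faces[, 2], faces[, 3]),
        cbind(faces[, 3], faces[, 1]))
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (2-manifold without boundary, consistently wound)
#' when every undirected edge is shared by exactly two faces traversing it
#' in opposite directions.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  he <- .half_edges(mesh$faces)
  nv <- nrow(mesh$vertices)
  key_dir <- (he[, 1] - 1) * nv + he[, 2]
  key_und <- (pmin(he[, 1], he[, 2]) - 1) * nv + pmax(he[, 1], he[, 2])
  if (anyDuplicated(key_dir) > 0) return(FALSE) # repeated directed edge
  tab <- table(key_und)
  all(tab == 2)
}

#' Boundary loops of a mesh
#'
#' Chains the boundary half-edges (edges used by exactly one face) into
#' closed loops; a watertight mesh has none, an open-base print model has
#' one, and a vented print model has two.
#'
#' @param mesh a [triangle_mesh()].
#' @return list of integer vectors of vertex indices, one per loop.
#' @export
mesh_boundary_loops <- function(mesh) {
  he <- .half_edges(mesh$faces)
  nv <- nrow(mesh$vertices)
  key_und <- (pmin(he[, 1], he[, 2]) - 1) * nv + pmax(he[, 1], he[, 2])
  cnt <- table(key_und)
  boundary <- he[key_und %in% as.numeric(names(cnt)[cnt == 1]), , drop = FALSE]
  if (nrow(boundary) == 0) return(list())
  nxt <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(boundary))) assign(as.character(boundary[i, 1]), boundary[i, 2], envir = nxt)
  visited <- character(0)
  loops <- list()
  for (i in seq_len(nrow(boundary))) {
    start <- as.character(boundary[i, 1])
    if (start %in% visited) next
    loop <- integer(0)
    cur <- start
    repeat {
      visited <- c(visited, cur)
      loop <- c(loop, as.integer(cur))
      if (!exists(cur, envir = nxt, inherits = FALSE)) break
      cur <- as.character(get(cur, envir = nxt, inherits = FALSE))
      if (cur == start) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Read a surface mesh from PLY or STL
#'
#' Supports ascii and binary little-endian PLY, and ascii or binary STL.
#' Coordinates are taken to be mm (neither format carries units). STL
#' triangle soups are welded on exact coordinate equality so that
#' connectivity queries ([is_watertight()]) work after a round trip.
#'
#' @param path file path.
#' @param format `"auto"` (by extension/magic), `"ply"` or `"stl"`.
#' @param name mesh label; defaults to the file name.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ply", "stl")) ext else {
      magic <- readBin(path, "raw", 4)
      if (rawToChar(magic[1:3]) == "ply") "ply" else "stl"
    }
  }
  if (is.null(name)) name <- basename(path)
  mesh <- if (format == "ply") .read_ply(path) else .read_stl(path)
  triangle_mesh(mesh$vertices, mesh$faces, name = name)
}

#' Write a surface mesh to PLY or binary STL
#'
#' PLY is written binary little-endian with double-precision coordinates
#' (preserving vertex order and geometry to well under 1e-6 mm); STL is
#' written binary with 32-bit floats per the format.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"ply"` or `"stl"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "stl")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (any(!is.finite(mesh$vertices))) stop("validation error: non-finite vertex coordinates")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl")) stop("cannot infer mesh format from extension: ", path)
    format <- ext
  }
  if (format == "ply") .write_ply(mesh, path) else .write_stl(mesh, path)
  invisible(path)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("format error: truncated PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop("format error: not a PLY file")
  fmt_line <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line)) {
    stop("format error: unsupported PLY format (need ascii or binary_little_endian)")
  }
  # parse elements and properties
  el_lines <- grep("^element", header)
  elements <- list()
  for (k in seq_along(el_lines)) {
    parts <- strsplit(trimws(header[el_lines[k]]), "\\s+")[[1]]
    to <- if (k < length(el_lines)) el_lines[k + 1] - 1 else length(header) - 1
    props <- header[(el_lines[k] + 1):to]
    props <- grep("^property", trimws(props), value = TRUE)
    elements[[parts[2]]] <- list(count = as.integer(parts[3]), props = props)
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("format error: PLY lacks vertex/face elements")
  }
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                 int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  if (binary) {
    vcount <- elements$vertex$count
    vprops <- strsplit(trimws(elements$vertex$props), "\\s+")
    ptypes <- vapply(vprops, function(p) p[2], "")
    pnames <- vapply(vprops, function(p) p[3], "")
    sizes <- unname(type_size[ptypes])
    if (any(is.na(sizes))) stop("format error: unsupported vertex property type")
    rowsize <- sum(sizes)
    raw <- readBin(con, "raw", vcount * rowsize)
    offs <- cumsum(c(0, sizes[-length(sizes)]))
    getcol <- function(j) {
      sz <- sizes[j]
      idx <- rep(offs[j] + seq_len(sz), vcount) +
        rep((seq_len(vcount) - 1) * rowsize, each = sz)
      what <- if (ptypes[j] %in% c("float", "float32", "double", "float64")) "double" else "integer"
      readBin(raw[idx], what, n = vcount, size = sz, endian = "little")
    }
    vx <- getcol(which(pnames == "x")[1])
    vy <- getcol(which(pnames == "y")[1])
    vz <- getcol(which(pnames == "z")[1])
    vertices <- cbind(vx, vy, vz)
    # face element: property list <count_type> <index_type> vertex_ind*
    fprop <- strsplit(trimws(elements$face$props[1]), "\\s+")[[1]]
    if (fprop[2] != "list") stop("format error: face element is not a list property")
    csz <- type_size[fprop[3]]; isz <- type_size[fprop[4]]
    fcount <- elements$face$count
    raw <- readBin(con, "raw", n = fcount * (csz + 3 * isz) + 16)
    # fast path: all triangles (uniform stride); verify via first counts
    stride <- csz + 3 * isz
    if (length(raw) >= fcount * stride) {
      counts <- readBin(raw[rep((seq_len(fcount) - 1) * stride, each = csz) +
                              rep(seq_len(csz), fcount)],
                        "integer", n = fcount, size = csz, endian = "little", signed = csz > 1)
      if (all(counts == 3)) {
        idx_raw_base <- rep((seq_len(fcount) - 1) * stride + csz, each = 3 * isz)
        idx <- idx_raw_base + rep(seq_len(3 * isz), fcount)
        ints <- readBin(raw[idx], "integer", n = 3 * fcount, size = isz, endian = "little")
        faces <- matrix(ints, ncol = 3, byrow = TRUE) + 1L
        return(list(vertices = vertices, faces = faces))
      }
    }
    stop("format error: PLY faces are not all triangles")
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vcount <- elements$vertex$count
    fcount <- elements$face$count
    if (length(body) < vcount + fcount) stop("format error: truncated PLY body")
    vprops <- strsplit(trimws(elements$vertex$props), "\\s+")
    pnames <- vapply(vprops, function(p) p[3], "")
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(vcount)]), "\\s+"))),
                   nrow = vcount, byrow = TRUE)
    vertices <- vdat[, match(c("x", "y", "z"), pnames), drop = FALSE]
    flines <- strsplit(trimws(body[vcount + seq_len(fcount)]), "\\s+")
    ns <- vapply(flines, function(f) as.integer(f[1]), 1L)
    if (any(ns != 3)) stop("format error: PLY faces are not all triangles")
    faces <- t(vapply(flines, function(f) as.integer(f[2:4]), integer(3))) + 1L
    list(vertices = vertices, faces = faces)
  }
}

.write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply", "format binary_little_endian 1.0",
              sprintf("comment %s", mesh$name),
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  writeLines(header, con, sep = "\n")
  writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
  # interleave uchar count byte with 3 little-endian int32 indices per face
  counts <- as.raw(rep(3L, nf))
  idx_raw <- writeBin(as.integer(t(mesh$faces - 1L)), raw(), size = 4, endian = "little")
  block <- rbind(matrix(counts, nrow = 1), matrix(idx_raw, nrow = 12))
  writeBin(as.vector(block), con)
  invisible(path)
}

.read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- !is.na(ntri) && (84 + ntri * 50 == sz)
  if (!is_binary) {
    close(con); on.exit(NULL)
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", txt, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
      stop("format error: unreadable STL file")
    }
    coords <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vlines), "\\s+"),
                                              function(p) p[2:4]))),
                     ncol = 3, byrow = TRUE)
  } else {
    raw <- readBin(con, "raw", ntri * 50)
    stride <- 50
    tri_off <- (seq_len(ntri) - 1) * stride
    # 12 floats per record (normal + 3 vertices), skip 2-byte attribute
    idx <- rep(tri_off, each = 48) + rep(seq_len(48), ntri)
    floats <- readBin(raw[idx], "double", n = ntri * 12, size = 4, endian = "little")
    fm <- matrix(floats, ncol = 12, byrow = TRUE)
    coords <- matrix(0, ntri * 3, 3)
    coords[seq(1, ntri * 3, by = 3), ] <- fm[, 4:6, drop = FALSE]
    coords[seq(2, ntri * 3, by = 3), ] <- fm[, 7:9, drop = FALSE]
    coords[seq(3, ntri * 3, by = 3), ] <- fm[, 10:12, drop = FALSE]
  }
  if (nrow(coords) == 0) stop("validation error: empty mesh in STL file")
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = "_")
  uniq <- !duplicated(key)
  vertices <- coords[uniq, , drop = FALSE]
  map <- match(key, key[uniq])
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

.write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f)
  writeBin(c(charToRaw(sprintf("%-10s", mesh$name)), raw(70))[1:80], con)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  rec <- cbind(n, a, b, c_) # 12 floats per triangle
  floats <- as.vector(t(rec))
  fr <- writeBin(floats, raw(), size = 4, endian = "little")
  fr_m <- matrix(fr, nrow = 48)
  attr_bytes <- matrix(as.raw(0), nrow = 2, ncol = nf)
  writeBin(as.vector(rbind(fr_m, attr_bytes)), con)
  invisible(path)
}

#' Ordered basilar-membrane landmark set
#'
#' Landmarks are 3D points in mm ordered from the cochlear base toward the
#' apex along the basilar-membrane edge of the scala tympani; at least 4
#' points are required (plane fitting and tangent estimation need them).
#'
#' @param points numeric matrix (n x 3), base-to-apex order.
#' @return object of class `landmark_set` with `points` and `count`.
#' @export
landmark_set <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("landmarks must be an n x 3 matrix")
  if (nrow(points) < 4) stop("need at least 4 landmarks")
  if (any(!is.finite(points))) stop("parse error: non-numeric/non-finite landmark")
  spacing <- sqrt(rowSums(diff(points)^2))
  if (any(spacing <= 0)) stop("landmarks must have positive consecutive spacing")
  structure(list(points = points, count = nrow(points)), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  span <- sqrt(sum((x$points[x$count, ] - x$points[1, ])^2))
  cat(sprintf("landmark_set: %d points, base-apex chord %.2f mm\n", x$count, span))
  invisible(x)
}

#' Read basilar-membrane landmarks from a delimited text file
#'
#' Accepts whitespace- or comma-delimited x,y,z rows (mm), `#` comments,
#' and an optional header line.
#'
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("format error: file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("parse error: no landmark rows in ", path)
  parse_row <- function(l) {
    suppressWarnings(as.numeric(strsplit(l, "[,[:space:]]+")[[1]]))
  }
  first <- parse_row(lines[1])
  if (any(is.na(first))) lines <- lines[-1] # header
  rows <- lapply(lines, parse_row)
  if (any(vapply(rows, function(r) length(r) < 3 || any(is.na(r[1:3])), TRUE))) {
    stop("parse error: non-numeric landmark row")
  }
  pts <- t(vapply(rows, function(r) r[1:3], numeric(3)))
  if (nrow(pts) < 4) stop("need at least 4 landmarks, got ", nrow(pts))
  landmark_set(pts)
}

#' Write landmarks as CSV (x,y,z in mm)
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  df <- as.data.frame(landmarks$points)
  names(df) <- c("x", "y", "z")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# basilar-membrane landmarks, mm, base to apex", con)
  writeLines("x,y,z", con)
  writeLines(sprintf("%.9g,%.9g,%.9g", df$x, df$y, df$z), con)
  invisible(path)
}
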