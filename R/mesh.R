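#' Corresponded triangle mesh
#'
#' Construct a triangulated surface mesh. Meshes are the atomic data object
#' of the package: one closed, orientable triangulated surface per structure
#' per hemisphere, with vertex-level correspondence across subjects and
#' visits guaranteed by a shared template topology.
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates in mm.
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param hemisphere `"left"` or `"right"`.
#' @param topology_id opaque token identifying the template topology; all
#'   meshes entering a vertex-wise comparison must share it.
#' @param validate if `TRUE` (default) check index bounds and closedness.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, hemisphere = c("left", "right"),
                          topology_id = "template", validate = TRUE) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix of vertex indices")
  mesh <- structure(
    list(vertices = vertices, faces = faces, hemisphere = hemisphere,
         topology_id = topology_id),
    class = "triangle_mesh")
  if (validate) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face indices out of range [1, V]")
    chk <- mesh_closedness(mesh)
    if (!chk$closed)
      stop("mesh is not a closed 2-manifold: ", chk$reason)
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, %s hemisphere (topology '%s')\n",
              nrow(x$vertices), nrow(x$faces), x$hemisphere, x$topology_id))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

## Each undirected edge of a closed orientable 2-manifold is shared by exactly
## two faces, with opposite traversal directions under consistent winding.
mesh_closedness <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    return(list(closed = FALSE,
                reason = sprintf("%d edge(s) not shared by exactly 2 faces",
                                 sum(cnt != 2L))))
  list(closed = TRUE, reason = "")
}

#' Enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem signed-tetrahedron sum: each face contributes the
#' signed volume of the tetrahedron it spans with the origin,
#' \eqn{\det(v_1, v_2, v_3)/6}; the total is exact for polyhedra and
#' translation-invariant for closed surfaces. The absolute value makes the
#' result orientation-invariant.
#'
#' @param mesh a `triangle_mesh` (closed, orientable).
#' @return enclosed volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  chk <- mesh_closedness(mesh)
  if (!chk$closed) stop("enclosed_volume requires a closed mesh: ", chk$reason)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det3)) / 6
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals (the face cross products
#' already carry the area weight), normalized per vertex. Normals are forced
#' outward: if the mean dot product with the centroid-to-vertex direction is
#' negative the whole field is flipped, so meshes with reversed winding still
#' yield outward normals. Zero-area faces are skipped with a warning.
#'
#' @param mesh a `triangle_mesh`.
#' @return V x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(fn^2))
  if (any(area2 == 0))
    warning(sum(area2 == 0), " degenerate (zero-area) face(s) skipped")
  nv <- nrow(v)
  acc <- matrix(0, nv, 3)
  for (k in 1:3) {
    tb <- rowsum(fn, f[, k], reorder = FALSE)
    ids <- as.integer(rownames(tb))
    acc[ids, ] <- acc[ids, ] + tb
  }
  nrm <- sqrt(rowSums(acc^2))
  nrm[nrm == 0] <- 1
  n <- acc / nrm
  ctr <- colMeans(v)
  outward <- sweep(v, 2, ctr)
  if (mean(rowSums(n * outward)) < 0) n <- -n
  n
}

#' Validate vertex correspondence across a set of meshes
#'
#' Downstream vertex-wise statistics assume every mesh shares the template's
#' vertex count, face list and hemisphere partition. This check is cheap and
#' should be run before any group analysis.
#'
#' @param meshes list of `triangle_mesh` objects; the first is the reference.
#' @return list with `ok` (logical) and `mismatches`
#'   (data.frame mesh / reason), class `correspondence_report`.
#' @export
validate_correspondence <- function(meshes) {
  stopifnot(length(meshes) >= 1)
  ref <- meshes[[1]]
  ids <- names(meshes)
  if (is.null(ids)) ids <- as.character(seq_along(meshes))
  mism <- list()
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    reason <- NULL
    if (nrow(m$vertices) != nrow(ref$vertices))
      reason <- "vertex count differs"
    else if (!identical(dim(m$faces), dim(ref$faces)) ||
             any(m$faces != ref$faces))
      reason <- "face list differs"
    else if (!identical(m$hemisphere, ref$hemisphere))
      reason <- "hemisphere differs"
    else if (!identical(m$topology_id, ref$topology_id))
      reason <- "topology_id differs"
    if (!is.null(reason))
      mism[[length(mism) + 1L]] <- data.frame(mesh = ids[i], reason = reason,
                                              stringsAsFactors = FALSE)
  }
  mism <- if (length(mism)) do.call(rbind, mism) else
    data.frame(mesh = character(), reason = character())
  structure(list(ok = nrow(mism) == 0L, mismatches = mism),
            class = "correspondence_report")
}

#' @export
print.correspondence_report <- function(x, ...) {
  if (x$ok) cat("correspondence ok\n")
  else {
    cat("correspondence FAILED:\n")
    print(x$mismatches)
  }
  invisible(x)
}

## ---- file formats -----------------------------------------------------

#' Read a triangulated surface from disk
#'
#' Supports legacy VTK ASCII polydata (the package's canonical format, with
#' optional per-vertex SCALARS fields returned in the `"point_data"`
#' attribute) and ascii PLY 1.0 (geometry only). Vertex order is preserved
#' exactly as stored.
#'
#' @param path file path.
#' @param format `"vtk"` or `"ply"`; default guessed from the extension.
#' @param hemisphere,topology_id metadata attached to the returned mesh.
#' @return a `triangle_mesh`; any scalar point-data fields are attached as a
#'   named list in `attr(mesh, "point_data")`.
#' @export
read_surface <- function(path, format = c("auto", "vtk", "ply"),
                         hemisphere = "left", topology_id = "template") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vtk = "vtk", ply = "ply",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "vtk") read_vtk(path, hemisphere, topology_id)
  else read_ply(path, hemisphere, topology_id)
}

read_vtk <- function(path, hemisphere, topology_id) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# vtk DataFile", lines[1]))
    stop("parse error at line 1 of ", path, ": missing '# vtk DataFile' header")
  if (length(lines) < 4)
    stop("parse error in ", path, ": truncated header")
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("parse error at line 3 of ", path, ": only ASCII VTK supported")
  if (!grepl("POLYDATA", toupper(lines[4])))
    stop("parse error at line 4 of ", path, ": DATASET POLYDATA expected")
  toks <- scan(text = paste(lines[-(1:4)], collapse = "\n"), what = "character",
               quiet = TRUE)
  pos <- 1L
  take <- function(n) {
    out <- toks[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  expect <- function(word) {
    got <- take(1L)
    if (toupper(got) != word)
      stop("parse error in ", path, ": expected ", word, ", got '", got, "'")
  }
  expect("POINTS")
  nv <- as.integer(take(1L)); take(1L)  # dtype token
  verts <- matrix(as.numeric(take(3L * nv)), ncol = 3, byrow = TRUE)
  expect("POLYGONS")
  nf <- as.integer(take(1L))
  ntok <- as.integer(take(1L))
  cells <- as.integer(take(ntok))
  cm <- matrix(cells, ncol = ntok / nf, byrow = TRUE)
  if (any(cm[, 1] != 3L))
    stop("format error in ", path, ": non-triangular face (cell size != 3)")
  faces <- cm[, 2:4, drop = FALSE] + 1L
  point_data <- list()
  while (pos <= length(toks)) {
    word <- toupper(toks[pos])
    if (word == "POINT_DATA") {
      pos <- pos + 2L
    } else if (word == "SCALARS") {
      pos <- pos + 1L
      nm <- take(1L); take(1L)           # name, dtype
      ncomp <- suppressWarnings(as.integer(toks[pos]))
      if (!is.na(ncomp)) pos <- pos + 1L else ncomp <- 1L
      if (toupper(toks[pos]) == "LOOKUP_TABLE") pos <- pos + 2L
      point_data[[nm]] <- as.numeric(take(nv * ncomp))
    } else {
      break
    }
  }
  mesh <- triangle_mesh(verts, faces, hemisphere, topology_id)
  if (length(point_data)) attr(mesh, "point_data") <- point_data
  mesh
}

read_ply <- function(path, hemisphere, topology_id) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1]) != "ply")
    stop("parse error at line 1 of ", path, ": missing 'ply' magic")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("parse error in ", path, ": no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("format error in ", path, ": only ascii PLY supported")
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "",
                       grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "",
                       grep("element\\s+face", hdr, value = TRUE)[1]))
  ## vertex property names, in declared order
  vi <- grep("element\\s+vertex", hdr)
  fi <- grep("element\\s+face", hdr)
  props <- hdr[(vi + 1):(fi - 1)]
  props <- props[grepl("^\\s*property\\s", props)]
  pnames <- vapply(strsplit(trimws(props), "\\s+"),
                   function(x) x[length(x)], "")
  body <- lines[(hdr_end + 1):length(lines)]
  vrows <- body[seq_len(nv)]
  vmat <- matrix(as.numeric(unlist(strsplit(trimws(vrows), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  ix <- match(c("x", "y", "z"), pnames)
  if (any(is.na(ix))) stop("format error in ", path, ": x/y/z properties missing")
  verts <- vmat[, ix, drop = FALSE]
  frows <- body[nv + seq_len(nf)]
  fl <- strsplit(trimws(frows), "\\s+")
  counts <- vapply(fl, function(x) as.integer(x[1]), 0L)
  if (any(counts != 3L))
    stop("format error in ", path, ": non-triangular face in PLY")
  faces <- t(vapply(fl, function(x) as.integer(x[2:4]), integer(3))) + 1L
  triangle_mesh(verts, faces, hemisphere, topology_id)
}

#' Write a surface (optionally with per-vertex scalar fields) to legacy VTK
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @param scalars `NULL`, a numeric vector of length V, or a named list of
#'   such vectors; written as float SCALARS point data readable by standard
#'   viewers.
#' @param digits significant digits for coordinates and scalars (default 17,
#'   i.e. lossless for doubles).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, scalars = NULL, digits = 17) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  if (!is.null(scalars) && !is.list(scalars)) scalars <- list(scalars = scalars)
  if (!is.null(scalars)) {
    bad <- vapply(scalars, function(s) length(s) != nv, TRUE)
    if (any(bad))
      stop("scalar field length != V for: ",
           paste(names(scalars)[bad], collapse = ", "))
  }
  fmt <- function(x) format(x, digits = digits, scientific = TRUE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("hippomorph surface (", mesh$hemisphere, ")"),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nv)), con)
  writeLines(paste(fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (!is.null(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(fmt(as.numeric(scalars[[nm]])), con)
    }
  }
  invisible(path)
}

## ---- icosphere --------------------------------------------------------

#' Subdivided icosahedron on the unit sphere
#'
#' Standard icosphere: start from the regular icosahedron, split every edge
#' at its midpoint `level` times, projecting new vertices to the sphere.
#' Vertex count is 10 * 4^level + 2; faces 20 * 4^level.
#'
#' @param level non-negative integer subdivision level.
#' @param radius sphere radius (default 1).
#' @return a `triangle_mesh` (hemisphere `"left"`, topology
#'   `"icosphere-<level>"`).
#' @export
icosphere <- function(level = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    nv <- nrow(v)
    edge_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    mids <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(a, b) {
      k <- as.character(edge_key(a, b))
      hit <- mids[[k]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      mids[[k]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  triangle_mesh(v * radius, f, hemisphere = "left",
                topology_id = paste0("icosphere-", level))
}
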