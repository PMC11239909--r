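#' Triangulated surface mesh
#'
#' Constructs a `surface_mesh`: a triangulated membrane surface with vertex
#' coordinates in nanometres. This is the substrate of all cross-section
#' geometry in the package.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in nm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param validate check index ranges and reject zero-area faces.
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' f <- rbind(c(1, 2, 3), c(1, 3, 4))
#' m <- surface_mesh(v, f)
#' surface_area(m)
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (validate) {
    stopifnot_finite(vertices, "vertex coordinates")
    if (nrow(faces) > 0) {
      if (min(faces) < 1L || max(faces) > nrow(vertices))
        stop("face indices out of range")
      a <- triangle_areas(vertices, faces)
      if (any(a <= 0))
        stop(sprintf("%d degenerate (zero-area) face(s)", sum(a <= 0)))
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

triangle_areas <- function(V, F) {
  if (nrow(F) == 0) return(numeric(0))
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas, in nm^2. Additive over disjoint submeshes and
#' invariant under rigid motion.
#'
#' @param mesh a [surface_mesh].
#' @return area in nm^2 (0 for an empty mesh).
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  sum(triangle_areas(mesh$vertices, mesh$faces))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.4g nm^2\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

#' Apply a rigid motion to a mesh
#'
#' @param mesh a [surface_mesh].
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 offset in nm (default zero).
#' @return the transformed [surface_mesh].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices %*% t(rotation)
  V <- sweep(V, 2, translation, "+")
  surface_mesh(V, mesh$faces, validate = FALSE)
}

#' Clip a mesh by a half-space
#'
#' Keeps only the faces whose vertices all lie on the negative side of the
#' plane. Used to emulate junctions truncated at a tomogram border: the clip
#' is face-wise, so the cut edge is jagged at the tessellation scale, exactly
#' as a segmentation stops at the last traced slice.
#'
#' @param mesh a [surface_mesh].
#' @param origin point on the clipping plane (nm).
#' @param normal plane normal; faces on the positive side are discarded.
#' @return the clipped [surface_mesh] (possibly empty).
#' @export
clip_mesh <- function(mesh, origin, normal) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- unitize(normal)
  d <- as.vector(mesh$vertices %*% n) - sum(origin * n)
  keep_v <- d <= 0
  keep_f <- keep_v[mesh$faces[, 1]] & keep_v[mesh$faces[, 2]] & keep_v[mesh$faces[, 3]]
  F <- mesh$faces[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[F], ncol = 3), validate = FALSE)
}

## ---- mesh file I/O (ASCII OBJ / PLY / STL) -------------------------------

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "ply", "stl")) stop("unknown mesh format: ", ext)
  ext
}

#' Read / write triangulated meshes (ASCII OBJ, PLY, STL)
#'
#' Round trips are lossless at the declared precision (15 significant
#' digits). Quad faces in OBJ/PLY files are split into two triangles;
#' higher-order polygons are rejected. Coordinates are taken to be nm; every
#' writer emits a units comment where the format allows one.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of `"obj"`, `"ply"`, `"stl"`.
#' @return `read_mesh` returns a [surface_mesh]; `write_mesh` returns `path`
#'   invisibly.
#' @export
read_mesh <- function(path, format = guess_mesh_format(path)) {
  force(format)
  lines <- readLines(path, warn = FALSE)
  switch(format,
    obj = read_obj(lines),
    ply = read_ply(lines),
    stl = read_stl(lines),
    stop("unknown mesh format: ", format)
  )
}

#' @rdname read_mesh
#' @param mesh a [surface_mesh] to write.
#' @export
write_mesh <- function(mesh, path, format = guess_mesh_format(path)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  fmtnum <- function(x) formatC(x, format = "g", digits = 15)
  txt <- switch(format,
    obj = c("# units: nm",
            sprintf("v %s %s %s", fmtnum(V[, 1]), fmtnum(V[, 2]), fmtnum(V[, 3])),
            sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])),
    ply = c("ply", "format ascii 1.0", "comment units: nm",
            sprintf("element vertex %d", nrow(V)),
            "property double x", "property double y", "property double z",
            sprintf("element face %d", nrow(F)),
            "property list uchar int vertex_indices", "end_header",
            sprintf("%s %s %s", fmtnum(V[, 1]), fmtnum(V[, 2]), fmtnum(V[, 3])),
            sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)),
    stl = {
      a <- V[F[, 1], , drop = FALSE]
      b <- V[F[, 2], , drop = FALSE]
      cc <- V[F[, 3], , drop = FALSE]
      c("solid mesh_nm",
        as.vector(rbind(
          "facet normal 0 0 0",
          "  outer loop",
          sprintf("    vertex %s %s %s", fmtnum(a[, 1]), fmtnum(a[, 2]), fmtnum(a[, 3])),
          sprintf("    vertex %s %s %s", fmtnum(b[, 1]), fmtnum(b[, 2]), fmtnum(b[, 3])),
          sprintf("    vertex %s %s %s", fmtnum(cc[, 1]), fmtnum(cc[, 2]), fmtnum(cc[, 3])),
          "  endloop",
          "endfacet")),
        "endsolid mesh_nm")
    },
    stop("unknown mesh format: ", format)
  )
  writeLines(txt, path)
  invisible(path)
}

read_obj <- function(lines) {
  lines <- trimws(lines)
  vs <- lines[startsWith(lines, "v ")]
  fs <- lines[startsWith(lines, "f ")]
  V <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vs), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  tri <- list()
  for (f in fs) {
    toks <- strsplit(sub("^f\\s+", "", f), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1))
    if (length(idx) == 3) tri[[length(tri) + 1]] <- idx
    else if (length(idx) == 4) {
      tri[[length(tri) + 1]] <- idx[c(1, 2, 3)]
      tri[[length(tri) + 1]] <- idx[c(1, 3, 4)]
    } else stop("OBJ faces with >4 vertices are not supported")
  }
  if (is.null(V)) stop("OBJ file contains no vertices")
  surface_mesh(V, do.call(rbind, tri), validate = FALSE)
}

read_ply <- function(lines) {
  if (length(lines) == 0 || trimws(lines[1]) != "ply") stop("corrupt PLY header")
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("corrupt PLY header: no end_header")
  header <- trimws(lines[seq_len(hend)])
  if (!any(grepl("^format\\s+ascii", header))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", header, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1) stop("corrupt PLY header: missing elements")
  body <- trimws(lines[(hend + 1):length(lines)])
  body <- body[nzchar(body)]
  vtok <- strsplit(body[seq_len(nv)], "\\s+")
  V <- do.call(rbind, lapply(vtok, function(p) as.numeric(p[1:3])))
  tri <- list()
  for (f in body[nv + seq_len(nf)]) {
    p <- as.integer(strsplit(f, "\\s+")[[1]])
    k <- p[1]
    idx <- p[2:(1 + k)] + 1L
    if (k == 3) tri[[length(tri) + 1]] <- idx
    else if (k == 4) {
      tri[[length(tri) + 1]] <- idx[c(1, 2, 3)]
      tri[[length(tri) + 1]] <- idx[c(1, 3, 4)]
    } else stop("PLY faces with >4 vertices are not supported")
  }
  surface_mesh(V, do.call(rbind, tri), validate = FALSE)
}

read_stl <- function(lines) {
  lt <- trimws(lines)
  if (length(lt) == 0 || !startsWith(lt[1], "solid")) stop("corrupt STL header (only ASCII STL is supported)")
  vlines <- lt[startsWith(lt, "vertex")]
  if (length(vlines) %% 3 != 0) stop("corrupt STL: vertex count not a multiple of 3")
  P <- do.call(rbind, lapply(strsplit(sub("^vertex\\s+", "", vlines), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  # merge duplicate vertices so areas and topology survive the round trip
  key <- apply(P, 1, function(r) paste(formatC(r, format = "g", digits = 15), collapse = " "))
  uk <- !duplicated(key)
  V <- P[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(V, F, validate = FALSE)
}
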