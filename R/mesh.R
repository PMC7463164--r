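#' Triangulated surface meshes
#'
#' A `surface_mesh` holds an n x 3 vertex matrix (mm) and an m x 3 integer
#' face matrix of 1-based vertex indices, plus a frame tag.  Only triangles
#' are allowed: quads and higher polygons are rejected rather than silently
#' triangulated, so the caller stays in control of the geometry.
#'
#' @param vertices numeric n x 3 matrix
#' @param faces integer m x 3 matrix of 1-based indices
#' @param frame `"photo"` or `"MNI"`
#' @return a `surface_mesh` object
#' @export
surface_mesh <- function(vertices, faces, frame) {
  check_frame_tag(frame)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || !is.numeric(vertices) ||
      any(!is.finite(vertices))) {
    opto_validation_error("vertices must be a finite numeric n x 3 matrix")
  }
  faces <- matrix(as.integer(as.matrix(faces)), ncol = ncol(as.matrix(faces)))
  if (ncol(faces) != 3L) {
    opto_format_error("faces must be triangles (3 vertex indices per face)")
  }
  nv <- nrow(vertices)
  if (nrow(faces)) {
    bad <- which(faces < 1L | faces > nv, arr.ind = TRUE)
    if (nrow(bad)) {
      opto_format_error(sprintf(
        "face %d references out-of-range vertex index %d (mesh has %d vertices)",
        bad[1, 1], faces[bad[1, 1], bad[1, 2]], nv))
    }
    dup <- which(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
                   faces[, 2] == faces[, 3])
    if (length(dup)) {
      opto_format_error(sprintf(
        "degenerate face %d: repeated vertex index", dup[1]))
    }
    a <- vertices[faces[, 1], , drop = FALSE]
    ab <- vertices[faces[, 2], , drop = FALSE] - a
    ac <- vertices[faces[, 3], , drop = FALSE] - a
    cr <- cross3(ab, ac)
    zero <- which(row_norms(cr) <= 1e-12)
    if (length(zero)) {
      opto_format_error(sprintf("degenerate face %d: zero area", zero[1]))
    }
  }
  structure(list(vertices = vertices, faces = faces),
            frame = frame, class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, frame '%s'\n",
              nrow(x$vertices), nrow(x$faces), frame_of(x)))
  invisible(x)
}

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Read a triangulated mesh from PLY or OBJ
#'
#' Supports ASCII and binary little/big-endian PLY and Wavefront OBJ.
#' Vertex order is preserved from the file.  Non-triangular faces are a
#' format error.
#'
#' @param path file path, extension `.ply` or `.obj`
#' @param frame frame tag to attach (files carry none); default `"MNI"`
#' @return a [surface_mesh()]
#' @export
read_mesh <- function(path, frame = "MNI") {
  if (!file.exists(path)) opto_format_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path, frame)
  else if (ext == "obj") read_obj(path, frame)
  else opto_format_error(sprintf("unsupported mesh format '.%s' (%s)", ext, path))
}

#' @param mesh a [surface_mesh()]
#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") write_ply(mesh, path)
  else if (ext == "obj") write_obj(mesh, path)
  else opto_format_error(sprintf("unsupported mesh format '.%s' (%s)", ext, path))
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, endian) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "numeric", 1L, size = sz, endian = endian)
  } else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", 1L, size = sz, signed = signed || sz == 4L,
            endian = endian)
  }
}

read_ply <- function(path, frame) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    opto_format_error(sprintf("%s: not a PLY file", path))
  }
  fmt <- NULL
  elements <- list()  # each: list(name, count, props=list(list(name,type,list_count_type)))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) opto_format_error(sprintf("%s: truncated PLY header", path))
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], count_type = tok[3], is_list = TRUE)
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], is_list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    opto_format_error(sprintf("%s: PLY lacks vertex or face element", path))
  }
  if (identical(fmt, "ascii")) {
    dat <- read_ply_ascii(con, elements, path)
  } else if (fmt %in% c("binary_little_endian", "binary_big_endian")) {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    dat <- read_ply_binary(con, elements, endian, path)
  } else {
    opto_format_error(sprintf("%s: unknown PLY format '%s'", path, fmt))
  }
  surface_mesh(dat$vertices, dat$faces, frame)
}

read_ply_ascii <- function(con, elements, path) {
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 0L
  out <- list()
  for (el in elements) {
    rows <- lines[pos + seq_len(el$count)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      ix <- match(c("x", "y", "z"), pnames)
      if (anyNA(ix)) opto_format_error(sprintf("%s: vertex lacks x/y/z", path))
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      out$vertices <- m[, ix, drop = FALSE]
    } else if (el$name == "face") {
      fl <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
      cnt <- vapply(fl, `[[`, 0, 1L)
      if (any(cnt != 3)) {
        opto_format_error(sprintf(
          "%s: face %d has %d vertices; only triangles are supported",
          path, which(cnt != 3)[1], cnt[cnt != 3][1]))
      }
      out$faces <- do.call(rbind, lapply(fl, function(v) v[2:4] + 1))
    }
  }
  out
}

read_ply_binary <- function(con, elements, endian, path) {
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      m <- matrix(NA_real_, el$count, length(el$props))
      for (i in seq_len(el$count)) {
        for (j in seq_along(el$props)) {
          m[i, j] <- ply_read_scalar(con, el$props[[j]]$type, endian)
        }
      }
      ix <- match(c("x", "y", "z"), pnames)
      if (anyNA(ix)) opto_format_error(sprintf("%s: vertex lacks x/y/z", path))
      out$vertices <- m[, ix, drop = FALSE]
    } else if (el$name == "face") {
      faces <- matrix(NA_integer_, el$count, 3L)
      lp <- el$props[[1]]
      for (i in seq_len(el$count)) {
        cnt <- ply_read_scalar(con, lp$count_type, endian)
        if (cnt != 3L) {
          opto_format_error(sprintf(
            "%s: face %d has %d vertices; only triangles are supported",
            path, i, cnt))
        }
        for (j in 1:3) faces[i, j] <- ply_read_scalar(con, lp$type, endian) + 1L
      }
      out$faces <- faces
    } else {
      # skip unknown fixed-size elements
      for (i in seq_len(el$count)) {
        for (p in el$props) ply_read_scalar(con, p$type, endian)
      }
    }
  }
  out
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f)) {
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

read_obj <- function(path, frame) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines)) opto_format_error(sprintf("%s: OBJ has no vertices", path))
  v <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(t) {
    as.numeric(t[2:4])
  }))
  f <- lapply(seq_along(flines), function(i) {
    tok <- strsplit(flines[i], "\\s+")[[1]][-1]
    if (length(tok) != 3L) {
      opto_format_error(sprintf(
        "%s: face %d has %d vertices; only triangles are supported",
        path, i, length(tok)))
    }
    # "f 1/2/3" style: take the vertex index before any slash
    as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L))
  })
  surface_mesh(v, do.call(rbind, f), frame)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f)) writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
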