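#' Read and write surface meshes (PLY, OBJ, STL)
#'
#' PLY supports an optional per-vertex scalar channel (e.g. `thickness_mm`),
#' in ASCII or binary little-endian form. OBJ and STL carry geometry only;
#' STL stores independent triangles, so vertices are merged within 1e-6 mm
#' on read.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path; the extension selects the format.
#' @param scalars optional named list of per-vertex numeric channels
#'   (PLY only).
#' @param binary write binary PLY / STL instead of ASCII.
#' @export
write_mesh <- function(mesh, path, scalars = NULL, binary = FALSE) {
  switch(tolower(tools::file_ext(path)),
    ply = write_ply(mesh, path, scalars, binary),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path, binary),
    stop("unsupported mesh extension '", tools::file_ext(path),
         "'; supported formats: ply, obj, stl")
  )
  invisible(path)
}

#' @rdname write_mesh
#' @param label optional tissue label to attach.
#' @return `read_mesh`: a `surface_mesh`; PLY scalar channels are attached
#'   as the `"scalars"` attribute (named list).
#' @export
read_mesh <- function(path, label = NULL) {
  switch(tolower(tools::file_ext(path)),
    ply = read_ply(path, label),
    obj = read_obj(path, label),
    stl = read_stl(path, label),
    stop("unsupported mesh extension '", tools::file_ext(path),
         "'; supported formats: ply, obj, stl")
  )
}

write_ply <- function(mesh, path, scalars = NULL, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  snames <- names(scalars)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           if (length(snames)) paste("property double", snames),
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vdata <- cbind(mesh$vertices,
                 if (length(snames)) sapply(scalars, as.numeric))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(vdata)), con, size = 8, endian = "little")
    fmat <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    lines <- c(hdr,
               apply(vdata, 1, function(r) paste(format(r, digits = 17),
                                                 collapse = " ")),
               apply(mesh$faces - 1L, 1,
                     function(r) paste(c(3L, r), collapse = " ")))
    writeLines(lines, path)
  }
  invisible(path)
}

read_ply <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("malformed PLY: no end_header")
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", hdr,
                                                  value = TRUE))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  vstart <- which(grepl("^element vertex", hdr))
  vend <- which(grepl("^element face", hdr))
  props <- hdr[(vstart + 1):(vend - 1)]
  props <- props[grepl("^property", props)]
  ptypes <- sub("^property (\\S+) .*$", "\\1", props)
  pnames <- sub("^property \\S+ (\\S+)$", "\\1", props)
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (!all(ptypes %in% names(sizes))) {
    stop("unsupported PLY vertex property types: ",
         paste(setdiff(ptypes, names(sizes)), collapse = ", "))
  }
  np <- length(pnames)
  if (fmt == "ascii") {
    txt <- readLines(con)
    vt <- utils::read.table(text = txt[seq_len(nv)])
    vdata <- as.matrix(vt)
    fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(fl, function(x) as.integer(x[2:4]), integer(3))) + 1L
  } else if (fmt == "binary_little_endian") {
    same <- length(unique(sizes[ptypes])) == 1
    vdata <- matrix(NA_real_, nv, np)
    if (same) {
      raw <- readBin(con, "double", n = nv * np, size = sizes[ptypes[1]],
                     endian = "little")
      vdata <- matrix(raw, nv, np, byrow = TRUE)
    } else {
      for (i in seq_len(nv)) {
        for (j in seq_len(np)) {
          vdata[i, j] <- readBin(con, "double", 1, size = sizes[ptypes[j]],
                                 endian = "little")
        }
      }
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      idx <- readBin(con, "integer", cnt, size = 4, endian = "little")
      faces[i, ] <- idx[1:3] + 1L
    }
  } else {
    stop("unsupported PLY format '", fmt, "'")
  }
  colnames(vdata) <- pnames
  mesh <- surface_mesh(vdata[, c("x", "y", "z")], faces, label,
                       validate = FALSE)
  extra <- setdiff(pnames, c("x", "y", "z"))
  if (length(extra)) {
    attr(mesh, "scalars") <- stats::setNames(
      lapply(extra, function(nm) unname(vdata[, nm])), extra)
  }
  mesh
}

write_obj <- function(mesh, path) {
  lines <- c(paste("v", apply(mesh$vertices, 1, function(r) {
               paste(format(r, digits = 17), collapse = " ")
             })),
             paste("f", apply(mesh$faces, 1, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

read_obj <- function(path, label = NULL) {
  txt <- readLines(path)
  vl <- strsplit(trimws(grep("^v ", txt, value = TRUE)), "\\s+")
  fl <- strsplit(trimws(grep("^f ", txt, value = TRUE)), "\\s+")
  verts <- t(vapply(vl, function(x) as.numeric(x[2:4]), numeric(3)))
  faces <- t(vapply(fl, function(x) {
    as.integer(sub("/.*$", "", x[2:4]))
  }, integer(3)))
  surface_mesh(verts, faces, label, validate = FALSE)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  fc <- face_cross(mesh)
  len <- sqrt(rowSums(fc^2))
  len[len == 0] <- 1
  nrm <- fc / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    tri <- function(i) {
      c(sprintf("  facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2],
                nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.17g %.17g %.17g", v[f[i, ], 1],
                v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop", "  endfacet")
    }
    writeLines(c("solid mesh", unlist(lapply(seq_len(nrow(f)), tri)),
                 "endsolid mesh"), path)
  }
  invisible(path)
}

read_stl <- function(path, label = NULL) {
  head <- readBin(path, "raw", 5)
  if (rawToChar(head) == "solid" && is_ascii_stl(path)) {
    txt <- readLines(path)
    vl <- strsplit(trimws(grep("vertex", txt, value = TRUE)), "\\s+")
    verts <- t(vapply(vl, function(x) as.numeric(x[2:4]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    verts <- matrix(NA_real_, nf * 3, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "double", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      verts[(i - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, byrow = TRUE)
    }
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  dedup_vertices(surface_mesh(verts, faces, label, validate = FALSE))
}

is_ascii_stl <- function(path) {
  txt <- tryCatch(readLines(path, n = 20, warn = FALSE),
                  error = function(e) character(0))
  any(grepl("facet", txt))
}
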