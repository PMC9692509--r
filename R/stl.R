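#' Read a triangulated surface from an STL file
#'
#' Supports both binary and ASCII STL.  A file is treated as ASCII when it
#' starts with the keyword `solid` and contains a `facet` keyword in its
#' first kilobyte; otherwise it is parsed as little-endian binary STL
#' (80-byte header, uint32 facet count, 50 bytes per facet).  No region
#' labeling is performed; the reader exists so that real airway surfaces can
#' be inspected alongside the synthetic surrogate.
#'
#' @param path file path.
#' @return an object of class `stl_surface`: a list with `facets`
#'   (n-by-3-by-3 array, facet x vertex x coordinate), `normals`
#'   (n-by-3, as stored in the file) and `n_facets`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("read_stl: no such file: ", path)
  size <- file.info(path)$size
  head_raw <- readBin(path, "raw", n = min(size, 1024))
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (size < 84) stop("read_stl: malformed binary STL, file truncated at byte ", size)
  invisible(readBin(con, "raw", n = 80)) # header
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (n < 0 || size < 84 + n * 50) {
    stop("read_stl: malformed binary STL, expected ", 84 + n * 50,
         " bytes for ", n, " facets but file ends at byte ", size)
  }
  body <- readBin(con, "raw", n = n * 50)
  # each record: 12 floats (normal + 3 vertices) + uint16 attribute
  rec <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(rec[1:48, ]), "numeric", size = 4,
                    n = 12L * n, endian = "little")
  vals <- matrix(floats, ncol = 12, byrow = TRUE)
  facets <- array(NA_real_, dim = c(n, 3, 3))
  for (v in 1:3) facets[, v, ] <- vals[, 3 * v + (1:3), drop = FALSE]
  structure(list(facets = facets, normals = vals[, 1:3, drop = FALSE],
                 n_facets = n),
            class = "stl_surface")
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vert_lines <- grep("^\\s*vertex\\s", lines)
  norm_lines <- grep("^\\s*facet\\s+normal\\s", lines)
  if (length(vert_lines) == 0 || length(vert_lines) %% 3 != 0) {
    stop("read_stl: malformed ASCII STL, vertex count ", length(vert_lines),
         " is not a multiple of 3 (near line ",
         if (length(vert_lines)) max(vert_lines) else 1, ")")
  }
  if (!any(grepl("^\\s*endsolid", lines))) {
    stop("read_stl: malformed ASCII STL, missing endsolid (file truncated)")
  }
  num3 <- function(ls, skip) {
    t(vapply(strsplit(trimws(ls), "\\s+"), function(x) {
      v <- suppressWarnings(as.numeric(x[seq(skip + 1, skip + 3)]))
      if (anyNA(v)) stop("read_stl: malformed ASCII STL, unparsable coordinates")
      v
    }, numeric(3)))
  }
  verts <- num3(lines[vert_lines], 1L)
  n <- nrow(verts) / 3L
  facets <- array(NA_real_, dim = c(n, 3, 3))
  for (v in 1:3) facets[, v, ] <- verts[seq(v, by = 3, length.out = n), , drop = FALSE]
  normals <- if (length(norm_lines) == n) num3(lines[norm_lines], 2L) else
    matrix(0, n, 3)
  structure(list(facets = facets, normals = normals, n_facets = n),
            class = "stl_surface")
}

#' Write a triangulated surface to binary STL
#'
#' Vertex coordinates are stored as 32-bit floats (the STL format's native
#' precision), so a write/read round trip reproduces coordinates that were
#' themselves representable as 32-bit floats bitwise.
#'
#' @param surface an `stl_surface`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path) {
  stopifnot(inherits(surface, "stl_surface"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  n <- surface$n_facets
  writeBin(as.integer(n), con, size = 4, endian = "little")
  for (k in seq_len(n)) {
    rec <- c(surface$normals[k, ], surface$facets[k, 1, ],
             surface$facets[k, 2, ], surface$facets[k, 3, ])
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' @export
print.stl_surface <- function(x, ...) {
  rng <- apply(x$facets, 3, range)
  cat("<stl_surface>", x$n_facets, "facets\n")
  cat(sprintf("  bounding box: [%g, %g] x [%g, %g] x [%g, %g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}
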