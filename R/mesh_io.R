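#' Read and write triangle meshes (OBJ and PLY)
#'
#' OBJ files are plain text; `g` statements map to `face_group` ids in file
#' order (an OBJ without groups loads as a single group). PLY files carry
#' the group as a per-face integer property `group`; both `ascii` and
#' `binary_little_endian` PLY are supported, and the binary form round-trips
#' vertices, faces and groups bit-exactly.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path; format inferred from the `.obj`/`.ply` extension
#'   unless `format` is given.
#' @param format `"obj"` or `"ply"`.
#' @param binary for PLY: write `binary_little_endian` (default) or ascii.
#' @return `read_mesh()` returns a [triangle_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
write_mesh <- function(mesh, path, format = guess_format(path), binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  switch(format,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    stop(sprintf("unsupported mesh format '%s'", format))
  )
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = guess_format(path)) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  switch(format,
    obj = read_obj(path),
    ply = read_ply(path),
    stop(sprintf("unsupported mesh format '%s'", format))
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("obj", "ply")) ext else stop(
    sprintf("cannot infer mesh format from '%s'; pass format=", path)
  )
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  ord <- order(mesh$face_group)
  f <- mesh$faces[ord, , drop = FALSE]
  g <- mesh$face_group[ord]
  last <- NA_integer_
  lines <- character(0)
  for (i in seq_along(g)) {
    if (is.na(last) || g[i] != last) {
      lines <- c(lines, sprintf("g group_%d", g[i]))
      last <- g[i]
    }
    lines <- c(lines, sprintf("f %d %d %d", f[i, 1], f[i, 2], f[i, 3]))
  }
  writeLines(lines, con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- list()
  fs <- list()
  gs <- integer(0)
  cur_group <- NA_integer_
  next_group <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "v") {
      if (length(tok) < 4) stop(sprintf("malformed OBJ vertex at line %d", i))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz))) stop(sprintf("malformed OBJ vertex at line %d", i))
      vs[[length(vs) + 1L]] <- xyz
    } else if (tok[1] == "g") {
      next_group <- next_group + 1L
      cur_group <- next_group
    } else if (tok[1] == "f") {
      if (length(tok) < 4) stop(sprintf("malformed OBJ face at line %d", i))
      # keep only the vertex index of v/vt/vn references
      idx <- suppressWarnings(as.integer(vapply(
        strsplit(tok[-1], "/"), `[[`, "", 1L
      )))
      if (any(is.na(idx))) stop(sprintf("malformed OBJ face at line %d", i))
      if (length(idx) > 3) { # fan-triangulate polygons
        for (k in 2:(length(idx) - 1)) {
          fs[[length(fs) + 1L]] <- idx[c(1, k, k + 1)]
          gs <- c(gs, if (is.na(cur_group)) 0L else cur_group)
        }
      } else {
        fs[[length(fs) + 1L]] <- idx
        gs <- c(gs, if (is.na(cur_group)) 0L else cur_group)
      }
    }
  }
  if (length(vs) == 0 || length(fs) == 0) {
    stop(sprintf("malformed OBJ file '%s': no vertices or faces (line %d)",
                 path, length(lines)))
  }
  if (all(gs == 0L)) gs <- rep(0L, length(fs)) # ungrouped OBJ -> group 0
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs), gs)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c(
    "ply", sprintf("format %s 1.0", fmt),
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "property int group",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
      writeBin(as.integer(mesh$face_group[i]), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    v <- mesh$vertices
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf(
      "3 %d %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
      mesh$faces[, 3] - 1L, mesh$face_group
    ), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop(sprintf("malformed PLY '%s': truncated header (line %d)",
                                      path, length(header)))
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 200) stop(sprintf("malformed PLY '%s': no end_header", path))
  }
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop(sprintf("malformed PLY '%s': missing format (line 2)", path))
  binary <- grepl("binary_little_endian", fmt_line)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1 || is.na(nv) || is.na(nf)) {
    stop(sprintf("malformed PLY '%s': missing element counts", path))
  }
  has_group <- any(grepl("^property int group", header))
  vprops <- grep("^property (double|float) ", header, value = TRUE)
  vsize <- ifelse(grepl("double", vprops), 8L, 4L)
  if (binary) {
    v <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(length(vsize))
      for (j in seq_along(vsize)) {
        x <- readBin(con, "double", n = 1, size = vsize[j], endian = "little")
        if (length(x) == 0) stop(sprintf("malformed PLY '%s': truncated vertices (vertex %d)", path, i))
        row[j] <- x
      }
      v[i, ] <- row[1:3]
    }
    f <- matrix(NA_integer_, nf, 3)
    g <- integer(nf)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
      if (length(cnt) == 0) stop(sprintf("malformed PLY '%s': truncated faces (face %d)", path, i))
      if (cnt != 3) stop(sprintf("PLY '%s': face %d is not a triangle", path, i))
      idx <- readBin(con, "integer", n = 3, size = 4, endian = "little")
      if (length(idx) < 3) stop(sprintf("malformed PLY '%s': truncated faces (face %d)", path, i))
      f[i, ] <- idx + 1L
      g[i] <- if (has_group) {
        x <- readBin(con, "integer", n = 1, size = 4, endian = "little")
        if (length(x) == 0) stop(sprintf("malformed PLY '%s': truncated groups (face %d)", path, i))
        x
      } else 0L
    }
  } else {
    body <- readLines(con, warn = FALSE)
    if (length(body) < nv + nf) {
      stop(sprintf("malformed PLY '%s': truncated body (line %d)",
                   path, length(header) + length(body)))
    }
    vrows <- lapply(body[seq_len(nv)], function(x) as.numeric(strsplit(trimws(x), "[[:space:]]+")[[1]]))
    v <- do.call(rbind, vrows)[, 1:3, drop = FALSE]
    frows <- lapply(body[nv + seq_len(nf)], function(x) as.numeric(strsplit(trimws(x), "[[:space:]]+")[[1]]))
    fmat <- do.call(rbind, frows)
    if (any(fmat[, 1] != 3)) stop(sprintf("PLY '%s': non-triangular face", path))
    f <- matrix(as.integer(fmat[, 2:4] + 1L), nf, 3)
    g <- if (has_group && ncol(fmat) >= 5) as.integer(fmat[, 5]) else rep(0L, nf)
  }
  if (any(is.na(v))) stop(sprintf("malformed PLY '%s': bad vertex data", path))
  triangle_mesh(v, f, g)
}
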