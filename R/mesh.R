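#' Triangle mesh container
#'
#' A minimal indexed triangle mesh in millimetres, z-up, with the chamber
#' floor at `z = 0`. Faces are stored counter-clockwise so that the
#' right-hand-rule normal points outward (upward for an upward-facing leaf).
#' Each face carries an integer `face_group` id assigning it to a leaf or a
#' piece of chamber furniture.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param face_group integer vector (length m) of group ids; defaults to a
#'   single group `1L`.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, face_group = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertices contain non-finite coordinates")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (is.null(face_group)) face_group <- rep(1L, nrow(faces))
  face_group <- as.integer(face_group)
  if (length(face_group) != nrow(faces)) {
    stop("face_group must have one id per face")
  }
  m <- structure(
    list(vertices = vertices, faces = faces, face_group = face_group),
    class = "triangle_mesh"
  )
  a <- face_areas(m)
  if (nrow(faces) > 0 && any(a <= 0)) {
    stop("mesh contains degenerate (zero-area) triangles")
  }
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d faces, %d groups\n",
    nrow(x$vertices), nrow(x$faces), length(unique(x$face_group))
  ))
  invisible(x)
}

# per-face one-sided areas in mm^2 (cross-product formula)
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) return(numeric(0))
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' One-sided surface area of a mesh group
#'
#' Sums the triangle areas (cross-product formula) of all faces belonging to
#' `group` and converts mm^2 to cm^2, the unit leaf areas are reported in.
#'
#' @param mesh a [triangle_mesh()].
#' @param group integer group id; `NULL` sums over the whole mesh.
#' @return Area in cm^2.
#' @export
surface_area <- function(mesh, group = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  a <- face_areas(mesh)
  if (is.null(group)) return(sum(a) / 100)
  keep <- mesh$face_group == group
  if (!any(keep)) stop(sprintf("no faces with group id %s in mesh", group))
  sum(a[keep]) / 100
}

# area-weighted mean z (mm) of a group; the height used for the
# leaf-order-vs-height ordering checks
group_mean_height <- function(mesh, group) {
  keep <- mesh$face_group == group
  if (!any(keep)) stop(sprintf("no faces with group id %s in mesh", group))
  f <- mesh$faces[keep, , drop = FALSE]
  zc <- (mesh$vertices[f[, 1], 3] + mesh$vertices[f[, 2], 3] +
    mesh$vertices[f[, 3], 3]) / 3
  a <- face_areas(mesh)[keep]
  sum(zc * a) / sum(a)
}

# concatenate meshes, offsetting the face groups of `b` so ids stay unique
merge_meshes <- function(a, b, group_offset = NULL) {
  if (is.null(group_offset)) {
    group_offset <- if (nrow(a$faces) > 0) max(a$face_group) else 0L
  }
  triangle_mesh(
    rbind(a$vertices, b$vertices),
    rbind(a$faces, b$faces + nrow(a$vertices)),
    c(a$face_group, b$face_group + as.integer(group_offset))
  )
}

# unit-sphere icosahedron refinement, used in tests as an analytic-area oracle
icosphere <- function(radius = 1, subdivisions = 2) {
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
  for (i in seq_len(subdivisions)) {
    nf <- nrow(f)
    newv <- list(v)
    key <- new.env(hash = TRUE)
    nv <- nrow(v)
    midpoint <- function(i1, i2) {
      k <- paste(min(i1, i2), max(i1, i2))
      hit <- key[[k]]
      if (!is.null(hit)) return(hit)
      p <- v[i1, ] + v[i2, ]
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      newv[[length(newv) + 1L]] <<- matrix(p, 1)
      key[[k]] <- nv
      nv
    }
    f2 <- matrix(0L, nf * 4, 3)
    for (j in seq_len(nf)) {
      a <- f[j, 1]; b <- f[j, 2]; cc <- f[j, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      f2[(j - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca)
      )
    }
    v <- do.call(rbind, newv)
    f <- f2
  }
  triangle_mesh(v * radius, f)
}
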