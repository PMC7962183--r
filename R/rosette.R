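#' Specification for a synthetic rosette
#'
#' Parametric stand-in for a 3D-scanned kale rosette: leaves are inserted on
#' a short vertical axis in a spiral-phyllotaxis pattern (successive azimuths
#' separated by the divergence angle, default the golden angle 137.5
#' degrees), with insertion height and petiole elevation increasing from the
#' oldest (bottom) leaf to the youngest (top) leaf. Each leaf is an
#' elliptic-outline lamina swept along a drooping midrib and tessellated
#' into triangles.
#'
#' @param n_leaves number of leaves (leaf order 1 = oldest, bottom).
#' @param divergence_angle azimuthal offset between successive leaves,
#'   degrees in (0, 360).
#' @param area_profile optional per-leaf one-sided areas (cm^2, length
#'   `n_leaves`). When supplied each lamina is rescaled so its mesh area
#'   matches exactly. Default: the package's unimodal kale-like profile
#'   peaking mid-canopy (see [kale_area_profile()]).
#' @param length_width_ratio lamina length / max width.
#' @param elevation_profile petiole elevation per leaf (degrees from
#'   horizontal, length `n_leaves`); defaults to a convex ramp from 20
#'   (oldest, spreading) to 65 (youngest, upright),
#'   `20 + 45 ((k-1)/(n-1))^1.4`.
#' @param droop downward bend of the oldest leaf's midrib over its length
#'   (degrees); the lamina curvature parameter. Droop fades linearly to 0
#'   for the youngest leaf, mimicking the upright habit of expanding
#'   leaves.
#' @param base_height insertion height of leaf 1 above the floor (mm).
#' @param internode vertical spacing between successive insertions (mm).
#' @param triangles_per_leaf target tessellation density.
#' @param seed integer seed for the small azimuth/size jitter.
#' @param jitter relative jitter applied to azimuth (degrees) and lamina
#'   size; 0 gives a perfectly regular rosette.
#' @return An object of class `rosette_spec`.
#' @export
rosette_spec <- function(n_leaves = 10,
                         divergence_angle = 137.5,
                         area_profile = NULL,
                         length_width_ratio = 1.4,
                         elevation_profile = NULL,
                         droop = 35,
                         base_height = 20,
                         internode = 15,
                         triangles_per_leaf = 500,
                         seed = 1L,
                         jitter = 0) {
  if (!is.numeric(n_leaves) || n_leaves < 1) {
    stop("invalid rosette spec: n_leaves must be >= 1")
  }
  n_leaves <- as.integer(n_leaves)
  if (divergence_angle <= 0 || divergence_angle >= 360) {
    stop("invalid rosette spec: divergence_angle must lie in (0, 360)")
  }
  if (is.null(area_profile)) area_profile <- kale_area_profile(n_leaves)
  if (length(area_profile) != n_leaves || any(area_profile <= 0)) {
    stop("invalid rosette spec: area_profile must be positive, one per leaf")
  }
  if (is.null(elevation_profile)) {
    elevation_profile <- if (n_leaves == 1) 45 else {
      20 + 45 * ((seq_len(n_leaves) - 1) / (n_leaves - 1))^1.4
    }
  }
  if (length(elevation_profile) != n_leaves) {
    stop("invalid rosette spec: elevation_profile must have one entry per leaf")
  }
  if (length_width_ratio <= 0) {
    stop("invalid rosette spec: length_width_ratio must be positive")
  }
  if (triangles_per_leaf < 8) {
    stop("invalid rosette spec: triangles_per_leaf must be at least 8")
  }
  structure(
    list(
      n_leaves = n_leaves, divergence_angle = divergence_angle,
      area_profile = area_profile, length_width_ratio = length_width_ratio,
      elevation_profile = elevation_profile, droop = droop,
      base_height = base_height, internode = internode,
      triangles_per_leaf = triangles_per_leaf, seed = as.integer(seed),
      jitter = jitter
    ),
    class = "rosette_spec"
  )
}

#' Unimodal kale-like leaf area profile
#'
#' Default per-leaf one-sided areas (cm^2): small at the senescing bottom
#' leaf, peaking mid-canopy, declining toward the youngest expanding leaves
#' — the shape observed in mature kale rosettes. For ten leaves the values
#' for orders 2..10 follow the published control-plant means of a kale UV-B
#' supplementation experiment; leaf 1 is assigned a small senescent area.
#'
#' @param n_leaves number of leaves.
#' @return Numeric vector of areas (cm^2).
#' @export
kale_area_profile <- function(n_leaves = 10) {
  ref <- c(25, 32.25, 84.49, 168.31, 179.44, 200.07, 182.72, 139.49, 91.2, 49.94)
  if (n_leaves == 10) return(ref)
  prof <- stats::approx(seq(0, 1, length.out = 10), ref,
    xout = seq(0, 1, length.out = n_leaves)
  )$y
  # leaf count proxies plant age: younger rosettes carry proportionally
  # smaller leaves (areas scale with the square of the linear size)
  prof * min(1, n_leaves / 10)^2
}

#' Build a rosette mesh from a spec
#'
#' Leaf `k` is placed at azimuth `(k - 1) * divergence_angle` (mod 360) and
#' insertion height `base_height + (k - 1) * internode`; laminae are
#' tessellated and, when an area profile is given, rescaled uniformly about
#' their insertion point so group areas match the profile. Deterministic for
#' a fixed spec (including its seed).
#'
#' @param spec a [rosette_spec()].
#' @return A list with elements `mesh` (a [triangle_mesh()], face groups =
#'   leaf order) and `leaves` (a data frame with `leaf_order`, `group`,
#'   `azimuth_deg`, `insertion_z_mm`, `mean_z_mm`, `area_cm2`, `optics_id`).
#' @export
build_rosette <- function(spec) {
  stopifnot(inherits(spec, "rosette_spec"))
  rng <- local({
    set.seed(spec$seed)
    function(n) stats::runif(n)
  })
  mesh <- NULL
  rows <- vector("list", spec$n_leaves)
  for (k in seq_len(spec$n_leaves)) {
    az <- ((k - 1) * spec$divergence_angle) %% 360
    az_j <- az + (rng(1) - 0.5) * 2 * spec$jitter * 10 # up to +-10 deg at jitter 1
    size_j <- 1 + (rng(1) - 0.5) * 2 * spec$jitter * 0.1
    h <- spec$base_height + (k - 1) * spec$internode
    # droop fades with youth: senescing bottom leaves bend fully, the
    # youngest leaf stays straight and upright
    droop_k <- if (spec$n_leaves == 1) spec$droop else {
      spec$droop * (1 - (k - 1) / (spec$n_leaves - 1))
    }
    leaf <- lamina_mesh(
      target_area_cm2 = spec$area_profile[k] * size_j,
      lw_ratio = spec$length_width_ratio,
      elevation = spec$elevation_profile[k],
      droop = droop_k,
      azimuth = az_j,
      insertion = c(0, 0, h),
      n_tri = spec$triangles_per_leaf
    )
    leaf$face_group <- rep(k, nrow(leaf$faces))
    mesh <- if (is.null(mesh)) leaf else merge_meshes(mesh, leaf, group_offset = 0L)
    rows[[k]] <- data.frame(
      leaf_order = k, group = k, azimuth_deg = az,
      insertion_z_mm = h, mean_z_mm = NA_real_, area_cm2 = NA_real_,
      optics_id = "leaf"
    )
  }
  leaves <- do.call(rbind, rows)
  leaves$area_cm2 <- vapply(leaves$group, function(g) surface_area(mesh, g), 0)
  leaves$mean_z_mm <- vapply(leaves$group, function(g) group_mean_height(mesh, g), 0)
  list(mesh = mesh, leaves = leaves)
}

# One lamina: elliptic outline of half-width w(s) = (W/2) sqrt(4 s (1 - s))
# swept along a midrib that starts at `elevation` degrees above horizontal
# and bends downward by `droop` degrees over its length. Tessellated as a
# strip grid with triangle fans at the tip rows (no degenerate faces), then
# rescaled uniformly about the insertion point to hit the target area.
lamina_mesh <- function(target_area_cm2, lw_ratio, elevation, droop,
                        azimuth, insertion, n_tri) {
  # grid resolution: ns strips along the midrib, nt across; interior quads
  # give 2 triangles each, the two tip strips give fans
  ns <- max(4L, round(sqrt(n_tri * lw_ratio / 2)))
  nt <- max(2L, round(n_tri / (2 * ns)))
  # provisional length from the smooth-surface area of the elliptic outline
  # (area = pi/4 * L * W); exact match enforced by rescaling below
  L <- sqrt(target_area_cm2 * 100 * lw_ratio * 4 / pi)
  W <- L / lw_ratio
  s <- seq(0, 1, length.out = ns + 1)
  # midrib polyline in the vertical plane of the leaf azimuth
  ang <- (elevation - droop * s) * pi / 180
  dr <- L / ns * cos((ang[-1] + ang[-length(ang)]) / 2)
  dz <- L / ns * sin((ang[-1] + ang[-length(ang)]) / 2)
  rr <- c(0, cumsum(dr))
  zz <- c(0, cumsum(dz))
  halfw <- (W / 2) * sqrt(pmax(0, 4 * s * (1 - s)))
  ca <- cos(azimuth * pi / 180)
  sa <- sin(azimuth * pi / 180)
  along <- c(ca, sa, 0) # radial direction of the midrib in plan
  across <- c(-sa, ca, 0) # horizontal, perpendicular to the midrib plane
  verts <- list()
  idx <- matrix(NA_integer_, ns + 1, nt + 1) # row i: station s[i]
  nv <- 0L
  for (i in seq_len(ns + 1)) {
    if (halfw[i] == 0) {
      nv <- nv + 1L
      verts[[nv]] <- insertion + along * rr[i] + c(0, 0, zz[i])
      idx[i, ] <- nv
    } else {
      t <- seq(-1, 1, length.out = nt + 1)
      for (j in seq_len(nt + 1)) {
        nv <- nv + 1L
        verts[[nv]] <- insertion + along * rr[i] + c(0, 0, zz[i]) +
          across * (t[j] * halfw[i])
        idx[i, j] <- nv
      }
    }
  }
  faces <- list()
  nf <- 0L
  for (i in seq_len(ns)) {
    a <- idx[i, ]
    b <- idx[i + 1, ]
    if (halfw[i] == 0 && halfw[i + 1] == 0) next
    if (halfw[i] == 0) { # base tip fan
      for (j in seq_len(nt)) {
        nf <- nf + 1L
        faces[[nf]] <- c(a[1], b[j], b[j + 1])
      }
    } else if (halfw[i + 1] == 0) { # apex tip fan
      for (j in seq_len(nt)) {
        nf <- nf + 1L
        faces[[nf]] <- c(a[j], b[1], a[j + 1])
      }
    } else {
      for (j in seq_len(nt)) {
        nf <- nf + 1L
        faces[[nf]] <- c(a[j], b[j], b[j + 1])
        nf <- nf + 1L
        faces[[nf]] <- c(a[j], b[j + 1], a[j + 1])
      }
    }
  }
  m <- triangle_mesh(do.call(rbind, verts), do.call(rbind, faces))
  # uniform rescale about the insertion point: exact area match
  sc <- sqrt(target_area_cm2 / surface_area(m))
  m$vertices <- sweep(sweep(m$vertices, 2, insertion) * sc, 2, insertion, "+")
  m
}
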