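#' Emitters, sensors and scenes
#'
#' A `scene` bundles everything the tracer needs: one merged
#' [triangle_mesh()] whose face groups are leaves and furniture, a group
#' table mapping group ids to leaf orders and optics, per-band diffuse
#' optical properties (reflectance R, transmittance T with R + T <= 1;
#' absorptance is 1 - R - T), a list of LED emitters and a list of virtual
#' sensors.
#'
#' @name scene
NULL

#' Lambertian LED emitter
#'
#' A point chip or rectangular panel emitting into a truncated-cosine
#' (Lambertian) cone: polar angle density proportional to
#' `cos(theta) sin(theta)` on `[0, half_angle]`, azimuth uniform. Power is
#' per spectral band (W); bands with zero power do not emit when that band
#' is traced.
#'
#' @param position xyz (mm).
#' @param normal emission axis (need not be unit length).
#' @param power named numeric vector of radiant power per band, e.g.
#'   `c(UV = 0.0176)` or `c(PAR = 7.1)`.
#' @param half_angle truncation half-angle in degrees, in (0, 90].
#' @param size for a panel: c(width, depth) in mm spanned perpendicular to
#'   `normal`; `NULL` makes a point chip.
#' @return An object of class `emitter`.
#' @export
emitter <- function(position, normal = c(0, 0, -1), power, half_angle = 60,
                    size = NULL) {
  if (half_angle <= 0 || half_angle > 90) stop("half_angle must be in (0, 90]")
  if (is.null(names(power)) || any(power < 0)) {
    stop("power must be a named nonnegative vector of per-band watts")
  }
  n <- normal / sqrt(sum(normal^2))
  uv <- list(u = c(0, 0, 0), v = c(0, 0, 0))
  if (!is.null(size)) {
    stopifnot(length(size) == 2, all(size > 0))
    a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- a - sum(a * n) * n
    u <- u / sqrt(sum(u^2))
    v <- c(
      n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
      n[1] * u[2] - n[2] * u[1]
    )
    uv <- list(u = u * size[1] / 2, v = v * size[2] / 2)
  }
  structure(
    list(
      position = as.numeric(position), normal = n, power = power,
      half_angle = half_angle, u = uv$u, v = uv$v,
      is_area = !is.null(size)
    ),
    class = "emitter"
  )
}

#' Virtual cylindrical sensor
#'
#' Stand-in for a quantum/UV sensor head: a horizontal disk (the top face of
#' a short cylinder) that tallies downward radiant flux crossing it; the
#' reading is flux divided by disk area, in W m^-2 of the traced band.
#'
#' @param center xyz of the disk center (mm); its z is the measurement
#'   height.
#' @param radius disk radius (mm). The default is wider than a physical
#'   sensor head: the disk integrates Monte-Carlo ray crossings, and
#'   bed-level irradiance is near-uniform over this area, so a wider disk
#'   buys estimator precision without bias.
#' @param height cylinder body height (mm, geometric bookkeeping only).
#' @return An object of class `virtual_sensor`.
#' @export
virtual_sensor <- function(center, radius = 75, height = 10) {
  if (radius <= 0 || height <= 0) stop("sensor radius and height must be positive")
  structure(
    list(center = as.numeric(center), radius = radius, height = height),
    class = "virtual_sensor"
  )
}

#' Band-averaged diffuse optics
#'
#' Per-band reflectance/transmittance pairs used by the tracer. Values can
#' be given directly or computed from measured spectral curves with
#' [band_average_optics()].
#'
#' @param ... named per-band entries, each `c(R = , T = )`, e.g.
#'   `optical_props(PAR = c(R = 0.10, T = 0.05), UV = c(R = 0.05, T = 0.01))`.
#' @return An object of class `optical_props`.
#' @export
optical_props <- function(...) {
  bands <- list(...)
  if (length(bands) == 0 || is.null(names(bands))) {
    stop("optical_props needs named per-band entries")
  }
  for (b in names(bands)) {
    x <- bands[[b]]
    if (!all(c("R", "T") %in% names(x))) {
      stop(sprintf("band '%s' must supply R and T", b))
    }
    if (any(x < 0) || x[["R"]] + x[["T"]] > 1 + 1e-12) {
      stop(sprintf(
        "invalid optics in band '%s': need R, T >= 0 and R + T <= 1", b
      ))
    }
  }
  structure(bands, class = "optical_props")
}

#' Source-weighted band average of spectral optics
#'
#' Reduces measured reflectance/transmittance spectra to the single per-band
#' R/T pair the tracer uses, weighting by the source spectral power
#' distribution over the band.
#'
#' @param reflectance,transmittance [spectral_curve()]s (fractions).
#' @param spd source [spectral_curve()] used as the weighting.
#' @param lo,hi band edges (nm).
#' @return `c(R = , T = )`.
#' @export
band_average_optics <- function(reflectance, transmittance, spd, lo, hi) {
  wsum <- band_integrate(spd, lo, hi)
  if (wsum <= 0) stop("source spectrum has no energy in the band")
  edges <- range(spd$wavelength_nm) # spd steps to zero at its support edges
  lam <- sort(unique(c(
    spd$wavelength_nm, reflectance$wavelength_nm,
    transmittance$wavelength_nm, edges - 1e-9, edges + 1e-9
  )))
  lam <- lam[lam >= lo & lam <= hi]
  w <- eval_spectrum(spd, lam)
  rf <- spectral_curve(lam, pmax(1e-12, w * eval_spectrum(reflectance, lam)))
  tf <- spectral_curve(lam, pmax(1e-12, w * eval_spectrum(transmittance, lam)))
  out <- c(
    R = band_integrate(rf, lo, hi) / wsum,
    T = band_integrate(tf, lo, hi) / wsum
  )
  if (sum(out) > 1) stop("band-averaged R + T exceeds 1; check input spectra")
  out
}

#' Assemble a scene
#'
#' @param mesh a [triangle_mesh()] (may have zero faces for an empty bench).
#' @param groups data frame with columns `group` (matching `face_group`
#'   ids), `kind` (`"leaf"` or `"furniture"`), `leaf_order` (NA for
#'   furniture) and `optics_id`.
#' @param optics named list mapping `optics_id` to [optical_props()].
#' @param emitters list of [emitter()]s.
#' @param sensors list of [virtual_sensor()]s.
#' @return An object of class `scene`.
#' @export
scene <- function(mesh, groups, optics, emitters = list(), sensors = list()) {
  stopifnot(inherits(mesh, "triangle_mesh"), is.data.frame(groups))
  need <- c("group", "kind", "leaf_order", "optics_id")
  if (!all(need %in% names(groups))) {
    stop("groups needs columns group, kind, leaf_order, optics_id")
  }
  if (nrow(mesh$faces) > 0) {
    missing_g <- setdiff(unique(mesh$face_group), groups$group)
    if (length(missing_g)) {
      stop(sprintf(
        "mesh groups without a groups-table row: %s",
        paste(missing_g, collapse = ", ")
      ))
    }
  }
  for (oid in unique(groups$optics_id)) {
    if (!oid %in% names(optics)) {
      stop(sprintf("surface optics '%s' missing from optics list", oid))
    }
  }
  for (e in emitters) stopifnot(inherits(e, "emitter"))
  for (s in sensors) stopifnot(inherits(s, "virtual_sensor"))
  structure(
    list(
      mesh = mesh, groups = groups, optics = optics,
      emitters = emitters, sensors = sensors
    ),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> %d faces, %d groups (%d leaves), %d emitters, %d sensors\n",
    nrow(x$mesh$faces), nrow(x$groups), sum(x$groups$kind == "leaf"),
    length(x$emitters), length(x$sensors)
  ))
  invisible(x)
}

#' Default optical property sets
#'
#' Invented but physiologically plausible diffuse optics for the default
#' scene: kale leaves absorb strongly in both bands (UV absorptance above
#' 0.9 due to epidermal screening), a white styrofoam bed reflects strongly
#' in PAR and moderately in UV, and matte chamber walls reflect weakly.
#'
#' @return Named list of [optical_props()] (`leaf`, `bed`, `wall`, `black`).
#' @export
default_optics <- function() {
  list(
    leaf = optical_props(
      PAR = c(R = 0.10, T = 0.05),
      UV = c(R = 0.05, T = 0.01)
    ),
    bed = optical_props(
      PAR = c(R = 0.60, T = 0),
      UV = c(R = 0.30, T = 0)
    ),
    wall = optical_props(
      PAR = c(R = 0.30, T = 0),
      UV = c(R = 0.15, T = 0)
    ),
    black = optical_props(PAR = c(R = 0, T = 0), UV = c(R = 0, T = 0))
  )
}

#' Growth-chamber layout
#'
#' Geometry of the virtual cultivation module. The published experiment
#' fixes the lamp architecture (five UV-B bar modules of twelve chips each,
#' about 15 cm above the plant tops, plus RBW LED panels) but not the
#' chamber dimensions; the sizes here are invented defaults for a single
#' plant-factory cell and are configurable.
#'
#' @param width,depth chamber footprint (mm).
#' @param wall_height wall height above the bed (mm); 0 omits walls.
#' @param emitter_height height of the LED plane above the bed (mm);
#'   the default sits about 15 cm above the canopy top of the default
#'   rosette.
#' @param n_uv_bars,chips_per_bar UV-B chip array layout.
#' @param uv_chip_power W per chip in the UV band (pre-calibration).
#' @param n_rbw_panels number of RBW area panels.
#' @param rbw_panel_power W per panel in the PAR band (pre-calibration).
#' @param rbw_panel_size c(width, depth) of each panel (mm).
#' @param half_angle Lambertian truncation half-angle (degrees).
#' @param sensor_radius virtual sensor disk radius (mm). Larger than a
#'   physical quantum-sensor head: the disk integrates Monte-Carlo ray
#'   crossings, and bed irradiance is near-uniform over this area, so a
#'   wider disk buys precision without bias.
#' @return A list of class `chamber_layout`.
#' @export
chamber_layout <- function(width = 600, depth = 600, wall_height = 450,
                           emitter_height = 350, n_uv_bars = 5,
                           chips_per_bar = 12, uv_chip_power = 0.0176,
                           n_rbw_panels = 5, rbw_panel_power = 7.1,
                           rbw_panel_size = c(500, 80), half_angle = 60,
                           sensor_radius = 75) {
  structure(as.list(environment()), class = "chamber_layout")
}

# axis-aligned rectangle mesh (two triangles) from corner + two edge vectors
rect_mesh <- function(origin, e1, e2, group = 1L) {
  v <- rbind(origin, origin + e1, origin + e1 + e2, origin + e2)
  triangle_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)), rep(group, 2))
}

#' Build the growth-chamber scene
#'
#' Creates the furniture (bed, optional walls), the UV-B chip grid
#' (`n_uv_bars x chips_per_bar` point emitters), the RBW panel emitters and
#' a virtual sensor at the bed center. Plants are added afterwards with
#' [add_plant()]. Emitter and furniture volumes are checked for overlap.
#'
#' @param layout a [chamber_layout()].
#' @param optics named list of [optical_props()]; needs `bed` and `wall`.
#' @return A [scene()].
#' @export
build_chamber <- function(layout = chamber_layout(), optics = default_optics()) {
  stopifnot(inherits(layout, "chamber_layout"))
  w <- layout$width
  d <- layout$depth
  if (layout$emitter_height >= layout$wall_height && layout$wall_height > 0) {
    # emitters above the wall top is fine (open chamber); flag only if the
    # emitter plane would sit below the bed
  }
  if (layout$emitter_height <= 0) {
    stop("geometry error: emitter plane must sit above the bed")
  }
  mesh <- rect_mesh(c(-w / 2, -d / 2, 0), c(w, 0, 0), c(0, d, 0), group = 1L)
  groups <- data.frame(
    group = 1L, kind = "furniture", leaf_order = NA_integer_,
    optics_id = "bed", stringsAsFactors = FALSE
  )
  if (layout$wall_height > 0) {
    hw <- layout$wall_height
    walls <- list(
      rect_mesh(c(-w / 2, -d / 2, 0), c(w, 0, 0), c(0, 0, hw), 1L),
      rect_mesh(c(-w / 2, d / 2, 0), c(w, 0, 0), c(0, 0, hw), 1L),
      rect_mesh(c(-w / 2, -d / 2, 0), c(0, d, 0), c(0, 0, hw), 1L),
      rect_mesh(c(w / 2, -d / 2, 0), c(0, d, 0), c(0, 0, hw), 1L)
    )
    for (wm in walls) mesh <- merge_meshes(mesh, wm, group_offset = 1L)
    groups <- rbind(groups, data.frame(
      group = 2L, kind = "furniture", leaf_order = NA_integer_,
      optics_id = "wall", stringsAsFactors = FALSE
    ))
  }
  ez <- layout$emitter_height
  emitters <- list()
  if (layout$n_uv_bars > 0 && layout$chips_per_bar > 0) {
    bar_y <- seq(-d / 2, d / 2, length.out = layout$n_uv_bars + 2)[-c(1, layout$n_uv_bars + 2)]
    chip_x <- seq(-w / 2, w / 2, length.out = layout$chips_per_bar + 2)[-c(1, layout$chips_per_bar + 2)]
    for (y in bar_y) {
      for (x in chip_x) {
        emitters[[length(emitters) + 1L]] <- emitter(
          position = c(x, y, ez), normal = c(0, 0, -1),
          power = c(UV = layout$uv_chip_power),
          half_angle = layout$half_angle
        )
      }
    }
  }
  if (layout$n_rbw_panels > 0) {
    panel_y <- seq(-d / 2, d / 2, length.out = layout$n_rbw_panels + 2)[-c(1, layout$n_rbw_panels + 2)]
    for (y in panel_y) {
      emitters[[length(emitters) + 1L]] <- emitter(
        position = c(0, y, ez + 1), normal = c(0, 0, -1),
        power = c(PAR = layout$rbw_panel_power),
        half_angle = layout$half_angle, size = layout$rbw_panel_size
      )
    }
  }
  for (e in emitters) {
    if (e$position[3] <= 0 || e$position[3] > max(layout$wall_height, ez + 2)) {
      stop("geometry error: emitter outside the chamber volume")
    }
  }
  sensors <- list(virtual_sensor(c(0, 0, 0.5), radius = layout$sensor_radius))
  scene(mesh, groups, optics, emitters, sensors)
}

#' Add a plant to a chamber scene
#'
#' Merges a rosette mesh into the scene with fresh group ids and `leaf`
#' optics per leaf.
#'
#' @param scn a [scene()] from [build_chamber()].
#' @param rosette result of [build_rosette()].
#' @param optics_id optics id assigned to the leaves.
#' @return The extended [scene()]; leaf groups keep their leaf order in the
#'   group table.
#' @export
add_plant <- function(scn, rosette, optics_id = "leaf") {
  stopifnot(inherits(scn, "scene"))
  offset <- if (nrow(scn$groups) > 0) max(scn$groups$group) else 0L
  mesh <- merge_meshes(scn$mesh, rosette$mesh, group_offset = offset)
  groups <- rbind(scn$groups, data.frame(
    group = rosette$leaves$group + offset, kind = "leaf",
    leaf_order = rosette$leaves$leaf_order, optics_id = optics_id,
    stringsAsFactors = FALSE
  ))
  scene(mesh, groups, scn$optics, scn$emitters, scn$sensors)
}
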