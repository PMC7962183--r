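#' Sample emission rays from a Lambertian LED
#'
#' Draws ray origins and directions from an [emitter()]: polar angle from
#' the truncated-cosine density (proportional to `cos(theta) sin(theta)` on
#' `[0, half_angle]`, i.e. CDF `sin^2(theta) / sin^2(theta_max)`), azimuth
#' uniform, origins uniform over the panel for area emitters. Uses R's RNG,
#' so `set.seed()` makes the stream reproducible.
#'
#' @param em an [emitter()].
#' @param n number of rays.
#' @param band band name whose power sets the per-ray weight.
#' @return List with `origin` (n x 3), `direction` (n x 3, unit),
#'   `theta_deg` (polar angle from the emitter axis) and `weight`
#'   (W per ray).
#' @export
sample_emission <- function(em, n, band = names(em$power)[1]) {
  stopifnot(inherits(em, "emitter"))
  smax <- sin(em$half_angle * pi / 180)
  st <- sqrt(stats::runif(n)) * smax
  ct <- sqrt(pmax(0, 1 - st^2))
  phi <- stats::runif(n, 0, 2 * pi)
  nrm <- em$normal
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(
    a[2] * nrm[3] - a[3] * nrm[2], a[3] * nrm[1] - a[1] * nrm[3],
    a[1] * nrm[2] - a[2] * nrm[1]
  )
  u <- u / sqrt(sum(u^2))
  v <- c(
    nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
    nrm[1] * u[2] - nrm[2] * u[1]
  )
  dir <- cbind(
    st * cos(phi) * u[1] + st * sin(phi) * v[1] + ct * nrm[1],
    st * cos(phi) * u[2] + st * sin(phi) * v[2] + ct * nrm[2],
    st * cos(phi) * u[3] + st * sin(phi) * v[3] + ct * nrm[3]
  )
  org <- matrix(rep(em$position, each = n), n, 3)
  if (em$is_area) {
    aa <- stats::runif(n, -1, 1)
    bb <- stats::runif(n, -1, 1)
    org <- org + outer(aa, em$u) + outer(bb, em$v)
  }
  pw <- if (band %in% names(em$power)) em$power[[band]] else 0
  list(
    origin = org, direction = dir,
    theta_deg = acos(pmin(1, pmax(-1, ct))) * 180 / pi,
    weight = pw / n
  )
}

#' Ray-mesh intersection
#'
#' Nearest-hit intersection of rays against a mesh, either through the BVH
#' acceleration structure (default) or by brute-force testing of every
#' triangle (the oracle the BVH is validated against).
#'
#' @param mesh a [triangle_mesh()].
#' @param origins,directions n x 3 matrices.
#' @param method `"bvh"` or `"brute"`.
#' @return Data frame with `face` (1-based index, `NA` on miss) and `t`
#'   (distance in mm).
#' @export
intersect_rays <- function(mesh, origins, directions, method = c("bvh", "brute")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  method <- match.arg(method)
  origins <- matrix(as.numeric(origins), ncol = 3)
  directions <- matrix(as.numeric(directions), ncol = 3)
  res <- .cpp_intersect(
    mesh$vertices, mesh$faces - 1L, origins, directions,
    method == "brute"
  )
  data.frame(
    face = ifelse(res$face == 0L, NA_integer_, res$face),
    t = res$t
  )
}

#' Sample a single surface interaction
#'
#' Given band-averaged diffuse reflectance `R` and transmittance `T`
#' (`R + T <= 1`), each incident packet is absorbed with probability
#' `1 - R - T`, diffusely reflected with probability `R` (cosine-weighted
#' about the incident-side normal) or diffusely transmitted with
#' probability `T` (cosine-weighted about the far-side normal). This is the
#' interaction model the tracer applies at every hit, exposed for
#' distributional testing.
#'
#' @param normal surface normal at the hit (any orientation).
#' @param incident incident ray direction.
#' @param R,T reflectance and transmittance.
#' @param n number of samples.
#' @param seed integer seed.
#' @return List with `outcome` (factor absorb/reflect/transmit) and
#'   `direction` (n x 3, `NA` rows for absorbed packets).
#' @export
surface_interaction <- function(normal, incident, R, T, n = 1, seed = 1) {
  res <- .cpp_scatter(as.numeric(normal), as.numeric(incident),
                      R, T, as.integer(n), as.double(seed))
  list(
    outcome = factor(c("absorb", "reflect", "transmit")[res$outcome + 1L],
                     levels = c("absorb", "reflect", "transmit")),
    direction = res$direction
  )
}

#' Monte-Carlo radiation interception
#'
#' Traces `n_rays` photon packets per band through the scene and tallies
#' per-group absorbed radiant flux. Each interaction absorbs, diffusely
#' reflects or diffusely transmits the whole packet with probabilities
#' `1 - R - T`, `R`, `T` (analog sampling), so the energy ledger
#' `emitted = absorbed + escaped + terminated` is an exact accounting
#' identity. The Monte-Carlo standard error comes from batch means.
#'
#' @param scn a [scene()].
#' @param n_rays rays per band.
#' @param bands character vector of band names to trace; default all bands
#'   with nonzero emitter power.
#' @param max_bounces interactions before a packet is terminated.
#' @param n_batches batches for the standard-error estimate (>= 10).
#' @param seed integer seed; band `b` uses `seed + 1000003 * (b - 1)`.
#' @return An `interception_tally`: list with `tally` (data frame: `group`,
#'   `kind`, `leaf_order`, `band`, `absorbed_w`, `area_cm2`,
#'   `irradiance_w_m2`, `stderr_w`), `balance` (per band: emitted, absorbed,
#'   escaped, terminated, counts) and `sensor` (per band x sensor readings,
#'   W m^-2).
#' @export
trace <- function(scn, n_rays = 1e5, bands = NULL, max_bounces = 10,
                  n_batches = 10, seed = 1) {
  stopifnot(inherits(scn, "scene"))
  if (n_rays < 1) stop("n_rays must be >= 1")
  if (n_batches < 2) stop("n_batches must be >= 2")
  all_bands <- unique(unlist(lapply(scn$emitters, function(e) names(e$power))))
  if (is.null(bands)) bands <- all_bands
  if (length(bands) == 0 || length(scn$emitters) == 0) {
    return(empty_tally(scn, bands))
  }
  # groups must be contiguous for the C++ tally; map ids -> 1..G
  gids <- sort(unique(scn$groups$group))
  gmap <- match(scn$mesh$face_group, gids)
  grows <- scn$groups[match(gids, scn$groups$group), ]
  areas <- vapply(gids, function(g) surface_area(scn$mesh, g), 0)
  out <- list()
  balance <- list()
  sensor <- list()
  for (bi in seq_along(bands)) {
    band <- bands[bi]
    # per-band optics; every surface must have optics for the traced band
    RT <- vapply(grows$optics_id, function(oid) {
      op <- scn$optics[[oid]]
      if (!band %in% names(op)) {
        stop(sprintf(
          "configuration error: optics '%s' has no band '%s'", oid, band
        ))
      }
      op[[band]][c("R", "T")]
    }, c(R = 0, T = 0))
    emat <- emitter_matrix(scn$emitters, band)
    if (nrow(emat) == 0) next
    smat <- sensor_matrix(scn$sensors)
    res <- .cpp_trace(
      scn$mesh$vertices, scn$mesh$faces - 1L, gmap - 1L, length(gids),
      RT["R", ], RT["T", ], emat, smat, as.double(n_rays),
      as.integer(max_bounces), as.integer(n_batches),
      as.double(seed + 1000003 * (bi - 1))
    )
    bm <- res$absorbed_batch * n_batches # per-batch flux estimates
    stderr_w <- apply(bm, 1, stats::sd) / sqrt(n_batches)
    out[[band]] <- data.frame(
      group = gids, kind = grows$kind, leaf_order = grows$leaf_order,
      band = band, absorbed_w = res$absorbed, area_cm2 = areas,
      irradiance_w_m2 = res$absorbed / (areas * 1e-4),
      stderr_w = stderr_w, stringsAsFactors = FALSE
    )
    balance[[band]] <- list(
      emitted = res$emitted, absorbed = sum(res$absorbed),
      escaped = res$escaped, terminated = res$terminated,
      counts = res$counts
    )
    if (length(scn$sensors)) {
      sensor[[band]] <- res$sensor_flux /
        (pi * vapply(scn$sensors, function(s) s$radius, 0)^2 * 1e-6)
    }
  }
  structure(
    list(
      tally = do.call(rbind, out), balance = balance, sensor = sensor,
      n_rays = n_rays, seed = seed
    ),
    class = "interception_tally"
  )
}

empty_tally <- function(scn, bands) {
  structure(
    list(
      tally = data.frame(
        group = integer(0), kind = character(0), leaf_order = integer(0),
        band = character(0), absorbed_w = numeric(0), area_cm2 = numeric(0),
        irradiance_w_m2 = numeric(0), stderr_w = numeric(0)
      ),
      balance = list(), sensor = list(), n_rays = 0, seed = NA
    ),
    class = "interception_tally"
  )
}

#' @export
print.interception_tally <- function(x, ...) {
  cat(sprintf(
    "<interception_tally> %d groups x %d band(s), %g rays/band\n",
    length(unique(x$tally$group)), length(unique(x$tally$band)), x$n_rays
  ))
  leaves <- x$tally[x$tally$kind == "leaf", ]
  if (nrow(leaves)) print(utils::head(leaves, 12), row.names = FALSE)
  invisible(x)
}

#' Energy-balance check of a tally
#'
#' Relative imbalance `|emitted - absorbed - escaped - terminated| /
#' emitted` per band; an accounting identity that must hold to numerical
#' precision for any analog trace.
#'
#' @param tally an `interception_tally`.
#' @return Named numeric vector (one entry per band).
#' @export
energy_balance_error <- function(tally) {
  vapply(tally$balance, function(b) {
    abs(b$emitted - b$absorbed - b$escaped - b$terminated) / b$emitted
  }, 0)
}

#' Per-leaf interception table
#'
#' @param tally an `interception_tally`.
#' @param band optional band filter.
#' @return The leaf rows of the tally, ordered by leaf order.
#' @export
leaf_interception <- function(tally, band = NULL) {
  d <- tally$tally[tally$tally$kind == "leaf", ]
  if (!is.null(band)) d <- d[d$band == band, ]
  d[order(d$band, d$leaf_order), ]
}

#' Write a tally to CSV
#'
#' @param tally an `interception_tally`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tally, path) {
  utils::write.csv(tally$tally, path, row.names = FALSE)
  invisible(path)
}

emitter_matrix <- function(emitters, band) {
  rows <- lapply(emitters, function(e) {
    pw <- if (band %in% names(e$power)) e$power[[band]] else 0
    if (pw <= 0) return(NULL)
    c(e$position, e$normal, e$u, e$v, e$half_angle, pw)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(matrix(numeric(0), 0, 14))
  }
  do.call(rbind, rows)
}

sensor_matrix <- function(sensors) {
  if (length(sensors) == 0) {
    return(matrix(numeric(0), 0, 4))
  }
  do.call(rbind, lapply(sensors, function(s) c(s$center, s$radius)))
}

#' Calibrate emitter power against a virtual sensor
#'
#' Runs a pilot trace, reads the first virtual sensor in the requested band,
#' and scales every emitter power in that band by `target / reading` —
#' valid because radiative transport is linear in source power. The
#' calibrated scene re-traces to the target reading within Monte-Carlo
#' error.
#'
#' @param scn a [scene()] with at least one sensor.
#' @param target_w_m2 desired sensor reading (W m^-2) in `band`.
#' @param band band to calibrate.
#' @param n_rays pilot rays.
#' @param seed pilot seed.
#' @return List with `scene` (rescaled), `scale`, `pilot_reading`.
#' @export
calibrate_power <- function(scn, target_w_m2, band, n_rays = 2e5, seed = 99) {
  stopifnot(inherits(scn, "scene"))
  if (length(scn$sensors) == 0) stop("calibration needs a virtual sensor")
  pilot <- trace(scn, n_rays = n_rays, bands = band, seed = seed)
  s0 <- pilot$sensor[[band]][1]
  if (!length(s0) || is.na(s0) || s0 <= 0) {
    stop("calibration error: sensor received no light in the pilot trace")
  }
  k <- target_w_m2 / s0
  scn$emitters <- lapply(scn$emitters, function(e) {
    if (band %in% names(e$power)) e$power[[band]] <- e$power[[band]] * k
    e
  })
  list(scene = scn, scale = k, pilot_reading = s0)
}
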