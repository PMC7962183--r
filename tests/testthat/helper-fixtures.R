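# Shared in-code fixtures for the test suite.

# right triangle with legs `leg` mm in the z = 0 plane
right_triangle_mesh <- function(leg = 10) {
  triangle_mesh(
    rbind(c(0, 0, 0), c(leg, 0, 0), c(0, leg, 0)),
    rbind(c(1, 2, 3))
  )
}

# large square "floor" centred at origin at height z, given one-band optics
floor_scene <- function(half = 1e4, z = 0, R = 0, T = 0, band = "UV",
                        emitters = list(), sensors = list()) {
  m <- rect_mesh(c(-half, -half, z), c(2 * half, 0, 0), c(0, 2 * half, 0), 1L)
  groups <- data.frame(
    group = 1L, kind = "furniture", leaf_order = NA_integer_,
    optics_id = "mat", stringsAsFactors = FALSE
  )
  args <- list()
  args[[band]] <- c(R = R, T = T)
  scene(m, groups, list(mat = do.call(optical_props, args)), emitters, sensors)
}

# small black square patch of side `side` mm centred on the z-axis
patch_scene <- function(side = 10, z = 0, band = "UV", emitters = list()) {
  h <- side / 2
  m <- rect_mesh(c(-h, -h, z), c(side, 0, 0), c(0, side, 0), 1L)
  groups <- data.frame(
    group = 1L, kind = "leaf", leaf_order = 1L,
    optics_id = "black", stringsAsFactors = FALSE
  )
  args <- list()
  args[[band]] <- c(R = 0, T = 0)
  scene(m, groups, list(black = do.call(optical_props, args)), emitters)
}

# random ray bundle aimed broadly at the origin from a shell of radius r
random_rays <- function(n, r = 50, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  origins <- u * r
  targets <- matrix(runif(3 * n, -5, 5), n, 3)
  dirs <- targets - origins
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(origins = origins, dirs = dirs)
}

# internal helpers used directly by tests
rect_mesh <- rosetrace:::rect_mesh
icosphere <- rosetrace:::icosphere
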