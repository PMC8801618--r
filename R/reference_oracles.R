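#' Infinite-medium diffusion Green's function
#'
#' `Phi(r) = exp(-mu_eff r) / (4 pi D r)` with `mu_eff = sqrt(mu_a / D)`:
#' the fluence at distance r from a unit point source in an infinite
#' homogeneous medium under the diffusion approximation. Serves as the
#' analytic oracle for the DE finite-element solver several transport
#' lengths away from sources and boundaries.
#'
#' @param props an `optical_properties` object.
#' @param r source-detector distance(s) (mm, > 0).
#' @return fluence per unit source power (mm^-2).
#' @export
de_greens_function <- function(props, r) {
  if (any(r <= 0)) stop("r must be positive")
  D <- diffusion_coefficient(props)
  mu_eff <- sqrt(props$mu_a / D)
  exp(-mu_eff * r) / (4 * pi * D * r)
}

#' Configure a Monte Carlo photon-transport run
#'
#' The MC oracle uses a voxelised geometry deliberately independent of the
#' tetrahedral FEM meshes. The `geometry` is a `phantom_spec` (voxelised by
#' centroid-inside tests) or a pre-built voxel grid.
#'
#' @param geometry a `phantom_spec`, or a list with `tissue` (3-D integer
#'   array, 0 = outside), `origin` (corner, mm) and `voxel` (edge, mm).
#' @param props named list of `optical_properties`; names must cover the
#'   tissues present.
#' @param n_photons photon count (> 0).
#' @param seed RNG seed (mandatory; fixed seed gives bit-identical output).
#' @param source list with `center`, `radius` (0 = point source); photons
#'   launch isotropically, uniformly over the source volume, unit weight.
#' @param voxel voxel edge length used when voxelising a `phantom_spec`
#'   (mm; default 0.5).
#' @param n_outside refractive index outside the medium (default 1).
#' @param roulette_wmin,roulette_psurv Russian-roulette threshold and
#'   survival probability (MCML-style defaults 1e-4 and 0.1).
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(geometry, props, n_photons, seed, source,
                      voxel = 0.5, n_outside = 1,
                      roulette_wmin = 1e-4, roulette_psurv = 0.1) {
  stopifnot(n_photons > 0)
  if (missing(seed)) stop("seed is mandatory in the MC config")
  if (inherits(geometry, "phantom_spec"))
    geometry <- voxelize_spec(geometry, voxel)
  structure(list(geometry = geometry, props = props,
                 n_photons = as.integer(n_photons), seed = seed,
                 source = source, n_outside = n_outside,
                 roulette_wmin = roulette_wmin,
                 roulette_psurv = roulette_psurv),
            class = "mc_config")
}

# voxelise a phantom_spec: integer tissue ids on a regular grid
voxelize_spec <- function(spec, voxel) {
  box <- switch(spec$geometry,
    sphere = rbind(-spec$size[1L] * c(1, 1, 1), spec$size[1L] * c(1, 1, 1)),
    cylinder = rbind(c(-spec$size[1L], -spec$size[1L], 0),
                     c(spec$size[1L], spec$size[1L], spec$size[2L])),
    slab = rbind(c(0, 0, 0), spec$size))
  nx <- ceiling((box[2L, ] - box[1L, ]) / voxel)
  cx <- box[1L, 1L] + voxel * (seq_len(nx[1L]) - 0.5)
  cy <- box[1L, 2L] + voxel * (seq_len(nx[2L]) - 0.5)
  cz <- box[1L, 3L] + voxel * (seq_len(nx[3L]) - 0.5)
  cent <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  tiss <- character(nrow(cent))
  inside <- inside_geometry(spec, cent)
  tiss[inside] <- spec$tissue
  for (inc in spec$inclusions) {
    d2 <- rowSums((cent - matrix(inc$center, nrow(cent), 3L, byrow = TRUE))^2)
    tiss[inside & d2 <= inc$radius^2] <- inc$tissue
  }
  levels <- unique(tiss[inside])
  ids <- integer(nrow(cent))
  ids[inside] <- match(tiss[inside], levels)
  list(tissue = array(ids, dim = nx), origin = box[1L, ], voxel = voxel,
       tissues = levels)
}

#' Run the Monte Carlo photon-transport oracle
#'
#' Photon-weight random walk with exponential step sampling on
#' `mu_t = mu_a + mu_s`, Henyey-Greenstein scattering, absorption by weight
#' attenuation with Russian roulette, and unpolarised Fresnel partial
#' reflection at the outer refractive boundary. Outputs are normalised per
#' launched photon.
#'
#' @param config an `mc_config`.
#' @return an object of class `mc_result`: list with `exit` (data.frame of
#'   exit positions, directions, weights), `fluence` (3-D array of interior
#'   fluence, weight/(mu_a * voxel volume * N) per voxel), `absorbed` (3-D
#'   array of absorbed weight), `totals` (launched/absorbed/exited/roulette
#'   weights) and the grid description.
#' @export
mc_simulate <- function(config) {
  g <- config$geometry
  tisnames <- g$tissues %||% names(config$props)
  missing <- setdiff(tisnames, names(config$props))
  if (length(missing))
    stop("optical properties missing for tissue(s): ",
         paste(missing, collapse = ", "))
  pr <- t(vapply(tisnames, function(nm) {
    p <- config$props[[nm]]
    c(p$mu_a, p$mu_s, p$g, p$refractive_index)
  }, numeric(4)))
  res <- .mc_run_cpp(as.integer(g$tissue), dim(g$tissue),
                     as.numeric(g$origin), g$voxel, pr,
                     config$n_outside, config$n_photons,
                     as.numeric(config$seed),
                     as.numeric(config$source$center),
                     as.numeric(config$source$radius %||% 0),
                     config$roulette_wmin, config$roulette_psurv)
  dims <- dim(g$tissue)
  absorbed <- array(res$absorbed, dim = dims)
  mua_vox <- array(0, dim = dims)
  for (i in seq_along(tisnames))
    mua_vox[g$tissue == i] <- pr[i, 1L]
  fl <- array(0, dim = dims)
  pos <- mua_vox > 0
  fl[pos] <- absorbed[pos] / (mua_vox[pos] * g$voxel^3 * config$n_photons)
  structure(list(
    exit = res$exit,
    absorbed = absorbed, fluence = fl,
    totals = c(launched = res$launched, absorbed = res$total_absorbed,
               exited = res$total_exited, roulette = res$roulette_delta),
    grid = g, n_photons = config$n_photons, seed = config$seed),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("mc_result:", x$n_photons, "photons, seed", x$seed, "\n")
  tt <- x$totals
  cat(sprintf("  absorbed %.4f, exited %.4f, roulette %.4g (per photon)\n",
              tt["absorbed"] / tt["launched"], tt["exited"] / tt["launched"],
              tt["roulette"] / tt["launched"]))
  invisible(x)
}

#' Bin surface exit power over equal-area angular patches of a sphere
#'
#' Partitions directions about `center` into `n_theta x n_phi` patches,
#' uniform in `cos(theta)` and azimuth (equal solid angle). Used to compare
#' MC exitance with FEM boundary fluence on matched surface samples.
#'
#' @param points m x 3 positions (exit events or face centroids).
#' @param weights length-m weights (exit weight, or flux times face area).
#' @param center sphere center.
#' @param n_theta,n_phi patch counts (defaults 6 and 8).
#' @return data.frame with one row per patch: `bin`, `power` (summed
#'   weight), and patch centroid direction.
#' @export
bin_surface_sphere <- function(points, weights, center = c(0, 0, 0),
                               n_theta = 6L, n_phi = 8L) {
  points <- as.matrix(points)
  d <- points - matrix(center, nrow(points), 3L, byrow = TRUE)
  r <- sqrt(rowSums(d^2))
  ct <- d[, 3L] / pmax(r, 1e-300)
  phi <- atan2(d[, 2L], d[, 1L])
  it <- pmin(pmax(floor((ct + 1) / 2 * n_theta), 0), n_theta - 1L)
  ip <- pmin(pmax(floor((phi + pi) / (2 * pi) * n_phi), 0), n_phi - 1L)
  bin <- as.integer(it * n_phi + ip + 1L)
  power <- vapply(seq_len(n_theta * n_phi), function(b)
    sum(weights[bin == b]), numeric(1))
  data.frame(bin = seq_len(n_theta * n_phi), power = power)
}

#' Select the highest-signal surface nodes
#'
#' Returns the indices of the `k` nodes with the largest reference values,
#' mirroring the practice of comparing models on the highest-energy surface
#' detection points.
#'
#' @param values numeric vector (e.g. measured fluence).
#' @param k number of nodes to keep.
#' @return integer indices of the top-k values, in decreasing order.
#' @export
top_energy_nodes <- function(values, k) {
  k <- min(k, length(values))
  order(values, decreasing = TRUE)[seq_len(k)]
}
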