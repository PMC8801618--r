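#' Describe an X-ray excitation beam
#'
#' @param X0 incident intensity (arbitrary units, >= 0).
#' @param direction unit propagation direction for a parallel beam
#'   (default whole-domain illumination along +x).
#' @param geometry `"parallel"` (default) or `"cone"`.
#' @param origin cone apex (mm); required for cone beams.
#' @param half_angle cone half-angle (degrees); required for cone beams.
#' @param mu_t named per-tissue X-ray attenuation coefficients (mm^-1);
#'   default 0 for every tissue (unattenuated excitation, the phantom-test
#'   default).
#' @return an object of class `xray_beam`.
#' @export
xray_beam <- function(X0 = 1, direction = c(1, 0, 0),
                      geometry = c("parallel", "cone"),
                      origin = NULL, half_angle = NULL, mu_t = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(X0 >= 0)
  if (geometry == "cone" && (is.null(origin) || is.null(half_angle)))
    stop("cone beam needs origin and half_angle")
  direction <- direction / sqrt(sum(direction^2))
  structure(list(X0 = X0, direction = direction, geometry = geometry,
                 origin = origin, half_angle = half_angle, mu_t = mu_t),
            class = "xray_beam")
}

# per-tet attenuation coefficient lookup
beam_mu_t <- function(beam, mesh) {
  if (is.null(beam$mu_t)) return(rep(0, nrow(mesh$tets)))
  if (length(beam$mu_t) == 1L && is.null(names(beam$mu_t)))
    return(rep(beam$mu_t, nrow(mesh$tets)))
  lab <- as.character(mesh$tissue)
  missing <- setdiff(unique(lab), names(beam$mu_t))
  if (length(missing))
    stop("mu_t missing for tissue(s): ", paste(missing, collapse = ", "))
  as.numeric(beam$mu_t[lab])
}

#' X-ray intensity at points inside a mesh
#'
#' Beer-Lambert attenuation `X = X0 exp(-sum_segments mu_t * length)` along
#' the beam ray reaching each query point, with the path length inside each
#' tetrahedron obtained by exact half-space clipping of the ray segment
#' against the tet's four face planes (piecewise-constant `mu_t` per tet).
#' Points outside a cone beam's aperture receive intensity 0 (noted via a
#' message).
#'
#' @param beam an `xray_beam`.
#' @param mesh a `tet_mesh`.
#' @param points m x 3 matrix of query positions (default: all mesh nodes).
#' @return numeric intensity vector of length m.
#' @export
xray_intensity <- function(beam, mesh, points = mesh$nodes) {
  points <- as.matrix(points)
  mu_t <- beam_mu_t(beam, mesh)
  m <- nrow(points)
  out <- numeric(m)
  act <- mu_t != 0
  if (!any(act)) {
    # no attenuating tissue: X0 everywhere the beam reaches
    reach <- beam_reaches(beam, points)
    out[reach] <- beam$X0
    if (any(!reach)) message(sum(!reach), " point(s) not reached by the beam")
    return(out)
  }
  tets <- mesh$tets[act, , drop = FALSE]
  mu <- mu_t[act]
  # inward face planes per tet: normal %*% x <= d
  planes <- tet_planes(mesh$nodes, tets)
  diam <- sqrt(sum((apply(mesh$nodes, 2L, max) - apply(mesh$nodes, 2L, min))^2))
  mesh_centroid <- colMeans(mesh$nodes)
  reach <- beam_reaches(beam, points)
  for (k in seq_len(m)) {
    if (!reach[k]) next
    p <- points[k, ]
    if (beam$geometry == "parallel") {
      dir <- beam$direction
      p0 <- p - dir * (2 * diam)
      smax_pt <- 2 * diam
    } else {
      dvec <- p - beam$origin
      len <- sqrt(sum(dvec^2))
      if (len == 0) { out[k] <- beam$X0; next }
      dir <- dvec / len
      p0 <- beam$origin
      smax_pt <- len
    }
    # nudge the ray laterally into general position so tets whose faces
    # contain the ray do not each claim the on-face segment
    o1 <- if (abs(dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    o1 <- o1 - sum(o1 * dir) * dir
    o1 <- o1 / sqrt(sum(o1^2))
    o2 <- c(dir[2L] * o1[3L] - dir[3L] * o1[2L],
            dir[3L] * o1[1L] - dir[1L] * o1[3L],
            dir[1L] * o1[2L] - dir[2L] * o1[1L])
    s1 <- sign(sum((mesh_centroid - p) * o1)); if (s1 == 0) s1 <- 1
    s2 <- sign(sum((mesh_centroid - p) * o2)); if (s2 == 0) s2 <- 1
    p0 <- p0 + (s1 * 1e-9 * diam) * o1 + (s2 * 1.37e-9 * diam) * o2
    a <- planes$N %*% dir                       # (4t)
    b <- planes$d - planes$N %*% p0
    r <- ifelse(abs(a) > 1e-14, b / a, ifelse(b >= 0, Inf, NaN))
    lo <- ifelse(a < -1e-14, r, ifelse(is.nan(r), Inf, 0))
    hi <- ifelse(a > 1e-14, r, ifelse(is.nan(r), -Inf, smax_pt))
    nt <- nrow(tets)
    smin <- pmax(pmax(lo[seq_len(nt)], lo[nt + seq_len(nt)]),
                 pmax(lo[2L * nt + seq_len(nt)], lo[3L * nt + seq_len(nt)]), 0)
    smax <- pmin(pmin(hi[seq_len(nt)], hi[nt + seq_len(nt)]),
                 pmin(hi[2L * nt + seq_len(nt)], hi[3L * nt + seq_len(nt)]),
                 smax_pt)
    seg <- pmax(0, smax - smin)
    out[k] <- beam$X0 * exp(-sum(mu * seg))
  }
  if (any(!reach)) message(sum(!reach), " point(s) not reached by the beam")
  out
}

# stacked inward half-space representation of all tets: 4t x 3 normals N and
# offsets d with inside <=> N x <= d
tet_planes <- function(nodes, tets) {
  nt <- nrow(tets)
  N <- matrix(0, 4L * nt, 3L); d <- numeric(4L * nt)
  opp <- list(c(2L, 4L, 3L), c(1L, 3L, 4L), c(1L, 4L, 2L), c(1L, 2L, 3L))
  for (f in 1:4) {
    fa <- tets[, opp[[f]], drop = FALSE]
    p1 <- nodes[fa[, 1L], , drop = FALSE]
    p2 <- nodes[fa[, 2L], , drop = FALSE]
    p3 <- nodes[fa[, 3L], , drop = FALSE]
    nrm <- -cross3(p2 - p1, p3 - p1)           # outward for positive tets
    idx <- (f - 1L) * nt + seq_len(nt)
    N[idx, ] <- nrm
    d[idx] <- rowSums(nrm * p1)
  }
  list(N = N, d = d)
}

beam_reaches <- function(beam, points) {
  if (beam$geometry == "parallel") return(rep(TRUE, nrow(points)))
  dvec <- points - matrix(beam$origin, nrow(points), 3L, byrow = TRUE)
  len <- sqrt(rowSums(dvec^2))
  ax <- beam$direction
  cosang <- as.numeric(dvec %*% ax) / pmax(len, 1e-300)
  len == 0 | cosang >= cos(beam$half_angle * pi / 180)
}

#' Nanophosphor luminescence source field
#'
#' `S(r) = epsilon * X(r) * rho(r)`: the emitted optical source power
#' density is the product of the luminescence yield, the local X-ray
#' intensity and the nanophosphor density.
#'
#' @param beam an `xray_beam`.
#' @param rho nodal nanophosphor density (length n, >= 0).
#' @param mesh a `tet_mesh`.
#' @param epsilon luminescence yield (free scale parameter; default 1).
#' @return a list of class `source_field` with `S` (nodal power density),
#'   `X` (nodal X-ray intensity), `epsilon`, `rho`.
#' @export
luminescence_source <- function(beam, rho, mesh, epsilon = 1) {
  if (length(rho) != nrow(mesh$nodes)) stop("rho must be nodal")
  if (any(rho < 0)) stop("rho must be non-negative")
  X <- xray_intensity(beam, mesh)
  structure(list(S = epsilon * X * rho, X = X, epsilon = epsilon, rho = rho),
            class = "source_field")
}
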