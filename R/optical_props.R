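#' Optical properties of a tissue
#'
#' @param mu_a absorption coefficient (mm^-1), >= 0.
#' @param mu_s scattering coefficient (mm^-1), > 0 (a pure absorber is
#'   allowed with `mu_s = 0` for oracle tests).
#' @param g scattering anisotropy, in [0, 1).
#' @param refractive_index tissue refractive index, >= 1 (default 1.37, the
#'   standard soft-tissue value).
#' @return an object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s, g, refractive_index = 1.37) {
  stopifnot(mu_a >= 0, mu_s >= 0, g >= 0, g < 1, refractive_index >= 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g,
                 refractive_index = refractive_index),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical_properties: mu_a=%.4g mm^-1, mu_s=%.4g mm^-1, g=%.3g, n=%.3g\n",
              x$mu_a, x$mu_s, x$g, x$refractive_index))
  cat(sprintf("  reduced scattering mu_s'=%.4g mm^-1, D=%.4g mm\n",
              x$mu_s * (1 - x$g), diffusion_coefficient(x)))
  invisible(x)
}

#' Diffusion coefficient D = 1 / (3 (mu_a + (1 - g) mu_s))
#'
#' @param props an `optical_properties` object (or list with the same
#'   fields).
#' @return D in mm.
#' @export
diffusion_coefficient <- function(props) {
  denom <- props$mu_a + (1 - props$g) * props$mu_s
  if (denom <= 0) stop("mu_a + (1 - g) mu_s must be positive")
  1 / (3 * denom)
}

#' SP3 moment absorption coefficients
#'
#' `mu_ai = mu_a + mu_s (1 - g^i)` for i = 1, 2, 3: the canonical moment
#' coefficients of the simplified spherical harmonics hierarchy. For
#' `0 < g < 1` they are ordered `mu_a1 <= mu_a2 <= mu_a3`, all >= `mu_a`.
#'
#' @inheritParams diffusion_coefficient
#' @return named numeric vector `c(mu_a1, mu_a2, mu_a3)` (mm^-1).
#' @export
sp3_moment_coefficients <- function(props) {
  i <- 1:3
  out <- props$mu_a + props$mu_s * (1 - props$g^i)
  names(out) <- c("mu_a1", "mu_a2", "mu_a3")
  out
}

# Unpolarised Fresnel reflectance for a ray inside a medium of index n_in
# hitting a boundary with outside index n_out, at incidence cosine mu.
fresnel_reflectance <- function(mu, n_in, n_out = 1) {
  mu <- pmin(pmax(mu, 0), 1)
  r <- numeric(length(mu))
  if (n_in == n_out) return(r)
  sin_i <- sqrt(pmax(0, 1 - mu^2))
  sin_t <- n_in / n_out * sin_i
  tir <- sin_t >= 1
  r[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    mu_t <- sqrt(pmax(0, 1 - sin_t[ok]^2))
    mi <- mu[ok]
    rs <- ((n_in * mi - n_out * mu_t) / (n_in * mi + n_out * mu_t))^2
    rp <- ((n_in * mu_t - n_out * mi) / (n_in * mu_t + n_out * mi))^2
    r[ok] <- 0.5 * (rs + rp)
  }
  r
}

# Legendre polynomials P0..P3 evaluated at mu.
legendre_p <- function(l, mu) {
  switch(as.character(l),
         "0" = rep(1, length(mu)),
         "1" = mu,
         "2" = (3 * mu^2 - 1) / 2,
         "3" = (5 * mu^3 - 3 * mu) / 2,
         stop("l out of range"))
}

#' Boundary coefficients for DE and SP3 partial-current conditions
#'
#' Computes the refractive-mismatch factor `A_n` of the diffusion Robin
#' condition and the 2 x 2 table `xi` of SP3 boundary-mass coefficients.
#'
#' Both are derived from partial-current (Marshak) conditions with specular
#' Fresnel reflection at the boundary, with the angular reflection moments
#' evaluated by fixed-order Gauss-Legendre quadrature. For the DE factor,
#' `A_n = (1 + R_j) / (1 - R_phi)` with `R_phi = int 2 mu R_F(mu) dmu` and
#' `R_j = int 3 mu^2 R_F(mu) dmu`. For SP3, the first- and third-order
#' Marshak conditions are solved for the normal derivatives of the composite
#' moments; `xi[s, t]` multiplies the boundary mass matrix in block (s, t) of
#' the SP3 system. At a matched boundary (`refractive_index = 1`) the table
#' reduces to its vacuum closed form
#' `rbind(c(1/2, -1/8), c(-1/8, 7/24))`.
#'
#' @param refractive_index tissue refractive index (>= 1); the outside is
#'   assumed to be air/vacuum (index 1).
#' @param n_quad quadrature order (default 64).
#' @return list with `A_n` (scalar) and `xi` (2 x 2 matrix).
#' @export
boundary_coefficients <- function(refractive_index = 1.37, n_quad = 64L) {
  stopifnot(refractive_index >= 1)
  # composite Gauss-Legendre rule split at the total-internal-reflection
  # kink mu_c (the Fresnel reflectance is non-smooth there)
  gl <- gauss_legendre_01(n_quad)
  mu_c <- sqrt(max(0, 1 - 1 / refractive_index^2))
  if (mu_c > 0) {
    mu <- c(gl$x * mu_c, mu_c + gl$x * (1 - mu_c))
    w <- c(gl$w * mu_c, gl$w * (1 - mu_c))
  } else {
    mu <- gl$x; w <- gl$w
  }
  rf <- fresnel_reflectance(mu, refractive_index, 1)
  r_phi <- sum(w * 2 * mu * rf)
  r_j <- sum(w * 3 * mu^2 * rf)
  a_n <- (1 + r_j) / (1 - r_phi)

  # Marshak conditions for the SP3 composite moments. Planar angular flux
  # ansatz psi(mu) = sum_l (2l+1)/2 m_l P_l(mu); for k in {1, 3}:
  #   int_{-1}^{0} psi P_k dmu = int_0^1 R_F(mu) psi(mu) P_k(-mu) dmu.
  alpha <- matrix(0, 2, 4)
  for (ki in 1:2) {
    k <- c(1L, 3L)[ki]
    for (l in 0:3) {
      cl <- (2 * l + 1) / 2
      # int_{-1}^0 P_l P_k = (-1)^(l+k) int_0^1 P_l P_k
      half <- sum(w * legendre_p(l, mu) * legendre_p(k, mu))
      lhs <- (-1)^(l + k) * half
      rhs <- sum(w * rf * legendre_p(l, mu) * legendre_p(k, -mu))
      alpha[ki, l + 1L] <- cl * (lhs - rhs)
    }
  }
  # substitute m0 = phi1 - (2/3) phi2, m2 = phi2 / 3 and solve the 2 x 2
  # system for the flux moments m1, m3 in terms of (phi1, phi2)
  amat <- alpha[, c(2L, 4L)]                       # coefficients of m1, m3
  bmat <- cbind(alpha[, 1L],                       # coefficient of phi1
                -(2 / 3) * alpha[, 1L] + alpha[, 3L] / 3)  # of phi2
  gam <- -solve(amat, bmat)                        # m = gam %*% c(phi1, phi2)
  # weak-form boundary terms: -int (1/(3 mu_a1)) dphi1/dn v = + int m1 v, so
  # xi[s, t] multiplies the boundary mass matrix in block (s, t)
  xi <- gam
  dimnames(xi) <- list(c("eq1", "eq2"), c("phi1", "phi2"))
  list(A_n = a_n, xi = xi)
}

# Gauss-Legendre rule on [0, 1].
gauss_legendre_01 <- function(n) {
  # Golub-Welsch via symmetric tridiagonal eigenproblem on [-1, 1]
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * (e$vectors[1L, ])^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

#' Decide DE vs SP3 region per tissue
#'
#' With an explicit `override` map the override is returned verbatim.
#' Otherwise a tissue is assigned to the diffusive (DE) region when its
#' reduced scattering dominates absorption, `mu_s (1 - g) >= ratio * mu_a`
#' (default ratio 10, reproducing the organ split adipose/stomach/kidneys vs
#' heart/liver/lungs for the shipped murine table at 610 nm), and to the SP3
#' region otherwise.
#'
#' @param tissue_table named list of `optical_properties`, one per tissue.
#' @param override optional named vector mapping tissue to region (1 or 2),
#'   returned as-is.
#' @param ratio diffusive-dominance threshold (default 10).
#' @return named integer vector mapping tissue name to region.
#' @export
region_rule <- function(tissue_table, override = NULL, ratio = 10) {
  if (!is.null(override)) return(override)
  if (!length(tissue_table)) stop("tissue table is empty")
  out <- vapply(tissue_table, function(p) {
    if (p$mu_s * (1 - p$g) >= ratio * p$mu_a) 1L else 2L
  }, integer(1))
  out
}

#' Load a per-tissue, per-wavelength optical parameter table
#'
#' The YAML layout is `tissue -> wavelength -> {mu_a, mu_s, g, n}`. The
#' murine six-organ table at 610 and 630 nm ships with the package as the
#' named fixture `"digimouse_610_630"`.
#'
#' @param name_or_path fixture name or a YAML file path.
#' @return nested list: `table[[tissue]][[wavelength]]` is an
#'   `optical_properties` object.
#' @export
load_tissue_table <- function(name_or_path = "digimouse_610_630") {
  path <- if (file.exists(name_or_path)) name_or_path else
    system.file("extdata", paste0(name_or_path, ".yaml"), package = "luxtomo")
  if (!nzchar(path) || !file.exists(path))
    stop("tissue table not found: ", name_or_path)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(tiss) {
    lapply(tiss, function(p) {
      optical_properties(p$mu_a, p$mu_s, p$g,
                         refractive_index = if (is.null(p$n)) 1.37 else p$n)
    })
  })
}

#' Slice a tissue table at one wavelength
#'
#' @param table nested table from [load_tissue_table()].
#' @param wavelength wavelength key, e.g. `"610"`.
#' @return named list of `optical_properties`, one per tissue.
#' @export
tissue_table_at <- function(table, wavelength) {
  wavelength <- as.character(wavelength)
  out <- lapply(table, function(tiss) {
    if (is.null(tiss[[wavelength]]))
      stop("wavelength ", wavelength, " missing from tissue table")
    tiss[[wavelength]]
  })
  out
}
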