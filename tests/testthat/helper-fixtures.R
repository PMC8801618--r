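# Shared fixtures and independent numerical oracles, built in code.

# single positively oriented unit right tetrahedron
unit_tet <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

# two tets sharing the face (1, 2, 3)
two_tet_mesh <- function(tissue = c("A", "B")) {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(0.4, 0.4, -1))
  tets <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 5L))
  tet_mesh(nodes, tets, tissue = tissue)
}

small_sphere_phantom <- function(radius = 5, h = 1.6, source_radius = 1.6) {
  build_phantom(phantom_spec(
    "sphere", size = radius, element_size = h, tissue = "med",
    sources = list(list(center = c(0, 0, 0), radius = source_radius,
                        density = 1))))
}

homog_props <- function(mu_a = 0.01, mu_s = 10, g = 0.9, n = 1) {
  optical_properties(mu_a, mu_s, g, refractive_index = n)
}

# Gauss-Legendre nodes/weights on [0, 1] (independent small implementation)
gl01 <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b; J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (e$values[ord] + 1) / 2, w = (2 * e$vectors[1L, ]^2)[ord] / 2)
}

# Numerical quadrature over a tetrahedron via the Duffy (collapsed cube)
# transform; exact for moderate-degree polynomials with n = 6 points/axis.
quad_tet <- function(f, verts, n = 6L) {
  g <- gl01(n)
  total <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    u <- g$x[a]; v <- g$x[b]; w <- g$x[cc]
    # map cube -> reference tet (barycentric l2, l3, l4)
    l2 <- u
    l3 <- v * (1 - u)
    l4 <- w * (1 - u) * (1 - v)
    jac <- (1 - u)^2 * (1 - v)
    lam <- c(1 - l2 - l3 - l4, l2, l3, l4)
    x <- as.numeric(t(verts) %*% lam)
    total <- total + g$w[a] * g$w[b] * g$w[cc] * jac * f(x, lam)
  }
  vol <- abs(det(rbind(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ],
                       verts[4, ] - verts[1, ]))) / 6
  total * 6 * vol          # reference-tet volume is 1/6
}

# quadrature over a triangle (collapsed square)
quad_tri <- function(f, verts, n = 8L) {
  g <- gl01(n)
  total <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    u <- g$x[a]; v <- g$x[b]
    l2 <- u
    l3 <- v * (1 - u)
    jac <- (1 - u)
    lam <- c(1 - l2 - l3, l2, l3)
    x <- as.numeric(t(verts) %*% lam)
    total <- total + g$w[a] * g$w[b] * jac * f(x, lam)
  }
  area <- 0.5 * sqrt(sum(pracma_cross(verts[2, ] - verts[1, ],
                                      verts[3, ] - verts[1, ])^2))
  total * 2 * area         # reference-triangle area is 1/2
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# dense reference assembly of the DE matrix by an independent per-element loop
dense_de_assembly <- function(mesh, props) {
  n <- nrow(mesh$nodes)
  D <- diffusion_coefficient(props)
  M <- matrix(0, n, n)
  for (e in seq_len(nrow(mesh$tets))) {
    v <- mesh$tets[e, ]
    el <- tet_element_matrices(mesh$nodes[v, ])
    M[v, v] <- M[v, v] + D * el$stiffness + props$mu_a * el$mass
  }
  A_n <- boundary_coefficients(props$refractive_index)$A_n
  for (f in seq_len(nrow(mesh$boundary_faces))) {
    v <- mesh$boundary_faces[f, ]
    fe <- face_element_matrix(mesh$nodes[v, ])
    M[v, v] <- M[v, v] + fe$mass / (2 * A_n)
  }
  M
}

random_tet <- function() {
  repeat {
    v <- matrix(stats::runif(12, -1, 1), 4L, 3L)
    vol <- det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) / 6
    if (abs(vol) > 1e-3) {
      if (vol < 0) v <- v[c(1, 2, 4, 3), ]
      return(v)
    }
  }
}
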