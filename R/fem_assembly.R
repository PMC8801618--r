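#' Element matrices of a linear tetrahedron
#'
#' Closed-form P1 integrals: the mass matrix is `V/10` on the diagonal and
#' `V/20` off-diagonal; the stiffness matrix is `V * G %*% t(G)` with `G` the
#' (constant) basis-function gradients. Stiffness rows sum to zero (constant
#' functions lie in the gradient null space).
#'
#' @param verts 4 x 3 matrix of vertex coordinates (mm).
#' @return list with `stiffness` (4 x 4), `mass` (4 x 4) and `volume` (mm^3).
#' @export
tet_element_matrices <- function(verts) {
  verts <- as.matrix(verts)
  J <- rbind(verts[2L, ] - verts[1L, ],
             verts[3L, ] - verts[1L, ],
             verts[4L, ] - verts[1L, ])
  detJ <- det(J)
  vol <- detJ / 6
  if (vol <= 0) stop("zero or negative tet volume")
  Jinv <- solve(J)
  # gradients of the reference barycentric functions mapped to physical space
  gref <- rbind(c(-1, -1, -1), diag(3))
  G <- gref %*% t(Jinv)
  stiffness <- vol * (G %*% t(G))
  mass <- vol / 20 * (matrix(1, 4, 4) + diag(4))
  list(stiffness = stiffness, mass = mass, volume = vol)
}

#' Element mass matrix of a linear boundary triangle
#'
#' Closed form for the P1 surface mass matrix: `area/6` diagonal, `area/12`
#' off-diagonal; row sums are `area/3`.
#'
#' @param verts 3 x 3 matrix of vertex coordinates (mm).
#' @return list with `mass` (3 x 3) and `area` (mm^2).
#' @export
face_element_matrix <- function(verts) {
  verts <- as.matrix(verts)
  cr <- cross3(matrix(verts[2L, ] - verts[1L, ], 1L),
               matrix(verts[3L, ] - verts[1L, ], 1L))
  area <- 0.5 * sqrt(sum(cr^2))
  if (area <= 0) stop("zero-area face")
  mass <- area / 12 * (matrix(1, 3, 3) + diag(3))
  list(mass = mass, area = area)
}

# Vectorised per-tet P1 quantities for assembly: returns volumes and the
# 4 x 3 gradient rows for all tets at once.
tet_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  c23 <- cross3(e2, e3); c31 <- cross3(e3, e1); c12 <- cross3(e1, e2)
  detJ <- rowSums(e1 * c23)
  vol <- detJ / 6
  # grad lambda_i, each t x 3; lambda_1 = -(g2+g3+g4)
  g2 <- c23 / detJ; g3 <- c31 / detJ; g4 <- c12 / detJ
  g1 <- -(g2 + g3 + g4)
  list(vol = vol, g = list(g1, g2, g3, g4))
}

# Boundary-face mass contributions weighted per-face: sum_faces w_f * mass_f.
assemble_boundary_matrix <- function(mesh, face_weight, n = nrow(mesh$nodes)) {
  bf <- mesh$boundary_faces
  nf <- nrow(bf)
  if (nf == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0), dims = c(n, n)))
  p1 <- mesh$nodes[bf[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[bf[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[bf[, 3L], , drop = FALSE]
  area <- 0.5 * sqrt(rowSums(cross3(p2 - p1, p3 - p1)^2))
  if (length(face_weight) == 1L) face_weight <- rep(face_weight, nf)
  ii <- jj <- integer(9L * nf); xx <- numeric(9L * nf)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    val <- face_weight * area * (if (a == b) 1 / 6 else 1 / 12)
    idx <- k + seq_len(nf)
    ii[idx] <- bf[, a]; jj[idx] <- bf[, b]; xx[idx] <- val
    k <- k + nf
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# Per-tet optical coefficient lookup: props_per_tet is either a single
# optical_properties (homogeneous) or a named list indexed by tissue label.
props_by_tet <- function(mesh, props) {
  if (inherits(props, "optical_properties")) {
    lab <- rep("all", nrow(mesh$tets))
    return(list(lab = lab, table = list(all = props)))
  }
  lab <- as.character(mesh$tissue)
  missing <- setdiff(unique(lab), names(props))
  if (length(missing))
    stop("missing optical properties for tissue(s): ",
         paste(missing, collapse = ", "))
  list(lab = lab, table = props)
}

tet_coef <- function(pb, f) {
  vals <- vapply(pb$table, f, numeric(1))
  vals[pb$lab]
}

#' Assemble the diffusion-equation finite-element system
#'
#' Builds the sparse system matrix
#' `M = sum_tets (D * stiffness + mu_a * mass) + sum_bfaces mass / (2 A_n)`
#' and the source-weight matrix `F` (global mass matrix), with one fluence
#' row per node.
#'
#' @param mesh a `tet_mesh` (boundary faces as stored in the mesh: for a
#'   regrouped sub-mesh these are only its share of the original outer
#'   boundary).
#' @param props an `optical_properties` object (homogeneous medium) or a
#'   named list of them indexed by the mesh's tissue labels.
#' @param lump row-sum-lump the volume mass terms (default `FALSE`). Lumping
#'   restores the discrete maximum principle when the optical attenuation
#'   length falls below the element size, at the cost of the consistent-mass
#'   convergence constant; the reconstruction pipeline enables it.
#' @return an object of class `assembled_system` with sparse `M`, `F`,
#'   `model = "de"`, `n_nodes`, `dimension` and a `layout` description.
#' @export
assemble_de <- function(mesh, props, lump = FALSE) {
  n <- nrow(mesh$nodes)
  pb <- props_by_tet(mesh, props)
  D <- tet_coef(pb, diffusion_coefficient)
  mua <- tet_coef(pb, function(p) p$mu_a)
  an <- vapply(pb$table,
               function(p) boundary_coefficients(p$refractive_index)$A_n,
               numeric(1))
  # boundary A_n from the owning tet's tissue
  bf_own <- boundary_face_owner_tissue(mesh)
  M <- assemble_volume_matrix_var(mesh, D, mua, lump = lump) +
    assemble_boundary_matrix(mesh, 1 / (2 * an[bf_own]))
  F_ <- assemble_volume_matrix_var(mesh, 0, rep(1, nrow(mesh$tets)),
                                   lump = lump)
  structure(list(M = M, F = F_, model = "de", n_nodes = n, dimension = n,
                 layout = "rows 1..n: fluence Phi per node"),
            class = "assembled_system")
}

# tissue label of the tet owning each boundary face
boundary_face_owner_tissue <- function(mesh) {
  bf <- mesh$boundary_faces
  if (nrow(bf) == 0L) return(character(0))
  af <- all_tet_faces(mesh$tets)
  own <- af$owner[match(face_keys(bf), af$key)]
  as.character(mesh$tissue)[own]
}

# variable per-tet coefficients variant; `lump = TRUE` row-sum-lumps the
# mass contribution (V/4 per vertex), restoring the discrete maximum
# principle when the optical attenuation length is below the element size
assemble_volume_matrix_var <- function(mesh, coef_stiff, coef_mass,
                                       n = nrow(mesh$nodes), lump = FALSE) {
  if (length(coef_stiff) == 1L) coef_stiff <- rep(coef_stiff, nrow(mesh$tets))
  if (length(coef_mass) == 1L) coef_mass <- rep(coef_mass, nrow(mesh$tets))
  tets <- mesh$tets
  tg <- tet_gradients(mesh$nodes, tets)
  vol <- tg$vol
  nt <- nrow(tets)
  ii <- jj <- integer(16L * nt); xx <- numeric(16L * nt)
  k <- 0L
  for (a in 1:4) {
    ga <- tg$g[[a]]
    for (b in 1:4) {
      gb <- tg$g[[b]]
      mcoef <- if (lump) (if (a == b) 1 / 4 else 0) else
        (if (a == b) 1 / 10 else 1 / 20)
      val <- coef_stiff * vol * rowSums(ga * gb) + coef_mass * vol * mcoef
      idx <- k + seq_len(nt)
      ii[idx] <- tets[, a]; jj[idx] <- tets[, b]; xx[idx] <- val
      k <- k + nt
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Assemble the SP3 finite-element block system
#'
#' Builds the 2n x 2n block system of the composite SP3 moments
#' `(phi1, phi2)`:
#' \describe{
#'   \item{block (1,1)}{`1/(3 mu_a1) * stiffness + mu_a * mass` plus
#'     `xi[1,1] * boundary mass`}
#'   \item{block (1,2)}{`-(2/3) mu_a * mass` plus `xi[1,2] * boundary mass`}
#'   \item{block (2,1)}{`-(2/3) mu_a * mass` plus `xi[2,1] * boundary mass`}
#'   \item{block (2,2)}{`1/(7 mu_a3) * stiffness +
#'     ((4/9) mu_a + (5/9) mu_a2) * mass` plus `xi[2,2] * boundary mass`}
#' }
#' The source-weight matrix `F` is block-diagonal with two copies of the
#' global mass matrix; the right-hand side for a source `S` is
#' `F %*% c(S, -(2/3) S)`. Unknown ordering is `[all phi1 rows, then all
#' phi2 rows]`.
#'
#' @inheritParams assemble_de
#' @param xi_scale optional 2 x 2 multiplicative adjustment of the boundary
#'   coefficient table (sensitivity checks of the boundary-term reading);
#'   default all ones.
#' @return an `assembled_system` with `model = "sp3"` and `dimension = 2n`.
#' @export
assemble_sp3 <- function(mesh, props, xi_scale = matrix(1, 2, 2),
                         lump = FALSE) {
  n <- nrow(mesh$nodes)
  pb <- props_by_tet(mesh, props)
  mom <- vapply(pb$table, sp3_moment_coefficients, numeric(3))
  mua <- tet_coef(pb, function(p) p$mu_a)
  mua1 <- mom["mu_a1", pb$lab]; mua2 <- mom["mu_a2", pb$lab]
  mua3 <- mom["mu_a3", pb$lab]
  xis <- lapply(pb$table,
                function(p) boundary_coefficients(p$refractive_index)$xi)
  bf_own <- boundary_face_owner_tissue(mesh)
  xi_face <- function(s, t_) {
    vapply(bf_own, function(l) xis[[l]][s, t_], numeric(1)) * xi_scale[s, t_]
  }
  M11 <- assemble_volume_matrix_var(mesh, 1 / (3 * mua1), mua, lump = lump) +
    assemble_boundary_matrix(mesh, xi_face(1L, 1L))
  M12 <- assemble_volume_matrix_var(mesh, 0, -(2 / 3) * mua, lump = lump) +
    assemble_boundary_matrix(mesh, xi_face(1L, 2L))
  M21 <- assemble_volume_matrix_var(mesh, 0, -(2 / 3) * mua, lump = lump) +
    assemble_boundary_matrix(mesh, xi_face(2L, 1L))
  M22 <- assemble_volume_matrix_var(mesh, 1 / (7 * mua3),
                                    (4 / 9) * mua + (5 / 9) * mua2,
                                    lump = lump) +
    assemble_boundary_matrix(mesh, xi_face(2L, 2L))
  M <- rbind(cbind(M11, M12), cbind(M21, M22))
  Fm <- assemble_volume_matrix_var(mesh, 0, rep(1, nrow(mesh$tets)),
                                   lump = lump)
  Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  F_ <- rbind(cbind(Fm, Z), cbind(Z, Fm))
  structure(list(M = M, F = F_, model = "sp3", n_nodes = n, dimension = 2L * n,
                 layout = "rows 1..n: phi1; rows n+1..2n: phi2"),
            class = "assembled_system")
}

#' @export
print.assembled_system <- function(x, ...) {
  cat("assembled_system (", x$model, "): dimension ", x$dimension,
      ", nnz(M) = ", length(x$M@x), "\n", sep = "")
  cat("  layout:", x$layout, "\n")
  invisible(x)
}

#' Dump a system's matrices in Matrix Market format
#'
#' @param system an `assembled_system` or `hybrid_system`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the written paths, invisibly.
#' @export
dump_system_mtx <- function(system, dir, prefix = system$model %||% "hybrid") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- file.path(dir, paste0(prefix, "_M.mtx"))
  pf <- file.path(dir, paste0(prefix, "_F.mtx"))
  Matrix::writeMM(methods::as(system$M, "generalMatrix"), pm)
  Matrix::writeMM(methods::as(system$F, "generalMatrix"), pf)
  invisible(c(pm, pf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
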