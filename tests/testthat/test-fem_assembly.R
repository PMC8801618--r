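test_that("unit right tet element matrices match the closed-form integrals", {
  el <- tet_element_matrices(unit_tet())
  expect_equal(el$volume, 1 / 6)
  expect_equal(diag(el$mass), rep(el$volume / 10, 4))
  expect_equal(el$mass[1, 2], el$volume / 20)
  expect_true(isSymmetric(el$stiffness))
  # partition of unity: stiffness rows sum to zero
  expect_lt(max(abs(rowSums(el$stiffness))), 1e-14)
  expect_error(tet_element_matrices(rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(0, 1, 0), c(1, 1, 0))),
               "volume")
})

test_that("random tet element matrices match the quadrature oracle", {
  set.seed(42)
  for (k in 1:8) {
    v <- random_tet()
    el <- tet_element_matrices(v)
    for (a in 1:4) for (b in a:4) {
      mass_q <- quad_tet(function(x, lam) lam[a] * lam[b], v)
      expect_equal(el$mass[a, b], mass_q, tolerance = 1e-12)
    }
    # stiffness via quadrature of the constant gradient product
    vol_q <- quad_tet(function(x, lam) 1, v)
    expect_equal(el$volume, vol_q, tolerance = 1e-12)
  }
})

test_that("triangle face matrices match closed form and quadrature", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  fe <- face_element_matrix(tri)
  expect_equal(fe$area, 1 / 2)
  expect_equal(diag(fe$mass), rep(1 / 12, 3))
  expect_equal(fe$mass[1, 3], 1 / 24)
  expect_equal(rowSums(fe$mass), rep(fe$area / 3, 3))
  set.seed(7)
  for (k in 1:5) {
    v <- matrix(stats::runif(9, -1, 1), 3L, 3L)
    fe <- face_element_matrix(v)
    for (a in 1:3) for (b in a:3) {
      expect_equal(fe$mass[a, b],
                   quad_tri(function(x, lam) lam[a] * lam[b], v),
                   tolerance = 1e-12)
    }
  }
  expect_error(face_element_matrix(rbind(c(0, 0, 0), c(1, 0, 0),
                                         c(2, 0, 0))), "zero-area")
})

test_that("the DE operator annihilates constants without absorption or boundary", {
  ph <- small_sphere_phantom(radius = 4, h = 1.6)
  m <- ph$mesh
  m$boundary_faces <- matrix(integer(0), 0L, 3L)   # pure Neumann problem
  sys <- assemble_de(m, list(med = homog_props(mu_a = 0)))
  ones <- rep(1, nrow(m$nodes))
  expect_lt(max(abs(as.numeric(sys$M %*% ones))), 1e-12)
})

test_that("a mass-only DE system reduces to the element mass matrix", {
  m <- tet_mesh(unit_tet(), matrix(1:4, 1L), tissue = "t")
  m$boundary_faces <- matrix(integer(0), 0L, 3L)
  # D = 0 requires bypassing the physical constructor: scattering dominated
  p <- optical_properties(1, 1e12, 0, refractive_index = 1)
  sys <- assemble_de(m, list(t = p))
  el <- tet_element_matrices(unit_tet())
  expect_equal(as.matrix(sys$M), el$mass, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("sparse DE assembly equals an independent dense per-element loop", {
  m <- two_tet_mesh(tissue = c("m", "m"))
  p <- homog_props(mu_a = 0.05, mu_s = 8, g = 0.85, n = 1.37)
  sys <- assemble_de(m, list(m = p))
  expect_equal(as.matrix(sys$M), dense_de_assembly(m, p),
               tolerance = 1e-12, ignore_attr = TRUE)
  # F is the symmetric global mass matrix with nonnegative entries
  expect_true(Matrix::isSymmetric(sys$F))
  expect_true(all(sys$F@x >= 0))
  # mass row sums give nodal volume shares; total is the mesh volume
  expect_equal(sum(Matrix::rowSums(sys$F)), mesh_volume(m))
})

test_that("the DE system matrix is symmetric positive definite", {
  ph <- small_sphere_phantom(radius = 4, h = 1.3)
  sys <- assemble_de(ph$mesh, list(med = homog_props(n = 1.37)))
  Ms <- as.matrix(sys$M)
  expect_lt(max(abs(Ms - t(Ms))), 1e-14)
  expect_gt(min(eigen(Ms, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("SP3 blocks reduce to pure absorption forms in the transport limit", {
  p_near1 <- optical_properties(0.4, 5, 1 - 1e-12)
  mom <- sp3_moment_coefficients(p_near1)
  expect_equal(unname(mom), rep(0.4, 3), tolerance = 1e-9)
})

test_that("single-tet SP3 blocks equal their closed-form element combinations", {
  m <- tet_mesh(unit_tet(), matrix(1:4, 1L), tissue = "t")
  p <- optical_properties(0.2, 4, 0.8, refractive_index = 1)
  sys <- assemble_sp3(m, list(t = p))
  el <- tet_element_matrices(unit_tet())
  mom <- sp3_moment_coefficients(p)
  xi <- boundary_coefficients(1)$xi
  bmass <- matrix(0, 4, 4)
  for (f in seq_len(nrow(m$boundary_faces))) {
    v <- m$boundary_faces[f, ]
    bmass[v, v] <- bmass[v, v] + face_element_matrix(m$nodes[v, ])$mass
  }
  M11 <- el$stiffness / (3 * mom[1]) + p$mu_a * el$mass + xi[1, 1] * bmass
  M12 <- -(2 / 3) * p$mu_a * el$mass + xi[1, 2] * bmass
  M21 <- -(2 / 3) * p$mu_a * el$mass + xi[2, 1] * bmass
  M22 <- el$stiffness / (7 * mom[3]) +
    ((4 / 9) * p$mu_a + (5 / 9) * mom[2]) * el$mass + xi[2, 2] * bmass
  expect_equal(as.matrix(sys$M),
               rbind(cbind(M11, M12), cbind(M21, M22)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # F block-diagonal with two mass copies
  expect_equal(as.matrix(sys$F[1:4, 1:4]), el$mass, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys$F[5:8, 5:8]), el$mass, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(max(abs(sys$F[1:4, 5:8])), 0)
})

test_that("lumped mass assembly preserves row sums and total volume", {
  ph <- small_sphere_phantom(radius = 4, h = 1.6)
  p <- homog_props()
  cons <- assemble_de(ph$mesh, list(med = p))
  lump <- assemble_de(ph$mesh, list(med = p), lump = TRUE)
  expect_equal(Matrix::rowSums(cons$F), Matrix::rowSums(lump$F),
               tolerance = 1e-12)
  expect_equal(sum(lump$F@x), mesh_volume(ph$mesh))
  # lumped F is diagonal
  expect_equal(length(Matrix::diag(lump$F)[Matrix::diag(lump$F) > 0]),
               Matrix::nnzero(lump$F))
})

test_that("system matrices can be dumped in Matrix Market format", {
  m <- two_tet_mesh(tissue = c("m", "m"))
  sys <- assemble_de(m, list(m = homog_props()))
  dir <- withr::local_tempdir()
  paths <- dump_system_mtx(sys, dir)
  expect_true(all(file.exists(file.path(dir, c("de_M.mtx", "de_F.mtx")))))
  M2 <- Matrix::readMM(file.path(dir, "de_M.mtx"))
  expect_equal(as.matrix(M2), as.matrix(sys$M), tolerance = 1e-12,
               ignore_attr = TRUE)
})
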