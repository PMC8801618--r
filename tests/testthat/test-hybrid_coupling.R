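# two-tet phantom with one tet per region, used across coupling tests
coupling_fixture <- function() {
  m <- classify_regions(two_tet_mesh(tissue = c("A", "B")),
                        c(A = 1L, B = 2L))
  rg <- regroup_mesh(m)
  props <- list(A = homog_props(mu_a = 0.05, n = 1),
                B = optical_properties(0.3, 5, 0.9, refractive_index = 1))
  de <- assemble_de(rg$mesh1, props)
  sp3 <- assemble_sp3(rg$mesh2, props)
  list(mesh = m, rg = rg, props = props,
       hybrid = build_hybrid_system(rg, de, sp3), de = de, sp3 = sp3)
}

test_that("the uncoupled hybrid matrix is the exact block diagonal", {
  fx <- coupling_fixture()
  h <- fx$hybrid
  expect_equal(h$dimension, fx$rg$n1 + 2L * fx$rg$n2)
  expect_equal(as.matrix(h$M[1:4, 1:4]), as.matrix(fx$de$M),
               ignore_attr = TRUE)
  expect_equal(as.matrix(h$M[5:12, 5:12]), as.matrix(fx$sp3$M),
               ignore_attr = TRUE)
  expect_equal(max(abs(h$M[1:4, 5:12])), 0)
  expect_equal(max(abs(h$M[5:12, 1:4])), 0)
  # F row sums concatenate the nodal volumes of both sub-meshes
  expect_equal(sum(Matrix::rowSums(h$F)[1:4]), mesh_volume(fx$rg$mesh1))
  expect_equal(sum(Matrix::rowSums(h$F)[5:8]), mesh_volume(fx$rg$mesh2))
})

test_that("a single-region mesh yields the pure system unchanged", {
  m <- two_tet_mesh(tissue = c("B", "B"))
  m$region <- c(2L, 2L)
  rg <- regroup_mesh(m)
  p <- list(B = optical_properties(0.3, 5, 0.9, refractive_index = 1))
  sp3 <- assemble_sp3(rg$mesh2, p)
  h <- couple_interface_nodes(build_hybrid_system(rg, NULL, sp3))
  expect_equal(as.matrix(h$M), as.matrix(sp3$M), ignore_attr = TRUE)
})

test_that("coupling without interface pairs is the identity", {
  fx <- coupling_fixture()
  h0 <- fx$hybrid
  h0$interface_pairs <- matrix(integer(0), 0L, 2L)
  h1 <- couple_interface_nodes(h0)
  expect_equal(as.matrix(h1$M), as.matrix(h0$uncoupled_M),
               ignore_attr = TRUE)
})

test_that("coupled interface rows carry a unit diagonal and the fluence relation", {
  fx <- coupling_fixture()
  h <- couple_interface_nodes(fx$hybrid)
  n1 <- h$n1; n2 <- h$n2
  for (k in seq_len(nrow(h$interface_pairs))) {
    d <- h$interface_pairs[k, 1L]
    s <- h$interface_pairs[k, 2L]
    row <- as.numeric(h$M[n1 + s, ])
    expected <- numeric(h$dimension)
    expected[n1 + s] <- 1            # phi1 unit diagonal
    expected[d] <- -1                # minus the DE fluence
    expected[n1 + n2 + s] <- -2 / 3  # minus (2/3) phi2
    expect_equal(row, expected)
    # the vacated entries were accumulated into the DE row
    orig <- as.numeric(h$uncoupled_M[d, ] + h$uncoupled_M[n1 + s, ])
    expect_equal(as.numeric(h$M[d, ]), orig)
    # F constraint rows carry no source weight
    expect_equal(max(abs(h$F[n1 + s, ])), 0)
  }
})

test_that("solving the coupled system keeps interface fluence continuous", {
  ph <- small_sphere_phantom(radius = 5, h = 1.2)
  m <- ph$mesh
  cen <- (m$nodes[m$tets[, 1L], ] + m$nodes[m$tets[, 2L], ] +
          m$nodes[m$tets[, 3L], ] + m$nodes[m$tets[, 4L], ]) / 4
  m$tissue <- ifelse(rowSums(cen^2) < 2.5^2, "core", "shell")
  props <- list(shell = homog_props(n = 1),
                core = optical_properties(0.3, 5, 0.9, refractive_index = 1))
  h <- assemble_model(m, props, rule = c(shell = 1L, core = 2L))
  sol <- solve_forward(h, merge_source_weights(h, ph$truth))
  x <- sol$x
  ip <- h$interface_pairs
  resid <- abs(x[ip[, 1L]] -
               (x[h$n1 + ip[, 2L]] - (2 / 3) * x[h$n1 + h$n2 + ip[, 2L]]))
  ref <- max(abs(sol$fluence[measurable_nodes(m)]))
  expect_lt(max(resid) / ref, 1e-10)
})

test_that("hybrid right-hand sides follow the SP3 source scaling", {
  fx <- coupling_fixture()
  h <- couple_interface_nodes(fx$hybrid)
  # zero source gives a zero solution
  rhs0 <- merge_source_weights(h, numeric(5))
  expect_equal(rhs0, numeric(h$dimension))
  expect_equal(solve_forward(h, rhs0)$x, numeric(h$dimension))
  # wrong length rejected
  expect_error(merge_source_weights(h, numeric(4)), "length")
  # point source at the region-2-only node: support confined to its
  # mass neighbourhood, phi2 block scaled by -2/3
  s2_only <- setdiff(fx$rg$orig_nodes2,
                     fx$rg$orig_nodes1[fx$rg$interface_pairs[, 1L]])
  S <- numeric(5); S[s2_only] <- 1
  rhs <- merge_source_weights(h, S)
  loc2 <- match(s2_only, fx$rg$orig_nodes2)
  f2 <- as.numeric(fx$sp3$F[loc2, 1:4])  # mass row of the source node
  # interface phi1 weights moved into the DE rows; own phi1 row keeps its
  # weight; phi2 block scaled by -2/3
  ip <- h$interface_pairs
  expect_equal(rhs[ip[, 1L]], f2[ip[, 2L]])
  expect_equal(rhs[4L + loc2], f2[loc2])
  expect_equal(rhs[8L + seq_len(4L)], -2 / 3 * f2)
  # total source weight in the Phi/phi1 blocks is the nodal volume share
  expect_equal(sum(rhs[1:8]), sum(f2))
  # a uniform source integrates to density times volume in the phi1 block
  Su <- rep(2, 5)
  rhsu <- merge_source_weights(couple_interface_nodes(fx$hybrid), Su)
  tot <- sum(rhsu[1:8])                  # Phi and phi1 blocks
  expect_equal(tot, 2 * mesh_volume(fx$mesh))
})

test_that("the hybrid model contains both pure models as exact limits", {
  ph <- small_sphere_phantom(radius = 5, h = 1.4)
  m <- ph$mesh
  props <- list(med = homog_props(n = 1.37))
  # all tets Region 1: hybrid equals standalone DE
  h1 <- assemble_model(m, props, model = "de")
  de <- assemble_de(m, props)
  s_h <- solve_forward(h1, merge_source_weights(h1, ph$truth))
  s_d <- solve_forward(de, as.numeric(de$F %*% ph$truth))
  bn <- measurable_nodes(m)
  expect_lt(max(abs(s_h$fluence[bn] - s_d$fluence[bn])) /
            max(abs(s_d$fluence[bn])), 1e-10)
  # all tets Region 2: hybrid equals standalone SP3
  h2 <- assemble_model(m, props, model = "sp3")
  sp3 <- assemble_sp3(m, props)
  s_h2 <- solve_forward(h2, merge_source_weights(h2, ph$truth))
  rhs_p <- as.numeric(sp3$F %*% c(ph$truth, -2 / 3 * ph$truth))
  s_p <- solve_forward(sp3, rhs_p)
  expect_lt(max(abs(s_h2$fluence[bn] - s_p$fluence[bn])) /
            max(abs(s_p$fluence[bn])), 1e-10)
})
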