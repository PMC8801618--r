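test_that("zero measurements reconstruct to the zero source", {
  A <- diag(3)
  r <- reconstruct(A, numeric(3), tau = 1, tau_relative = FALSE)
  expect_equal(r$S, numeric(3))
  expect_true(r$converged)
})

test_that("an orthonormal operator gives the soft-threshold solution", {
  # min 1/2 ||S - (2, 0)||^2 + ||S||_1 over S >= 0 has minimiser (1, 0)
  r <- reconstruct(diag(2), c(2, 0), tau = 1, tau_relative = FALSE)
  expect_equal(r$S, c(1, 0), tolerance = 1e-10)
  expect_true(r$converged)
})

test_that("the IVTCG objective is non-increasing and the estimate non-negative", {
  set.seed(21)
  A <- matrix(stats::rnorm(40 * 120), 40L)
  s_true <- numeric(120); s_true[c(7, 30)] <- c(2, 1)
  phi <- as.numeric(A %*% s_true) + 0.01 * stats::rnorm(40)
  r <- reconstruct(A, phi, tau = 0.05)
  expect_true(all(diff(r$objective) <= 1e-12))
  expect_true(all(r$S >= 0))
  # recovers the true support
  expect_true(all(c(7, 30) %in% order(r$S, decreasing = TRUE)[1:2]))
})

test_that("regularisation limits behave as expected", {
  set.seed(22)
  A <- matrix(stats::rnorm(30 * 10), 30L)
  s_true <- c(3, rep(0, 9))
  phi <- as.numeric(A %*% s_true)
  # large tau drives the estimate to zero
  big <- reconstruct(A, phi, tau = 10, tau_relative = TRUE)
  expect_equal(big$S, rep(0, 10))
  # small tau approaches the unregularised least-squares fit
  small <- reconstruct(A, phi, tau = 1e-8, tau_relative = TRUE,
                       max_outer = 200L)
  expect_lt(sqrt(sum((as.numeric(A %*% small$S) - phi)^2)) /
            sqrt(sum(phi^2)), 1e-3)
  expect_error(reconstruct(A, phi, tau = -1), "positive")
  expect_error(reconstruct(A, phi[1:5]), "conformable")
})

test_that("tikhonov solves the ridge normal equations with projection", {
  set.seed(23)
  A <- matrix(stats::rnorm(30 * 6), 30L)
  phi <- as.numeric(A %*% c(1, 2, 0, 0, 1, 0))
  r <- reconstruct(A, phi, tau = 1e-6, solver = "tikhonov",
                   tau_relative = FALSE, normalize = FALSE)
  ref <- solve(crossprod(A) + 2e-6 * diag(6), crossprod(A, phi))
  expect_equal(r$S, pmax(as.numeric(ref), 0), tolerance = 1e-8)
})

test_that("average relative error uses the global reference maximum", {
  expect_equal(metric_are(c(1, 2), c(2, 2)), 0.25)
  expect_equal(metric_are(c(5, 5), c(5, 5)), 0)
  # invariant under a common positive scale
  expect_equal(metric_are(3 * c(1, 2), 3 * c(2, 2)), 0.25)
  expect_error(metric_are(c(1, 2), c(0, 0)), "positive")
  expect_error(metric_are(1, c(1, 2)), "lengths")
})

test_that("location error is the Euclidean distance of energy centers", {
  expect_equal(metric_le(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_equal(metric_le(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_warning(le <- metric_le(NULL, c(0, 0, 0)), "empty")
  expect_true(is.na(le))
  # uniform weights on a symmetric node set center on the symmetry point
  nodes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)) + 2
  expect_equal(energy_weighted_center(rep(1, 6), nodes), c(2, 2, 2))
  expect_null(energy_weighted_center(rep(0, 6), nodes))
})

test_that("Dice overlap matches its set definition", {
  expect_equal(metric_dice(1:4, 1:4), 1)
  expect_equal(metric_dice(1:4, 5:8), 0)
  expect_equal(metric_dice(1:4, 3:6), 0.5)
  expect_warning(d <- metric_dice(integer(0), integer(0)), "undefined")
  expect_true(is.na(d))
})

test_that("contrast-to-noise ratio matches hand computation", {
  # roi values {1, 3}, bck {0, 0, 0, 2}: means 2 and 0.5, population
  # variances 1 and 0.75, weights (1/3, 2/3) -> CNR = 1.5 / sqrt(5/6)
  S <- c(1, 3, 0, 0, 0, 2)
  expect_equal(metric_cnr(S, 1:2, 3:6), 1.5 / sqrt(5 / 6))
  # constant field: zero contrast
  expect_equal(metric_cnr(rep(4, 6), 1:2, 3:6), 0)
  # zero variance with contrast: flagged infinite
  expect_warning(cnr <- metric_cnr(c(2, 2, 0, 0), 1:2, 3:4), "infinite")
  expect_equal(cnr, Inf)
  expect_error(metric_cnr(S, 1:2, 2:4), "disjoint")
  expect_error(metric_cnr(S, integer(0), 1:2), "non-empty")
})

test_that("thresholding at 30 percent of max defines the source region", {
  S <- c(10, 4, 2.9, 0, 3)
  reg <- source_roi(S)
  expect_equal(reg$roi, c(1L, 2L, 5L))
  expect_equal(reg$bck, c(3L, 4L))
  expect_equal(source_roi(numeric(3))$roi, integer(0))
})

test_that("noiseless same-mesh reconstruction recovers the source region", {
  # inverse-crime regression floor on a mesh with > 5,000 nodes
  ph <- paper_like_phantom(element_size = 1)
  expect_gt(nrow(ph$mesh$nodes), 5000)
  props <- tissue_table_at(load_tissue_table(), "630")
  sys <- assemble_model(ph$mesh, props, ph$region_rule, "mrhm", lump = TRUE)
  sol <- solve_forward(sys, merge_source_weights(sys, ph$truth))
  bn <- measurable_nodes(ph$mesh)
  phi <- sol$fluence[bn]
  keep <- sort(top_energy_nodes(phi, 300))
  A <- build_sensitivity(sys, bn[keep], 630)
  r <- reconstruct(A, phi[keep], tau = 0.1)
  truth_nodes <- which(ph$truth > 0)
  d <- metric_dice(source_roi(r$S)$roi, truth_nodes)
  expect_gte(d, 0.5)
  le <- metric_le(energy_weighted_center(r$S, ph$mesh$nodes),
                  ph$source_centers[[1L]])
  expect_lt(le, 1.25)
})

test_that("debiasing refit keeps data fit while spreading over neighbours", {
  set.seed(31)
  ph <- small_sphere_phantom(radius = 4, h = 1.3)
  props <- list(med = homog_props(n = 1))
  sys <- assemble_model(ph$mesh, props, model = "de")
  bn <- measurable_nodes(ph$mesh)
  A <- build_sensitivity(sys, bn, 610)
  phi <- as.numeric(A$A %*% ph$truth)
  r <- reconstruct(A, phi, tau = 0.05)
  nb <- mesh_node_neighbors(ph$mesh)
  S2 <- debias_refit(A, phi, r$S, nb)
  expect_true(all(S2 >= 0))
  res1 <- sum((as.numeric(A$A %*% r$S) - phi)^2)
  res2 <- sum((as.numeric(A$A %*% S2) - phi)^2)
  expect_lte(res2, res1 + 1e-12)
})
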