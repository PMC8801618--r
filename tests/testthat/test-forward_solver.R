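# shared small forward fixture: homogeneous sphere with central source
forward_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ph <- small_sphere_phantom(radius = 5, h = 1.6)
    props <- list(med = homog_props(n = 1))
    sys <- assemble_model(ph$mesh, props, model = "de")
    cache <<- list(ph = ph, props = props, sys = sys)
    cache
  }
})

test_that("a zero right-hand side yields the zero solution", {
  fx <- forward_fixture()
  sol <- solve_forward(fx$sys, numeric(fx$sys$dimension))
  expect_equal(sol$x, numeric(fx$sys$dimension))
  expect_equal(sol$residual, 0)
})

test_that("forward solutions satisfy the residual contract", {
  fx <- forward_fixture()
  rhs <- merge_source_weights(fx$sys, fx$ph$truth)
  sol <- solve_forward(fx$sys, rhs)
  expect_lt(sol$residual, 1e-10)
  expect_equal(length(sol$fluence), nrow(fx$ph$mesh$nodes))
})

test_that("surface fluence extraction respects the measurable selection", {
  fx <- forward_fixture()
  m <- fx$ph$mesh
  rhs <- merge_source_weights(fx$sys, fx$ph$truth)
  sol <- solve_forward(fx$sys, rhs)
  bn <- measurable_nodes(m)
  sm <- surface_fluence(sol$fluence, m, wavelength = 610)
  expect_s3_class(sm, "surface_measurement")
  expect_equal(nrow(sm), length(bn))
  expect_equal(sm$node, bn)              # stable sorted order
  # angular field of view keeps only nodes inside the cone
  fov <- list(axis = c(0, 0, 1), half_angle = 60)
  sel <- measurable_nodes(m, fov)
  ctr <- colMeans(m$nodes)
  dirs <- m$nodes[sel, , drop = FALSE] -
    matrix(ctr, length(sel), 3L, byrow = TRUE)
  cosang <- dirs[, 3L] / sqrt(rowSums(dirs^2))
  expect_true(all(cosang >= cos(60 * pi / 180) - 1e-12))
  expect_error(surface_fluence(sol$fluence, m, measurable = integer(0)),
               "empty")
  interior <- setdiff(seq_len(nrow(m$nodes)), bn)[1L]
  expect_error(surface_fluence(sol$fluence, m, measurable = interior),
               "non-boundary")
})

test_that("measurement CSV round trip preserves values", {
  fx <- forward_fixture()
  rhs <- merge_source_weights(fx$sys, fx$ph$truth)
  sm <- surface_fluence(solve_forward(fx$sys, rhs)$fluence, fx$ph$mesh,
                        wavelength = 610)
  p <- withr::local_tempfile(fileext = ".csv")
  write_measurement(sm, p)
  sm2 <- read_measurement(p)
  expect_equal(sm2$fluence, sm$fluence)
  expect_equal(sm2$node, sm$node)
})

test_that("the sensitivity matrix reproduces forward-solved surface fluence", {
  fx <- forward_fixture()
  m <- fx$ph$mesh
  bn <- measurable_nodes(m)
  A <- build_sensitivity(fx$sys, bn, wavelength = 610)
  set.seed(11)
  for (k in 1:10) {
    S <- stats::runif(nrow(m$nodes))
    pred <- as.numeric(A$A %*% S)
    sol <- solve_forward(fx$sys, merge_source_weights(fx$sys, S))
    ref <- sol$fluence[bn]
    expect_lt(max(abs(pred - ref)) / max(abs(ref)), 1e-8)
  }
})

test_that("adjoint sensitivity rows equal explicit column solves", {
  fx <- forward_fixture()
  m <- fx$ph$mesh
  bn <- measurable_nodes(m)[1:5]
  A <- build_sensitivity(fx$sys, bn, wavelength = 610)
  # column route: solve M x = F P e_k for unit sources, extract rows
  for (k in c(1L, as.integer(nrow(m$nodes) / 2L))) {
    S <- numeric(nrow(m$nodes)); S[k] <- 1
    sol <- solve_forward(fx$sys, merge_source_weights(fx$sys, S))
    expect_lt(max(abs(A$A[, k] - sol$fluence[bn])) /
              max(max(abs(sol$fluence[bn])), 1e-300), 1e-10)
  }
  # single-measurable-row case
  A1 <- build_sensitivity(fx$sys, bn[1L], wavelength = 610)
  expect_equal(nrow(A1$A), 1L)
  expect_equal(A1$A[1L, ], A$A[1L, ], tolerance = 1e-12)
})

test_that("finite-difference perturbations match the linear sensitivity", {
  fx <- forward_fixture()
  m <- fx$ph$mesh
  bn <- measurable_nodes(m)
  A <- build_sensitivity(fx$sys, bn, wavelength = 610)
  set.seed(3)
  S0 <- stats::runif(nrow(m$nodes))
  dS <- stats::rnorm(nrow(m$nodes)) * 1e-4
  f0 <- solve_forward(fx$sys, merge_source_weights(fx$sys, S0))$fluence[bn]
  f1 <- solve_forward(fx$sys,
                      merge_source_weights(fx$sys, S0 + dS))$fluence[bn]
  expect_lt(max(abs((f1 - f0) - as.numeric(A$A %*% dS))) /
            max(abs(f1 - f0)), 1e-6)
})

test_that("multispectral stacking preserves shapes and redundancy", {
  fx <- forward_fixture()
  bn <- measurable_nodes(fx$ph$mesh)
  A <- build_sensitivity(fx$sys, bn, wavelength = 610)
  phi <- as.numeric(A$A %*% fx$ph$truth)
  # single block passes through
  st1 <- stack_multispectral(list(A), list(phi))
  expect_equal(st1$A, A$A)
  expect_equal(st1$phi, phi)
  # two blocks stack by rows in the given order
  A2 <- build_sensitivity(fx$sys, bn, wavelength = 630)
  st2 <- stack_multispectral(list(A2, A), list(phi, phi))
  expect_equal(nrow(st2$A), 2L * length(phi))
  expect_equal(st2$blocks$wavelength, c(630, 610))
  expect_equal(st2$blocks$to, c(length(phi), 2L * length(phi)))
  # identical blocks with consistent data: stacked least squares equals
  # the single-wavelength least squares solution
  set.seed(5)
  cols <- sample(ncol(A$A), 8L)
  As <- A$A[, cols]
  y <- as.numeric(As %*% stats::runif(8L))
  single <- qr.solve(As, y)
  stacked <- qr.solve(rbind(As, As), c(y, y))
  expect_equal(stacked, single, tolerance = 1e-8)
  # column mismatch rejected
  A_small <- A; A_small$A <- A$A[, 1:10]
  expect_error(stack_multispectral(list(A, A_small), list(phi, phi)),
               "mismatch")
})

test_that("surface matching finds nearest nodes between meshes", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  tgt <- rbind(c(0.1, 0, 0), c(0.9, 0.1, 0), c(-0.2, 0.9, 0))
  expect_equal(match_surface_nodes(tgt, src), c(1L, 2L, 3L))
})
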