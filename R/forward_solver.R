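#' Solve an assembled or hybrid linear system
#'
#' Direct sparse LU factorisation with a residual contract: the relative
#' residual `||M x - rhs|| / ||rhs||` must be below `tol` or an error is
#' raised. For SP3 and hybrid systems the physical (composite) fluence
#' `Phi = phi1 - (2/3) phi2` is also reported per original-mesh node.
#'
#' @param system an `assembled_system` or `hybrid_system`.
#' @param rhs right-hand side vector (e.g. from [merge_source_weights()]).
#' @param tol residual tolerance (default 1e-10).
#' @return a list with `x` (raw solution vector), `fluence` (composite
#'   fluence per node: original-mesh nodes for a hybrid system, mesh nodes
#'   otherwise) and `residual`.
#' @export
solve_forward <- function(system, rhs, tol = 1e-10) {
  M <- system$M
  if (length(rhs) != nrow(M)) stop("rhs length does not match system dimension")
  if (all(rhs == 0)) {
    x <- numeric(length(rhs))
  } else {
    x <- as.numeric(Matrix::solve(M, rhs))
    res <- sqrt(sum((as.numeric(M %*% x) - rhs)^2)) / sqrt(sum(rhs^2))
    if (!is.finite(res) || res > tol)
      stop(sprintf("linear solve residual %.3e exceeds tolerance %.3e", res, tol))
  }
  fl <- composite_fluence(system, x)
  res <- if (all(rhs == 0)) 0 else
    sqrt(sum((as.numeric(M %*% x) - rhs)^2)) / sqrt(sum(rhs^2))
  list(x = x, fluence = fl, residual = res)
}

#' Composite fluence of a solution vector
#'
#' DE nodes report their fluence directly; SP3 nodes report
#' `phi1 - (2/3) phi2`. For a hybrid system values are mapped back to the
#' original mesh node numbering (interface nodes take the DE value, which
#' the coupling makes equal to the SP3 composite value).
#'
#' @param system the system the vector was solved on.
#' @param x solution vector.
#' @return numeric fluence vector.
#' @export
composite_fluence <- function(system, x) {
  if (inherits(system, "assembled_system")) {
    if (system$model == "de") return(x)
    n <- system$n_nodes
    return(x[seq_len(n)] - (2 / 3) * x[n + seq_len(n)])
  }
  rg <- system$regrouped
  n1 <- system$n1; n2 <- system$n2
  out <- numeric(rg$n_orig)
  if (n2) {
    phi1 <- x[n1 + seq_len(n2)]
    phi2 <- x[n1 + n2 + seq_len(n2)]
    out[rg$orig_nodes2] <- phi1 - (2 / 3) * phi2
  }
  if (n1) out[rg$orig_nodes1] <- x[seq_len(n1)]  # DE value wins at interface
  out
}

#' Select measurable boundary nodes
#'
#' @param mesh the (original) `tet_mesh`.
#' @param fov optional angular field-of-view predicate: a list with `axis`
#'   (3-vector from the mesh centroid), and `half_angle` (degrees); only
#'   boundary nodes whose direction from the centroid lies within the cone
#'   are retained. Default `NULL` keeps all boundary nodes.
#' @return integer vector of measurable node indices (original numbering).
#' @export
measurable_nodes <- function(mesh, fov = NULL) {
  bnodes <- sort(unique(as.vector(mesh$boundary_faces)))
  if (is.null(fov)) return(bnodes)
  ctr <- colMeans(mesh$nodes)
  ax <- fov$axis / sqrt(sum(fov$axis^2))
  dirs <- mesh$nodes[bnodes, , drop = FALSE] -
    matrix(ctr, length(bnodes), 3L, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  keep <- as.numeric(dirs %*% ax) >= cos(fov$half_angle * pi / 180)
  bnodes[keep]
}

#' Extract surface fluence at measurable nodes
#'
#' @param fluence nodal fluence (original-mesh numbering, e.g.
#'   `solve_forward(...)$fluence`).
#' @param mesh the original `tet_mesh`.
#' @param measurable integer vector of measurable node indices; must all be
#'   boundary nodes. Default: all boundary nodes.
#' @param wavelength wavelength tag stored with the measurement (nm).
#' @return a `surface_measurement`: data.frame with columns `node`, `x`,
#'   `y`, `z`, `wavelength`, `fluence`, ordered by node index (the stable
#'   documented order).
#' @export
surface_fluence <- function(fluence, mesh, measurable = NULL, wavelength = NA_real_) {
  bnodes <- sort(unique(as.vector(mesh$boundary_faces)))
  if (is.null(measurable)) measurable <- bnodes
  if (length(measurable) == 0L) stop("empty measurable-node selection")
  if (!all(measurable %in% bnodes))
    stop("measurable selection contains non-boundary nodes")
  measurable <- sort(measurable)
  out <- data.frame(node = measurable,
                    x = mesh$nodes[measurable, 1L],
                    y = mesh$nodes[measurable, 2L],
                    z = mesh$nodes[measurable, 3L],
                    wavelength = wavelength,
                    fluence = fluence[measurable])
  class(out) <- c("surface_measurement", "data.frame")
  attr(out, "provenance") <- "solver"
  out
}

#' Read/write surface measurements as CSV
#' @param x a `surface_measurement`.
#' @param path CSV path.
#' @export
write_measurement <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("surface_measurement", "data.frame")
  attr(out, "provenance") <- "file"
  out
}

# sparse measurement operator L (n_meas x dimension): composite fluence at
# the selected original-mesh boundary nodes.
measurement_operator <- function(hybrid, measurable) {
  rg <- hybrid$regrouped
  n1 <- hybrid$n1; n2 <- hybrid$n2
  i <- integer(0); j <- integer(0); x <- numeric(0)
  loc1 <- match(measurable, rg$orig_nodes1)
  loc2 <- match(measurable, rg$orig_nodes2)
  for (k in seq_along(measurable)) {
    if (!is.na(loc1[k])) {
      i <- c(i, k); j <- c(j, loc1[k]); x <- c(x, 1)
    } else if (!is.na(loc2[k])) {
      i <- c(i, k, k)
      j <- c(j, n1 + loc2[k], n1 + n2 + loc2[k])
      x <- c(x, 1, -2 / 3)
    } else stop("measurable node absent from both sub-meshes")
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(measurable), hybrid$dimension))
}

#' Build the sensitivity matrix of a hybrid system
#'
#' The sensitivity matrix maps a nodal source power density `S` (original
#' mesh numbering) to the measurable surface fluence: `A = L M^-1 F P`,
#' where `L` extracts the composite fluence at the measurable nodes and `P`
#' applies the SP3 `-(2/3)` second-moment source scaling. Rows are computed
#' by adjoint solves (`solve(t(M), t(L))`, one factorisation for all
#' measurable rows), which is mathematically identical to extracting rows of
#' the dense `M^-1 F` but never forms it.
#'
#' @param hybrid a coupled `hybrid_system`.
#' @param measurable integer vector of measurable original-mesh node
#'   indices (sorted internally; row order matches the sorted order, the
#'   same convention as [surface_fluence()]).
#' @param wavelength wavelength tag (nm).
#' @return an object of class `sensitivity_matrix`: list with dense `A`
#'   (n_meas x n_orig), `nodes` (measurable nodes in row order),
#'   `wavelength`.
#' @export
build_sensitivity <- function(hybrid, measurable, wavelength = NA_real_) {
  measurable <- sort(measurable)
  L <- measurement_operator(hybrid, measurable)
  W <- Matrix::solve(Matrix::t(hybrid$M), Matrix::t(L))   # dim x n_meas
  FP <- hybrid$F %*% hybrid_source_prolongation(hybrid)   # dim x n_orig
  A <- as.matrix(Matrix::t(W) %*% FP)
  structure(list(A = A, nodes = measurable, wavelength = wavelength,
                 n_source = ncol(A)),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("sensitivity_matrix:", nrow(x$A), "measurements x", ncol(x$A),
      "source nodes, wavelength", x$wavelength, "nm\n")
  invisible(x)
}

#' Stack sensitivity systems of several wavelengths
#'
#' Vertically stacks per-wavelength sensitivity matrices and measurement
#' vectors (unweighted). Blocks are stacked in the order given; all blocks
#' must share the source-node space.
#'
#' @param sens_list list of `sensitivity_matrix` objects.
#' @param meas_list list of numeric measurement vectors (one per block, in
#'   the block's row order).
#' @return list with stacked `A`, `phi` and per-block row ranges.
#' @export
stack_multispectral <- function(sens_list, meas_list) {
  stopifnot(length(sens_list) == length(meas_list), length(sens_list) >= 1L)
  ncols <- vapply(sens_list, function(s) ncol(s$A), integer(1))
  if (length(unique(ncols)) != 1L)
    stop("sensitivity blocks have mismatched source-node spaces")
  for (k in seq_along(sens_list))
    if (nrow(sens_list[[k]]$A) != length(meas_list[[k]]))
      stop("measurement vector ", k, " does not match its block's rows")
  A <- do.call(rbind, lapply(sens_list, function(s) s$A))
  phi <- unlist(meas_list, use.names = FALSE)
  ends <- cumsum(vapply(sens_list, function(s) nrow(s$A), integer(1)))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  list(A = A, phi = phi,
       blocks = data.frame(
         wavelength = vapply(sens_list, function(s) s$wavelength, numeric(1)),
         from = starts, to = ends))
}

#' Match surface nodes between two meshes
#'
#' Nearest-neighbour matching of boundary nodes, used to carry measurements
#' simulated on a fine mesh onto the measurable nodes of a coarser
#' reconstruction mesh.
#'
#' @param target_nodes m x 3 coordinates needing matches.
#' @param source_nodes k x 3 coordinates carrying values.
#' @return integer vector: for each target node, the index of its nearest
#'   source node.
#' @export
match_surface_nodes <- function(target_nodes, source_nodes) {
  target_nodes <- as.matrix(target_nodes); source_nodes <- as.matrix(source_nodes)
  vapply(seq_len(nrow(target_nodes)), function(i) {
    d2 <- rowSums((source_nodes - matrix(target_nodes[i, ], nrow(source_nodes),
                                         3L, byrow = TRUE))^2)
    which.min(d2)
  }, integer(1))
}
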