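#' Build the uncoupled hybrid block system
#'
#' Places the DE system of sub-mesh 1 and the SP3 system of sub-mesh 2 into
#' one block-diagonal matrix of dimension `n1 + 2 n2` with layout: rows
#' `1..n1` are the DE fluence of the Region-1 nodes; rows `n1+1..n1+n2` the
#' SP3 `phi1` of the Region-2 nodes; rows `n1+n2+1..n1+2n2` their `phi2`.
#' No cross terms are introduced at this stage; [couple_interface_nodes()]
#' performs the interface row surgery.
#'
#' @param regrouped a `regrouped_mesh`.
#' @param de_sys the DE `assembled_system` of `regrouped$mesh1` (or `NULL`
#'   when Region 1 is empty).
#' @param sp3_sys the SP3 `assembled_system` of `regrouped$mesh2` (or `NULL`
#'   when Region 2 is empty).
#' @return an object of class `hybrid_system` with sparse `M`, `F`,
#'   `uncoupled_M`, `uncoupled_F`, counts, `interface_pairs` and `coupled`
#'   flag.
#' @export
build_hybrid_system <- function(regrouped, de_sys, sp3_sys) {
  n1 <- regrouped$n1; n2 <- regrouped$n2
  if (n1 > 0L) {
    if (is.null(de_sys) || de_sys$dimension != n1)
      stop("DE system dimension does not match regrouped n1")
  }
  if (n2 > 0L) {
    if (is.null(sp3_sys) || sp3_sys$dimension != 2L * n2)
      stop("SP3 system dimension does not match regrouped n2")
  }
  blocks_M <- list(); blocks_F <- list()
  if (n1 > 0L) { blocks_M <- c(blocks_M, list(de_sys$M))
                 blocks_F <- c(blocks_F, list(de_sys$F)) }
  if (n2 > 0L) { blocks_M <- c(blocks_M, list(sp3_sys$M))
                 blocks_F <- c(blocks_F, list(sp3_sys$F)) }
  M <- if (length(blocks_M) == 1L) blocks_M[[1L]] else
    Matrix::bdiag(blocks_M)
  F_ <- if (length(blocks_F) == 1L) blocks_F[[1L]] else
    Matrix::bdiag(blocks_F)
  M <- methods::as(M, "CsparseMatrix")
  F_ <- methods::as(F_, "CsparseMatrix")
  structure(list(M = M, F = F_, uncoupled_M = M, uncoupled_F = F_,
                 n1 = n1, n2 = n2, dimension = n1 + 2L * n2,
                 interface_pairs = regrouped$interface_pairs,
                 regrouped = regrouped, coupled = FALSE,
                 layout = "rows 1..n1: Phi (DE); n1+1..n1+n2: phi1; n1+n2+1..n1+2n2: phi2"),
            class = "hybrid_system")
}

#' Couple duplicated interface nodes of a hybrid system
#'
#' For every interface pair (DE node `d`, SP3 node `s`):
#' \enumerate{
#'   \item the `phi1` row of `s` is accumulated into the DE row of `d`
#'     (entries "moved" so the flux balance at the shared point is counted
#'     once across both regions);
#'   \item the vacated `phi1` row is zeroed and replaced by a unit-diagonal
#'     constraint row encoding the composite-fluence continuity
#'     `phi1_s - Phi_d - (2/3) phi2_s = 0`, i.e. the physical surface
#'     fluence `Phi = phi1 - (2/3) phi2` is continuous across the interface;
#'   \item the rows of the source-weight matrix `F` follow the same
#'     replacement (constraint rows carry no source).
#' }
#' Implemented as a sparse row-surgery pass over the triplet form; the
#' uncoupled matrix is retained in `uncoupled_M` so the procedure is
#' testable row by row.
#'
#' @param hybrid an uncoupled `hybrid_system`.
#' @return the coupled `hybrid_system`.
#' @export
couple_interface_nodes <- function(hybrid) {
  pairs <- hybrid$interface_pairs
  if (is.null(pairs) || nrow(pairs) == 0L) {
    hybrid$coupled <- TRUE
    return(hybrid)
  }
  n1 <- hybrid$n1; n2 <- hybrid$n2; dim <- hybrid$dimension
  if (any(pairs[, 1L] > n1) || any(pairs[, 2L] > n2))
    stop("interface pair index out of range")
  d_rows <- pairs[, 1L]                 # DE rows
  p1_rows <- n1 + pairs[, 2L]           # phi1 rows to vacate
  p2_cols <- n1 + n2 + pairs[, 2L]      # phi2 columns in the constraint
  rowmap <- seq_len(dim)
  rowmap[p1_rows] <- d_rows
  surgery <- function(A, add_constraint) {
    T_ <- methods::as(A, "TsparseMatrix")
    i <- rowmap[T_@i + 1L]; j <- T_@j + 1L; x <- T_@x
    if (add_constraint) {
      i <- c(i, p1_rows, p1_rows, p1_rows)
      j <- c(j, p1_rows, d_rows, p2_cols)
      x <- c(x, rep(1, length(p1_rows)), rep(-1, length(d_rows)),
             rep(-2 / 3, length(p2_cols)))
    }
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(dim, ncol(A)))
  }
  hybrid$M <- surgery(hybrid$M, add_constraint = TRUE)
  hybrid$F <- surgery(hybrid$F, add_constraint = FALSE)
  hybrid$coupled <- TRUE
  hybrid
}

#' @export
print.hybrid_system <- function(x, ...) {
  cat("hybrid_system: dimension", x$dimension, "(n1 =", x$n1, ", n2 =",
      x$n2, "),", nrow(x$interface_pairs), "interface pairs,",
      if (x$coupled) "coupled" else "uncoupled", "\n")
  invisible(x)
}

#' Map a nodal source field through the hybrid source weights
#'
#' Maps a source power density `S` given on the *original* mesh nodes to the
#' hybrid right-hand side `F %*% c(S1, S2, -(2/3) S2)`, where `S1`/`S2` are
#' the restrictions of `S` to the two sub-meshes and the `-(2/3)` factor is
#' the SP3 second-moment source scaling. Coupled constraint rows end up with
#' zero right-hand side because their `F` rows were zeroed by the coupling.
#'
#' @param hybrid a `hybrid_system` (coupled or not).
#' @param S numeric vector of nodal source power density on the original
#'   mesh nodes.
#' @return numeric right-hand-side vector of length `dimension`.
#' @export
merge_source_weights <- function(hybrid, S) {
  rg <- hybrid$regrouped
  if (length(S) != rg$n_orig)
    stop("source vector length does not match the original mesh")
  as.numeric(hybrid$F %*% hybrid_source_vector(hybrid, S))
}

# c(S1, S2, -(2/3) S2) layout of a nodal source on the hybrid unknowns
hybrid_source_vector <- function(hybrid, S) {
  rg <- hybrid$regrouped
  s1 <- if (rg$n1) S[rg$orig_nodes1] else numeric(0)
  s2 <- if (rg$n2) S[rg$orig_nodes2] else numeric(0)
  c(s1, s2, -(2 / 3) * s2)
}

# sparse prolongation P: original-mesh nodal source -> hybrid source layout,
# so that rhs = F %*% P %*% S. Used by the sensitivity construction.
hybrid_source_prolongation <- function(hybrid) {
  rg <- hybrid$regrouped
  i <- integer(0); j <- integer(0); x <- numeric(0)
  if (rg$n1) {
    i <- c(i, seq_len(rg$n1)); j <- c(j, rg$orig_nodes1)
    x <- c(x, rep(1, rg$n1))
  }
  if (rg$n2) {
    i <- c(i, rg$n1 + seq_len(rg$n2), rg$n1 + rg$n2 + seq_len(rg$n2))
    j <- c(j, rg$orig_nodes2, rg$orig_nodes2)
    x <- c(x, rep(1, rg$n2), rep(-2 / 3, rg$n2))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(hybrid$dimension, rg$n_orig))
}

#' Assemble the full hybrid (or pure) transport system for a mesh
#'
#' Convenience wrapper: classifies, regroups, assembles DE on Region 1 and
#' SP3 on Region 2, builds the block system and couples the interface.
#' `model = "de"` or `"sp3"` forces the whole mesh into one region,
#' reproducing the corresponding pure model.
#'
#' @param mesh a `tet_mesh` with tissue labels.
#' @param props named list of `optical_properties` per tissue (or a single
#'   object for a homogeneous medium).
#' @param rule named tissue-to-region map; ignored for pure models.
#' @param model `"mrhm"` (hybrid), `"de"` or `"sp3"`.
#' @param lump passed to the assemblers: row-sum mass lumping (see
#'   [assemble_de()]).
#' @return a coupled `hybrid_system`.
#' @export
assemble_model <- function(mesh, props, rule = NULL,
                           model = c("mrhm", "de", "sp3"), lump = FALSE) {
  model <- match.arg(model)
  if (model == "de") {
    mesh$region <- rep(1L, nrow(mesh$tets))
  } else if (model == "sp3") {
    mesh$region <- rep(2L, nrow(mesh$tets))
  } else if (!is.null(rule)) {
    mesh <- classify_regions(mesh, rule)
  } else if (is.null(mesh$region)) {
    if (inherits(props, "optical_properties"))
      stop("mrhm needs a region rule or pre-set region labels")
    mesh <- classify_regions(mesh, region_rule(props))
  }
  rg <- regroup_mesh(mesh)
  de_sys <- if (rg$n1) assemble_de(rg$mesh1, props, lump = lump) else NULL
  sp3_sys <- if (rg$n2) assemble_sp3(rg$mesh2, props, lump = lump) else NULL
  couple_interface_nodes(build_hybrid_system(rg, de_sys, sp3_sys))
}
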