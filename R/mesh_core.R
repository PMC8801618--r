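#' Construct a labelled tetrahedral mesh
#'
#' A `tet_mesh` is the geometric substrate for all forward and inverse
#' modelling: node coordinates in mm, tetrahedral connectivity, a per-element
#' tissue label, an optional per-element region label (1 = diffusion-equation
#' region, 2 = SP3 region), and the faces of the outer surface.
#'
#' Tetrahedra are canonically reoriented so every signed volume is positive
#' (assembly formulas assume positive Jacobians). All indices are 0-free:
#' 1-based throughout the R interface, converted only at file-format
#' boundaries that require otherwise.
#'
#' @param nodes numeric matrix, n x 3, node coordinates (mm).
#' @param tets integer matrix, t x 4, 1-based node indices per tetrahedron.
#' @param tissue vector of length t with per-element tissue labels
#'   (character or integer).
#' @param region optional integer vector of length t with values in `{1, 2}`.
#' @param boundary_faces optional integer matrix of outer-surface faces;
#'   recomputed from the connectivity when missing.
#' @param validate logical; run the full validity checks (default `TRUE`).
#' @return an object of class `tet_mesh` with elements `nodes`, `tets`,
#'   `tissue`, `region`, `boundary_faces`.
#' @export
tet_mesh <- function(nodes, tets, tissue = rep(1L, nrow(tets)), region = NULL,
                     boundary_faces = NULL, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("tets must be a t x 4 matrix")
  if (length(tissue) != nrow(tets)) stop("tissue must have one label per tet")
  if (validate) {
    if (any(tets < 1L) || any(tets > nrow(nodes)))
      stop("tet refers to node index outside [1, n]")
    distinct <- apply(tets, 1L, function(v) length(unique(v)) == 4L)
    if (!all(distinct))
      stop("tet ", which(!distinct)[1L], " has repeated vertices")
  }
  vol <- tet_signed_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) { # canonical positive orientation
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  if (validate && any(vol <= .Machine$double.eps^0.9 * max(vol, 1)))
    stop("degenerate (zero-volume) tet at index ",
         which(vol <= .Machine$double.eps^0.9 * max(vol, 1))[1L])
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != nrow(tets) || !all(region %in% c(1L, 2L)))
      stop("region must be a per-tet vector with values in {1, 2}")
  }
  m <- structure(list(nodes = nodes, tets = tets, tissue = tissue,
                      region = region, boundary_faces = NULL),
                 class = "tet_mesh")
  m$boundary_faces <- if (is.null(boundary_faces)) {
    boundary_faces_of(tets)
  } else {
    bf <- as.matrix(boundary_faces); storage.mode(bf) <- "integer"; bf
  }
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      nrow(x$boundary_faces), "boundary faces\n")
  cat("  tissues:", paste(sort(unique(as.character(x$tissue))), collapse = ", "), "\n")
  if (!is.null(x$region))
    cat("  region split:", sum(x$region == 1L), "DE tets /",
        sum(x$region == 2L), "SP3 tets\n")
  invisible(x)
}

#' Signed volumes of tetrahedra
#'
#' @param nodes n x 3 coordinate matrix.
#' @param tets t x 4 index matrix.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c_ <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) -
   b[, 2L] * (c_[, 1L] * d[, 3L] - c_[, 3L] * d[, 1L]) +
   b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

#' Total mesh volume
#' @param mesh a `tet_mesh`.
#' @return total volume in mm^3.
#' @export
mesh_volume <- function(mesh) sum(abs(tet_signed_volumes(mesh$nodes, mesh$tets)))

# Sorted-vertex key for each triangle, vectorised.
face_keys <- function(faces) {
  a <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  c_ <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  b <- faces[, 1L] + faces[, 2L] + faces[, 3L] - a - c_
  paste(a, b, c_)
}

# All four faces of every tet, keyed by their sorted vertex triple.
all_tet_faces <- function(tets) {
  t <- nrow(tets)
  # face k is opposite local vertex k; vertex order chosen so the outward
  # normal of face k (for a positively oriented tet) is right-handed
  faces <- rbind(tets[, c(2L, 4L, 3L), drop = FALSE],
                 tets[, c(1L, 3L, 4L), drop = FALSE],
                 tets[, c(1L, 4L, 2L), drop = FALSE],
                 tets[, c(1L, 2L, 3L), drop = FALSE])
  owner <- rep.int(seq_len(t), 4L)
  list(faces = faces, owner = owner, key = face_keys(faces))
}

boundary_faces_of <- function(tets) {
  af <- all_tet_faces(tets)
  ki <- match(af$key, af$key)              # first-occurrence index per key
  cnt <- tabulate(ki, nbins = length(ki))
  if (any(cnt > 2L))
    stop("non-manifold face shared by more than two tets")
  keep <- cnt[ki] == 1L
  bf <- af$faces[keep, , drop = FALSE]
  storage.mode(bf) <- "integer"
  bf
}

#' Extract outer-boundary faces with outward normals
#'
#' A boundary face is a triangle belonging to exactly one tetrahedron. Only
#' the initial outer boundary of the solution domain carries boundary
#' (Robin-type) integrals; internal region interfaces do not.
#'
#' @param mesh a `tet_mesh`.
#' @return a list with `faces` (b x 3 node indices), `normals` (b x 3 unit
#'   outward normals), `areas` (length-b vector, mm^2) and `owner`
#'   (owning tet index per face).
#' @export
extract_boundary_faces <- function(mesh) {
  af <- all_tet_faces(mesh$tets)
  ki <- match(af$key, af$key)
  cnt <- tabulate(ki, nbins = length(ki))
  if (any(cnt > 2L)) stop("non-manifold face shared by more than two tets")
  keep <- cnt[ki] == 1L
  faces <- af$faces[keep, , drop = FALSE]
  owner <- af$owner[keep]
  p1 <- mesh$nodes[faces[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[faces[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[faces[, 3L], , drop = FALSE]
  cr <- cross3(p2 - p1, p3 - p1)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  normals <- cr / (2 * areas)
  # orient away from the owning tet centroid
  cent <- (mesh$nodes[mesh$tets[owner, 1L], , drop = FALSE] +
           mesh$nodes[mesh$tets[owner, 2L], , drop = FALSE] +
           mesh$nodes[mesh$tets[owner, 3L], , drop = FALSE] +
           mesh$nodes[mesh$tets[owner, 4L], , drop = FALSE]) / 4
  fc <- (p1 + p2 + p3) / 3
  flip <- rowSums(normals * (fc - cent)) < 0
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  list(faces = faces, normals = normals, areas = areas, owner = owner)
}

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Assign model regions from tissue labels
#'
#' Region assignment is a pure function of tissue: every element of one
#' tissue is modelled by the same approximation, mirroring organ-level
#' assignment (e.g. adipose, stomach and kidneys to the DE region; heart,
#' liver and lungs to the SP3 region).
#'
#' @param mesh a `tet_mesh`.
#' @param rule named vector or list mapping tissue label to region (1 or 2).
#' @return the mesh with `region` set.
#' @export
classify_regions <- function(mesh, rule) {
  rule <- unlist(rule)
  lab <- as.character(mesh$tissue)
  missing <- setdiff(unique(lab), names(rule))
  if (length(missing))
    stop("tissue label(s) absent from region rule: ",
         paste(missing, collapse = ", "))
  reg <- as.integer(rule[lab])
  if (!all(reg %in% c(1L, 2L))) stop("region rule values must be 1 or 2")
  mesh$region <- reg
  mesh
}

#' Regroup a two-region mesh into separate sub-meshes
#'
#' Splits a region-labelled mesh into two self-contained sub-meshes, one per
#' model region, with locally renumbered nodes. Nodes shared by both regions
#' are duplicated into each sub-mesh; the duplicates are recorded as
#' interface pairs so the two finite-element systems can later be coupled.
#' Node renumbering is stable (preserves the source mesh's relative order),
#' which makes regrouping deterministic.
#'
#' Each sub-mesh inherits only the portion of the *original* outer boundary
#' carried by its tets: the internal interface is not a boundary for the
#' Robin terms.
#'
#' @param mesh a `tet_mesh` with `region` set on every tet (if all tets lie
#'   in a single region, the other sub-mesh is empty and there are no
#'   interface pairs).
#' @return an object of class `regrouped_mesh` with elements `mesh1`,
#'   `mesh2`, `n1`, `n2`, `t1`, `t2`, `interface_pairs` (k x 2 matrix of
#'   (mesh1 index, mesh2 index)), `orig_nodes1`, `orig_nodes2` (original
#'   index of each local node), and `boundary_node_order` (data.frame of the
#'   reordered outer-boundary nodes).
#' @export
regroup_mesh <- function(mesh) {
  if (is.null(mesh$region)) stop("mesh has no region labels; run classify_regions()")
  sub <- function(r) {
    sel <- mesh$region == r
    tt <- mesh$tets[sel, , drop = FALSE]
    orig <- sort(unique(as.vector(tt)))
    if (length(orig) == 0L)
      return(list(mesh = NULL, orig = integer(0)))
    loc <- integer(nrow(mesh$nodes))
    loc[orig] <- seq_along(orig)
    ltets <- matrix(loc[tt], ncol = 4L)
    # boundary faces restricted to the original outer boundary
    keyb <- face_keys(mesh$boundary_faces)
    af <- all_tet_faces(tt)
    keep <- af$key %in% keyb
    bf <- matrix(loc[af$faces[keep, , drop = FALSE]], ncol = 3L)
    sm <- tet_mesh(mesh$nodes[orig, , drop = FALSE], ltets,
                   tissue = mesh$tissue[sel],
                   region = mesh$region[sel],
                   boundary_faces = bf, validate = FALSE)
    list(mesh = sm, orig = orig)
  }
  s1 <- sub(1L); s2 <- sub(2L)
  shared <- intersect(s1$orig, s2$orig)
  pairs <- if (length(shared)) {
    cbind(match(shared, s1$orig), match(shared, s2$orig))
  } else matrix(integer(0), ncol = 2L)
  colnames(pairs) <- c("mesh1", "mesh2")
  bnodes <- sort(unique(as.vector(mesh$boundary_faces)))
  in1 <- bnodes %in% s1$orig
  border <- data.frame(
    orig = c(bnodes[in1], bnodes[!in1]),
    mesh = c(rep(1L, sum(in1)), rep(2L, sum(!in1))))
  border$local <- ifelse(border$mesh == 1L,
                         match(border$orig, s1$orig),
                         match(border$orig, s2$orig))
  structure(list(
    mesh1 = s1$mesh, mesh2 = s2$mesh,
    n1 = length(s1$orig), n2 = length(s2$orig),
    t1 = if (is.null(s1$mesh)) 0L else nrow(s1$mesh$tets),
    t2 = if (is.null(s2$mesh)) 0L else nrow(s2$mesh$tets),
    interface_pairs = pairs,
    orig_nodes1 = s1$orig, orig_nodes2 = s2$orig,
    n_orig = nrow(mesh$nodes),
    boundary_node_order = border), class = "regrouped_mesh")
}

#' @export
print.regrouped_mesh <- function(x, ...) {
  cat("regrouped_mesh: n1 =", x$n1, "(DE), n2 =", x$n2, "(SP3), t1 =",
      x$t1, ", t2 =", x$t2, ",", nrow(x$interface_pairs),
      "interface pairs\n")
  invisible(x)
}

#' Find interface duplicates between two sub-meshes
#'
#' Interface nodes are duplicated by copying during regrouping, so by default
#' they are detected by exact (bitwise) coordinate identity; an absolute
#' tolerance can be supplied for externally produced mesh pairs. The match
#' must be one-to-one: distinct nodes of one sub-mesh at the same point make
#' the source mesh invalid.
#'
#' @param mesh1,mesh2 two `tet_mesh` objects from one regrouping.
#' @param tol absolute coordinate tolerance; 0 (default) means exact match.
#' @return k x 2 integer matrix of (mesh1 node, mesh2 node) pairs.
#' @export
find_interface_duplicates <- function(mesh1, mesh2, tol = 0) {
  key <- function(m, tl) {
    xyz <- if (tl > 0) round(m$nodes / tl) * tl else m$nodes
    paste(sprintf("%.17g", xyz[, 1L]), sprintf("%.17g", xyz[, 2L]),
          sprintf("%.17g", xyz[, 3L]))
  }
  k1 <- key(mesh1, tol); k2 <- key(mesh2, tol)
  if (anyDuplicated(k1) || anyDuplicated(k2))
    stop("coordinate collision: distinct nodes of one sub-mesh at the same point")
  shared <- intersect(k1, k2)
  if (!length(shared)) return(matrix(integer(0), ncol = 2L,
                                     dimnames = list(NULL, c("mesh1", "mesh2"))))
  cbind(mesh1 = match(shared, k1), mesh2 = match(shared, k2))
}

#' Merge a regrouped mesh back into a single mesh
#'
#' Inverse of [regroup_mesh()]: concatenates the sub-meshes and fuses the
#' interface duplicates. The result reproduces the source mesh up to node
#' relabeling (see [meshes_isomorphic()]).
#'
#' @param rg a `regrouped_mesh`.
#' @return a `tet_mesh`.
#' @export
merge_regrouped <- function(rg) {
  if (is.null(rg$mesh1)) return(rg$mesh2)
  if (is.null(rg$mesh2)) return(rg$mesh1)
  n1 <- rg$n1; n2 <- rg$n2
  map2 <- n1 + seq_len(n2)             # default: append mesh2 nodes
  if (nrow(rg$interface_pairs)) {
    map2[rg$interface_pairs[, 2L]] <- rg$interface_pairs[, 1L]
  }
  keep2 <- setdiff(seq_len(n2), rg$interface_pairs[, 2L])
  # compact the appended indices
  newidx <- integer(n1 + n2)
  newidx[seq_len(n1)] <- seq_len(n1)
  newidx[n1 + keep2] <- n1 + seq_along(keep2)
  for (i in seq_len(nrow(rg$interface_pairs)))
    newidx[n1 + rg$interface_pairs[i, 2L]] <- rg$interface_pairs[i, 1L]
  nodes <- rbind(rg$mesh1$nodes, rg$mesh2$nodes[keep2, , drop = FALSE])
  tets2 <- matrix(newidx[n1 + rg$mesh2$tets], ncol = 4L)
  tet_mesh(nodes, rbind(rg$mesh1$tets, tets2),
           tissue = c(rg$mesh1$tissue, rg$mesh2$tissue),
           region = c(rg$mesh1$region, rg$mesh2$region))
}

#' Test two meshes for equality up to node relabeling
#'
#' Canonicalises both meshes (nodes sorted lexicographically by coordinates,
#' tets as sorted vertex tuples, tets sorted) and compares coordinates and
#' connectivity exactly.
#'
#' @param a,b `tet_mesh` objects.
#' @return `TRUE` or `FALSE`.
#' @export
meshes_isomorphic <- function(a, b) {
  if (nrow(a$nodes) != nrow(b$nodes) || nrow(a$tets) != nrow(b$tets))
    return(FALSE)
  canon <- function(m) {
    ord <- order(m$nodes[, 1L], m$nodes[, 2L], m$nodes[, 3L])
    rank <- integer(nrow(m$nodes)); rank[ord] <- seq_along(ord)
    tt <- t(apply(matrix(rank[m$tets], ncol = 4L), 1L, sort))
    tt <- tt[order(tt[, 1L], tt[, 2L], tt[, 3L], tt[, 4L]), , drop = FALSE]
    list(nodes = m$nodes[ord, , drop = FALSE], tets = tt)
  }
  ca <- canon(a); cb <- canon(b)
  isTRUE(all.equal(ca$nodes, cb$nodes, tolerance = 0)) &&
    identical(ca$tets, cb$tets)
}
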