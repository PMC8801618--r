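#' Read a tetrahedral mesh from file
#'
#' Supported formats: legacy ASCII VTK unstructured grids (`.vtk`) and Gmsh
#' MSH 2.2 ASCII (`.msh`), both restricted to tetrahedral cells with an
#' integer per-cell tissue field. Node and cell indices are converted to
#' 1-based on read.
#'
#' @param path file path.
#' @param tissue_field name of the per-cell data array holding tissue labels
#'   (VTK `CELL_DATA` array name; ignored for MSH, where the physical/tag
#'   column is used).
#' @return a `tet_mesh`.
#' @export
load_mesh <- function(path, tissue_field = "tissue") {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    vtk = read_mesh_vtk(path, tissue_field),
    msh = read_mesh_msh(path),
    stop("unsupported mesh format: .", ext, " (supported: .vtk, .msh)"))
  message(sprintf("loaded mesh: %d nodes, %d tets", nrow(m$nodes), nrow(m$tets)))
  m
}

#' @rdname load_mesh
#' @param mesh a `tet_mesh` to write.
#' @param region_field optional name under which to write region labels.
#' @export
write_mesh <- function(mesh, path, tissue_field = "tissue",
                       region_field = "region") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    vtk = write_mesh_vtk(mesh, path, tissue_field, region_field),
    msh = write_mesh_msh(mesh, path),
    stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_mesh_vtk <- function(path, tissue_field = "tissue") {
  lines <- readLines(path)
  stopifnot(length(lines) > 4L)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1L]]
  i <- grep("^POINTS", lines)[1L]
  if (is.na(i)) stop("VTK file has no POINTS section")
  n <- as.integer(toks(lines[i])[2L])
  vals <- scan(text = lines[(i + 1L):length(lines)], n = 3L * n,
               quiet = TRUE)
  nodes <- matrix(vals, ncol = 3L, byrow = TRUE)
  i <- grep("^CELLS", lines)[1L]
  if (is.na(i)) stop("VTK file has no CELLS section")
  t <- as.integer(toks(lines[i])[2L])
  cvals <- scan(text = lines[(i + 1L):length(lines)],
                n = as.integer(toks(lines[i])[3L]), quiet = TRUE)
  # each record: count followed by indices
  tets <- matrix(0L, t, 4L); p <- 1L
  for (j in seq_len(t)) {
    k <- cvals[p]
    if (k != 4L) stop("mesh contains a non-tetrahedral cell (cell ", j, ")")
    tets[j, ] <- cvals[(p + 1L):(p + 4L)] + 1L
    p <- p + k + 1L
  }
  i <- grep("^CELL_TYPES", lines)[1L]
  if (!is.na(i)) {
    ct <- scan(text = lines[(i + 1L):length(lines)], n = t, quiet = TRUE)
    if (any(ct != 10L)) stop("mesh contains non-tet cell types")
  }
  tissue <- rep(1L, t); region <- NULL
  ic <- grep("^CELL_DATA", lines)[1L]
  if (!is.na(ic)) {
    arr_starts <- grep("^SCALARS", lines)
    arr_starts <- arr_starts[arr_starts > ic]
    got_tissue <- FALSE
    for (a in arr_starts) {
      nm <- toks(lines[a])[2L]
      v <- scan(text = lines[(a + 2L):length(lines)], n = t, quiet = TRUE)
      if (nm == tissue_field) { tissue <- as.integer(v); got_tissue <- TRUE }
      if (nm == "region") region <- as.integer(v)
    }
    if (!got_tissue)
      stop("tissue field '", tissue_field, "' not found in CELL_DATA")
  }
  tet_mesh(nodes, tets, tissue = tissue, region = region)
}

write_mesh_vtk <- function(mesh, path, tissue_field = "tissue",
                           region_field = "region") {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); t <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "luxtomo tetrahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1L, function(p)
    paste(format(p, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", t, 5L * t), con)
  writeLines(apply(mesh$tets - 1L, 1L, function(v)
    paste(c(4L, v), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", t), con)
  writeLines(rep("10", t), con)
  writeLines(sprintf("CELL_DATA %d", t), con)
  writeLines(c(sprintf("SCALARS %s int 1", tissue_field),
               "LOOKUP_TABLE default"), con)
  tis <- if (is.numeric(mesh$tissue)) as.integer(mesh$tissue) else
    as.integer(as.factor(mesh$tissue))
  writeLines(as.character(tis), con)
  if (!is.null(mesh$region)) {
    writeLines(c(sprintf("SCALARS %s int 1", region_field),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(mesh$region), con)
  }
  invisible(path)
}

read_mesh_msh <- function(path) {
  lines <- readLines(path)
  ver <- grep("^\\$MeshFormat", lines)[1L]
  if (is.na(ver)) stop("not a Gmsh MSH file")
  i0 <- grep("^\\$Nodes", lines)[1L]
  n <- as.integer(lines[i0 + 1L])
  nd <- utils::read.table(text = lines[(i0 + 2L):(i0 + 1L + n)])
  nodes <- unname(as.matrix(nd[, 2:4]))
  id <- as.integer(nd[, 1L])
  remap <- integer(max(id)); remap[id] <- seq_len(n)
  i0 <- grep("^\\$Elements", lines)[1L]
  ne <- as.integer(lines[i0 + 1L])
  el <- strsplit(trimws(lines[(i0 + 2L):(i0 + 1L + ne)]), "\\s+")
  tets <- list(); tissue <- integer(0)
  for (e in el) {
    e <- as.integer(e)
    if (e[2L] == 4L) {                     # 4 = linear tetrahedron
      ntags <- e[3L]
      tets[[length(tets) + 1L]] <- remap[e[(4L + ntags):(7L + ntags)]]
      tissue <- c(tissue, if (ntags >= 1L) e[4L] else 1L)
    }
  }
  if (!length(tets)) stop("MSH file contains no tetrahedral elements")
  tet_mesh(nodes, do.call(rbind, tets), tissue = tissue)
}

write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); t <- nrow(mesh$tets)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(paste(seq_len(n),
                   format(mesh$nodes[, 1L], digits = 17, trim = TRUE),
                   format(mesh$nodes[, 2L], digits = 17, trim = TRUE),
                   format(mesh$nodes[, 3L], digits = 17, trim = TRUE)), con)
  writeLines(c("$EndNodes", "$Elements", as.character(t)), con)
  tis <- if (is.numeric(mesh$tissue)) as.integer(mesh$tissue) else
    as.integer(as.factor(mesh$tissue))
  writeLines(paste(seq_len(t), 4L, 2L, tis, tis,
                   mesh$tets[, 1L], mesh$tets[, 2L],
                   mesh$tets[, 3L], mesh$tets[, 4L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}
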