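# Plain-text mesh/solution export: legacy VTK and Gmsh MSH 2.2.

#' Export a mesh (and optional nodal fields) to legacy VTK
#'
#' Cells are written as linear triangles on the corner nodes (adequate for
#' field inspection); nodal point data cover every node referenced.
#'
#' @param mesh a `mesh_model`.
#' @param file output path.
#' @param point_data optional named list of per-node vectors (length = number
#'   of nodes) or two-column matrices (r/z components).
#' @return invisibly, the file path.
#' @export
write_vtk <- function(mesh, file, point_data = list()) {
  corner <- do.call(cbind, lapply(mesh$blocks, function(b)
    b$elems[c(1, b$order + 1, nrow(b$elems)), , drop = FALSE]))
  region <- unlist(lapply(mesh$blocks, `[[`, "region"))
  n <- nrow(mesh$nodes)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "orbitfem axisymmetric mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  E <- ncol(corner)
  writeLines(sprintf("CELLS %d %d", E, 4 * E), con)
  writeLines(sprintf("3 %d %d %d", corner[1, ] - 1, corner[2, ] - 1,
                     corner[3, ] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(rep("5", E), con)
  writeLines(sprintf("CELL_DATA %d", E), con)
  writeLines("SCALARS region int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(as.character(region), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g 0", v[, 1], v[, 2]), con)
      } else {
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  invisible(file)
}

#' Export a mesh to Gmsh MSH 2.2 (ASCII)
#'
#' Order-1 and order-2 meshes export their native element type (2 or 9);
#' higher orders are written as corner-node linear triangles. Region names are
#' written as physical names.
#'
#' @param mesh a `mesh_model`.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  region_all <- unlist(lapply(mesh$blocks, `[[`, "region"))
  regs <- sort(unique(region_all))
  writeLines("$PhysicalNames", con)
  writeLines(as.character(length(regs)), con)
  writeLines(sprintf("2 %d \"%s\"", regs, mesh$region_names[regs]), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.9g %.9g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines("$EndNodes", con)
  writeLines("$Elements", con)
  E <- sum(vapply(mesh$blocks, function(b) ncol(b$elems), 1))
  writeLines(as.character(E), con)
  eid <- 0L
  for (b in mesh$blocks) {
    nb <- ncol(b$elems)
    if (b$order == 2) {
      # lattice -> gmsh type 9 ordering: corners V1 V2 V3, mids 12 23 31
      idx <- c(1, 3, 6, 2, 5, 4)
      lines <- sprintf("%d 9 2 %d %d %s", eid + seq_len(nb), b$region,
                       b$region,
                       apply(b$elems[idx, , drop = FALSE], 2, paste,
                             collapse = " "))
    } else {
      corner <- b$elems[c(1, b$order + 1, nrow(b$elems)), , drop = FALSE]
      lines <- sprintf("%d 2 2 %d %d %s", eid + seq_len(nb), b$region,
                       b$region,
                       apply(corner, 2, paste, collapse = " "))
    }
    writeLines(lines, con)
    eid <- eid + nb
  }
  writeLines("$EndElements", con)
  invisible(file)
}
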