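#' Extract the axis-aligned surface mesh of a phantom
#'
#' One mesh element per exposed voxel face: a face of a non-air voxel whose
#' neighbour across that face is air or lies outside the grid. Element
#' centers sit on the voxel face, normals are the outward +/- axis unit
#' vectors, and the area is the product of the two transverse spacings.
#' This exposed-face representation keeps photon-exit bookkeeping exact per
#' face; smoothed triangulations are for visualization only (see
#' [write_ply()]).
#'
#' @param grid A [voxel_grid()] with at least one non-air voxel adjacent to
#'   air or to the domain boundary.
#' @return A `surface_mesh`: tibble with columns `element_id`, `ix`, `iy`,
#'   `iz` (1-based voxel indices), `face` (1..6 = +x,-x,+y,-y,+z,-z),
#'   `cx`, `cy`, `cz` (element center, mm), `nx`, `ny`, `nz` (outward
#'   normal), `area` (mm^2), with the grid geometry in attributes.
#' @export
extract_surface_mesh <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  solid <- grid$tissue != 0L
  if (!any(solid)) abort("grid is all air: no surface to extract")
  d <- grid$dims
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- solid

  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  normals <- do.call(rbind, shifts)
  rows <- vector("list", 6)
  for (f in seq_len(6)) {
    s <- shifts[[f]]
    nb <- pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2], 2:(d[3] + 1) + s[3]]
    exposed <- which(solid & !nb, arr.ind = TRUE)
    if (nrow(exposed) == 0) next
    ctr <- sweep(sweep(exposed - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
    ctr <- ctr + 0.5 * matrix(s, nrow(exposed), 3, byrow = TRUE) *
      matrix(grid$spacing, nrow(exposed), 3, byrow = TRUE)
    axis <- which(s != 0)
    area <- prod(grid$spacing[-axis])
    rows[[f]] <- tibble(
      ix = exposed[, 1], iy = exposed[, 2], iz = exposed[, 3],
      face = f,
      cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
      nx = s[1], ny = s[2], nz = s[3],
      area = area
    )
  }
  mesh <- bind_rows(rows)
  mesh <- mesh[order(mesh$iz, mesh$iy, mesh$ix, mesh$face), ]
  mesh$element_id <- seq_len(nrow(mesh))
  mesh <- mesh[, c("element_id", "ix", "iy", "iz", "face",
                   "cx", "cy", "cz", "nx", "ny", "nz", "area")]
  attr(mesh, "dims") <- grid$dims
  attr(mesh, "spacing") <- grid$spacing
  attr(mesh, "origin") <- grid$origin
  class(mesh) <- c("surface_mesh", class(mesh))
  mesh
}

# map (voxel linear index, face code) pairs to element ids; NA if the face
# is not part of the mesh
match_mesh_elements <- function(mesh, voxel, face) {
  dims <- attr(mesh, "dims")
  mesh_vox <- mesh$ix + dims[1] * (mesh$iy - 1 + dims[2] * (mesh$iz - 1))
  key_mesh <- paste(mesh_vox, mesh$face)
  mesh$element_id[match(paste(voxel, face), key_mesh)]
}

#' Export a surface mesh as an ASCII PLY file
#'
#' Writes each exposed voxel face as a quad (for visualization; the
#' analysis itself runs on the face elements directly).
#'
#' @param mesh A `surface_mesh` from [extract_surface_mesh()].
#' @param path Output path.
#' @export
write_ply <- function(mesh, path) {
  sp <- attr(mesh, "spacing")
  n <- nrow(mesh)
  verts <- matrix(0, 4 * n, 3)
  for (i in seq_len(n)) {
    axis <- ceiling(mesh$face[i] / 2)
    others <- setdiff(1:3, axis)
    c0 <- c(mesh$cx[i], mesh$cy[i], mesh$cz[i])
    u <- v <- c(0, 0, 0)
    u[others[1]] <- sp[others[1]] / 2
    v[others[2]] <- sp[others[2]] / 2
    verts[4 * i - 3, ] <- c0 - u - v
    verts[4 * i - 2, ] <- c0 + u - v
    verts[4 * i - 1, ] <- c0 + u + v
    verts[4 * i, ] <- c0 - u + v
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", 4 * n),
               "property float x", "property float y", "property float z",
               paste("element face", n),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(verts, 1, function(r) paste(signif(r, 8), collapse = " ")),
             con)
  idx <- (seq_len(n) - 1) * 4
  writeLines(paste(4, idx, idx + 1, idx + 2, idx + 3), con)
  invisible(path)
}
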