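# 3D shape features of the lesion mask. Volume, area, sphericity and the
# diameters are computed on a triangle mesh of the mask surface (marching
# cubes at iso-level 0.5 with vertices at edge midpoints, the standard
# construction for binary masks); axis lengths come from the eigenvalues of
# the covariance of the voxel-centre coordinates.

# Triangle mesh of the mask surface. Returns vertices (n x 3 physical mm)
# and a triangle index matrix (m x 3), wound with outward normals.
mask_mesh <- function(mask, spacing) {
  d <- dim(mask)
  pm <- array(0L, dim = d + 2L)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.integer(mask)
  dp <- dim(pm)
  nc <- dp - 1L # cells per axis

  corner <- function(off) {
    pm[(1L + off[1]):(nc[1] + off[1]),
       (1L + off[2]):(nc[2] + off[2]),
       (1L + off[3]):(nc[3] + off[3]), drop = FALSE]
  }
  cfg <- array(0L, dim = nc)
  for (b in 1:8) {
    cfg <- cfg + corner(.mc_corner_offsets[b, ]) * (2L^(b - 1L))
  }
  cells <- which(cfg > 0L & cfg < 255L)
  if (length(cells) == 0L) {
    return(list(vertices = matrix(numeric(0), 0, 3),
                triangles = matrix(integer(0), 0, 3)))
  }
  idx <- arrayInd(cells, nc)
  cfgs <- cfg[cells]

  n_edges <- lengths(.mc_tri_table)[cfgs + 1L]
  edge_ids <- unlist(.mc_tri_table[cfgs + 1L], use.names = FALSE)
  cell_rep <- rep(seq_along(cells), n_edges)

  # vertex position = cell origin + edge midpoint offset, in padded index
  # space; shift back by the pad and convert to physical mm
  emid <- (.mc_corner_offsets[.mc_edge_corners[, 1], ] +
             .mc_corner_offsets[.mc_edge_corners[, 2], ]) / 2
  verts <- (idx[cell_rep, , drop = FALSE] - 1L) + emid[edge_ids, , drop = FALSE]
  verts <- sweep(sweep(verts, 2, c(1, 1, 1)), 2, spacing, `*`)
  tris <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, triangles = tris)
}

mesh_volume_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(c(volume = 0, area = 0))
  v1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  cross23 <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
                   v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
                   v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  vol <- abs(sum(rowSums(v1 * cross23)) / 6)
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  c(volume = vol, area = area)
}

#' Shape features of a lesion mask
#'
#' Fourteen mesh- and moment-based descriptors of the 3D lesion geometry:
#' mesh and voxel volume, surface area, surface-to-volume ratio, sphericity,
#' the maximum 3D diameter and the three in-plane maximum 2D diameters, the
#' three principal axis lengths, elongation and flatness. Shape features use
#' only the mask and spacing, never the intensities.
#'
#' @param vm A [rad_volume()].
#' @return Named numeric vector of the 14 `shape_*` features.
#' @export
extract_shape <- function(vm) {
  sp <- vm$spacing
  n_vox <- sum(vm$mask)
  mesh <- mask_mesh(vm$mask, sp)
  va <- mesh_volume_area(mesh)
  vol <- va[["volume"]]; area <- va[["area"]]

  coords <- mask_coords(vm)
  if (n_vox >= 2L) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else {
    ev <- c(0, 0, 0)
  }
  axis_len <- 4 * sqrt(ev)

  uv <- unique(round(mesh$vertices / 1e-9) * 1e-9)
  max3d <- if (nrow(uv) >= 2L) max_pairwise_dist_cpp(uv) else 0
  diam2d <- function(drop_axis) {
    if (nrow(uv) < 2L) return(0)
    g <- uv[, drop_axis]
    o <- order(g)
    max_pairwise_dist_grouped_cpp(uv[o, , drop = FALSE], g[o])
  }

  sphericity <- if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else 0
  c(
    shape_MeshVolume = vol,
    shape_VoxelVolume = n_vox * prod(sp),
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = if (vol > 0) area / vol else 0,
    shape_Sphericity = sphericity,
    shape_Maximum3DDiameter = max3d,
    shape_Maximum2DDiameterSlice = diam2d(3L),
    shape_Maximum2DDiameterColumn = diam2d(2L),
    shape_Maximum2DDiameterRow = diam2d(1L),
    shape_MajorAxisLength = axis_len[1],
    shape_MinorAxisLength = axis_len[2],
    shape_LeastAxisLength = axis_len[3],
    shape_Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    shape_Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}
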