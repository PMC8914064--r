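# Marching-cubes triangle table for binary volumes (iso-level 0.5).
# Per corner-configuration list of cube-edge ids (1-based), three per
# triangle; triangles are wound so normals point out of the mask.
# Corner b of a cell is inside when bit b of the configuration is set;
# corners ordered (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),
# (1,1,1),(0,1,1) in voxel-index steps.
.mc_edge_corners <- matrix(c(1L,2L,2L,3L,3L,4L,4L,1L,5L,6L,6L,7L,7L,8L,8L,5L,1L,5L,2L,6L,3L,7L,4L,8L), ncol = 2L, byrow = TRUE)

.mc_corner_offsets <- matrix(c(0L,0L,0L,1L,0L,0L,1L,1L,0L,0L,1L,0L,0L,0L,1L,1L,0L,1L,1L,1L,1L,0L,1L,1L), ncol = 3L, byrow = TRUE)

.mc_tri_table <- list(
  integer(0),
  c(4L,9L,1L),
  c(1L,10L,2L),
  c(9L,10L,4L,10L,2L,4L),
  c(3L,2L,11L),
  c(1L,4L,9L,11L,3L,2L),
  c(10L,11L,1L,11L,3L,1L),
  c(3L,4L,11L,11L,4L,9L,11L,9L,10L),
  c(12L,4L,3L),
  c(12L,9L,3L,9L,1L,3L),
  c(2L,1L,10L,12L,4L,3L),
  c(2L,3L,10L,10L,3L,12L,10L,12L,9L),
  c(4L,2L,12L,2L,11L,12L),
  c(1L,2L,9L,9L,2L,11L,9L,11L,12L),
  c(4L,1L,12L,12L,1L,10L,12L,10L,11L),
  c(12L,9L,10L,12L,10L,11L),
  c(5L,9L,8L),
  c(4L,8L,1L,8L,5L,1L),
  c(5L,9L,8L,2L,1L,10L),
  c(5L,10L,8L,8L,10L,2L,8L,2L,4L),
  c(5L,9L,8L,11L,3L,2L),
  c(5L,1L,8L,8L,1L,4L,11L,3L,2L),
  c(3L,1L,11L,11L,1L,10L,8L,5L,9L),
  c(11L,5L,10L,4L,5L,11L,8L,5L,4L,11L,3L,4L),
  c(9L,8L,5L,3L,12L,4L),
  c(12L,8L,3L,3L,8L,5L,3L,5L,1L),
  c(8L,5L,9L,2L,1L,10L,3L,12L,4L),
  c(3L,10L,2L,3L,5L,10L,12L,5L,3L,8L,5L,12L),
  c(11L,12L,2L,2L,12L,4L,5L,9L,8L),
  c(12L,8L,11L,11L,8L,1L,1L,8L,5L,11L,1L,2L),
  c(9L,8L,5L,10L,12L,4L,11L,12L,10L,1L,10L,4L),
  c(10L,8L,5L,12L,8L,10L,11L,12L,10L),
  c(10L,5L,6L),
  c(10L,5L,6L,4L,9L,1L),
  c(1L,5L,2L,5L,6L,2L),
  c(9L,5L,4L,4L,5L,6L,4L,6L,2L),
  c(6L,10L,5L,3L,2L,11L),
  c(4L,9L,1L,6L,10L,5L,11L,3L,2L),
  c(6L,11L,5L,5L,11L,3L,5L,3L,1L),
  c(3L,4L,11L,4L,9L,11L,11L,9L,6L,6L,9L,5L),
  c(10L,5L,6L,3L,12L,4L),
  c(12L,9L,3L,3L,9L,1L,6L,10L,5L),
  c(6L,2L,5L,5L,2L,1L,12L,4L,3L),
  c(2L,5L,6L,12L,5L,2L,9L,5L,12L,3L,12L,2L),
  c(4L,2L,12L,12L,2L,11L,5L,6L,10L),
  c(10L,5L,6L,11L,9L,1L,12L,9L,11L,2L,11L,1L),
  c(5L,6L,1L,1L,6L,12L,12L,6L,11L,12L,4L,1L),
  c(11L,5L,6L,9L,5L,11L,12L,9L,11L),
  c(10L,9L,6L,9L,8L,6L),
  c(10L,1L,6L,6L,1L,4L,6L,4L,8L),
  c(1L,9L,2L,2L,9L,8L,2L,8L,6L),
  c(4L,8L,6L,2L,4L,6L),
  c(8L,6L,9L,9L,6L,10L,3L,2L,11L),
  c(11L,3L,2L,10L,1L,4L,10L,4L,6L,6L,4L,8L),
  c(1L,9L,3L,3L,9L,6L,6L,9L,8L,3L,6L,11L),
  c(4L,11L,3L,6L,11L,4L,8L,6L,4L),
  c(10L,9L,6L,6L,9L,8L,3L,12L,4L),
  c(6L,12L,8L,1L,12L,6L,3L,12L,1L,6L,10L,1L),
  c(3L,12L,4L,1L,9L,8L,1L,8L,2L,2L,8L,6L),
  c(8L,3L,12L,2L,3L,8L,6L,2L,8L),
  c(12L,4L,11L,11L,4L,2L,9L,8L,6L,9L,6L,10L),
  c(1L,11L,12L,2L,11L,1L,1L,12L,8L,6L,10L,1L,1L,8L,6L),
  c(1L,8L,6L,9L,8L,1L,1L,6L,11L,12L,4L,1L,1L,11L,12L),
  c(11L,8L,6L,11L,12L,8L),
  c(6L,7L,11L),
  c(4L,9L,1L,11L,6L,7L),
  c(11L,6L,7L,1L,10L,2L),
  c(9L,10L,4L,4L,10L,2L,7L,11L,6L),
  c(7L,3L,6L,3L,2L,6L),
  c(7L,3L,6L,6L,3L,2L,9L,1L,4L),
  c(10L,6L,1L,1L,6L,7L,1L,7L,3L),
  c(10L,6L,9L,9L,6L,3L,3L,6L,7L,9L,3L,4L),
  c(3L,12L,4L,6L,7L,11L),
  c(1L,3L,9L,9L,3L,12L,6L,7L,11L),
  c(12L,4L,3L,10L,2L,1L,6L,7L,11L),
  c(11L,6L,7L,12L,10L,2L,9L,10L,12L,3L,12L,2L),
  c(7L,12L,6L,6L,12L,4L,6L,4L,2L),
  c(9L,1L,12L,12L,6L,1L,6L,1L,2L,6L,7L,12L),
  c(7L,12L,6L,12L,4L,6L,6L,4L,10L,10L,4L,1L),
  c(12L,6L,7L,10L,6L,12L,9L,10L,12L),
  c(8L,5L,9L,11L,6L,7L),
  c(4L,8L,1L,1L,8L,5L,11L,6L,7L),
  c(9L,8L,5L,11L,6L,7L,2L,1L,10L),
  c(6L,7L,11L,2L,8L,5L,4L,8L,2L,10L,2L,5L),
  c(2L,6L,3L,3L,6L,7L,9L,8L,5L),
  c(6L,7L,2L,2L,7L,3L,8L,5L,1L,8L,1L,4L),
  c(5L,9L,8L,7L,1L,10L,3L,1L,7L,6L,7L,10L),
  c(10L,7L,3L,6L,7L,10L,10L,3L,4L,8L,5L,10L,10L,4L,8L),
  c(5L,9L,8L,3L,12L,4L,11L,6L,7L),
  c(11L,6L,7L,12L,8L,5L,12L,5L,3L,3L,5L,1L),
  c(5L,9L,8L,1L,10L,2L,3L,12L,4L,11L,6L,7L),
  c(8L,5L,12L,12L,5L,3L,3L,5L,10L,10L,2L,3L,11L,6L,7L),
  c(8L,5L,9L,4L,6L,7L,2L,6L,4L,12L,4L,7L),
  c(12L,5L,1L,8L,5L,12L,12L,1L,2L,6L,7L,12L,12L,2L,6L),
  c(12L,4L,7L,7L,4L,6L,6L,4L,1L,1L,10L,6L,5L,9L,8L),
  c(12L,6L,7L,10L,6L,12L,12L,8L,5L,12L,5L,10L),
  c(5L,7L,10L,7L,11L,10L),
  c(11L,10L,7L,7L,10L,5L,4L,9L,1L),
  c(11L,2L,7L,7L,2L,1L,7L,1L,5L),
  c(4L,9L,2L,2L,7L,9L,7L,9L,5L,7L,11L,2L),
  c(2L,10L,3L,3L,10L,5L,3L,5L,7L),
  c(4L,9L,1L,2L,10L,5L,2L,5L,3L,3L,5L,7L),
  c(1L,5L,7L,1L,7L,3L),
  c(5L,4L,9L,3L,4L,5L,7L,3L,5L),
  c(5L,7L,10L,10L,7L,11L,4L,3L,12L),
  c(12L,9L,1L,3L,12L,1L,7L,10L,5L,11L,10L,7L),
  c(3L,12L,4L,1L,7L,11L,5L,7L,1L,2L,1L,11L),
  c(2L,12L,9L,3L,12L,2L,2L,9L,5L,7L,11L,2L,2L,5L,7L),
  c(7L,12L,5L,5L,12L,2L,2L,12L,4L,5L,2L,10L),
  c(2L,5L,7L,10L,5L,2L,2L,7L,12L,9L,1L,2L,2L,12L,9L),
  c(1L,12L,4L,7L,12L,1L,5L,7L,1L),
  c(12L,5L,7L,12L,9L,5L),
  c(8L,7L,9L,9L,7L,11L,9L,11L,10L),
  c(8L,1L,4L,11L,8L,1L,10L,1L,11L,7L,11L,8L),
  c(2L,7L,11L,2L,8L,7L,1L,8L,2L,9L,8L,1L),
  c(2L,7L,11L,8L,7L,2L,4L,8L,2L),
  c(3L,8L,7L,10L,8L,3L,9L,8L,10L,3L,2L,10L),
  c(10L,4L,8L,1L,4L,10L,10L,8L,7L,3L,2L,10L,10L,7L,3L),
  c(7L,9L,8L,1L,9L,7L,3L,1L,7L),
  c(7L,4L,8L,7L,3L,4L),
  c(12L,4L,3L,11L,9L,8L,10L,9L,11L,7L,11L,8L),
  c(8L,11L,10L,7L,11L,8L,8L,10L,1L,3L,12L,8L,8L,1L,3L),
  c(9L,8L,1L,1L,8L,2L,2L,8L,7L,7L,11L,2L,3L,12L,4L),
  c(8L,3L,12L,2L,3L,8L,8L,7L,11L,8L,11L,2L),
  c(7L,4L,2L,12L,4L,7L,7L,2L,10L,9L,8L,7L,7L,10L,9L),
  c(12L,8L,7L,10L,1L,2L),
  c(1L,12L,4L,7L,12L,1L,1L,9L,8L,1L,8L,7L),
  c(12L,8L,7L),
  c(7L,8L,12L),
  c(4L,9L,1L,7L,8L,12L),
  c(7L,8L,12L,2L,1L,10L),
  c(2L,4L,10L,10L,4L,9L,7L,8L,12L),
  c(12L,7L,8L,2L,11L,3L),
  c(7L,8L,12L,1L,4L,9L,2L,11L,3L),
  c(10L,11L,1L,1L,11L,3L,8L,12L,7L),
  c(7L,8L,12L,3L,4L,9L,3L,9L,11L,11L,9L,10L),
  c(8L,4L,7L,4L,3L,7L),
  c(8L,9L,7L,7L,9L,1L,7L,1L,3L),
  c(8L,4L,7L,7L,4L,3L,10L,2L,1L),
  c(7L,8L,3L,3L,8L,10L,10L,8L,9L,10L,2L,3L),
  c(11L,7L,2L,2L,7L,8L,2L,8L,4L),
  c(11L,7L,2L,7L,8L,2L,2L,8L,1L,1L,8L,9L),
  c(4L,1L,8L,8L,11L,1L,11L,1L,10L,8L,11L,7L),
  c(9L,7L,8L,11L,7L,9L,10L,11L,9L),
  c(7L,5L,12L,5L,9L,12L),
  c(4L,12L,1L,1L,12L,7L,1L,7L,5L),
  c(7L,5L,12L,12L,5L,9L,2L,1L,10L),
  c(5L,12L,7L,2L,12L,5L,4L,12L,2L,10L,2L,5L),
  c(9L,12L,5L,5L,12L,7L,2L,11L,3L),
  c(2L,11L,3L,4L,12L,7L,4L,7L,1L,1L,7L,5L),
  c(1L,10L,3L,3L,10L,11L,5L,9L,12L,5L,12L,7L),
  c(4L,7L,5L,12L,7L,4L,4L,5L,10L,11L,3L,4L,4L,10L,11L),
  c(9L,4L,5L,5L,4L,3L,5L,3L,7L),
  c(7L,5L,1L,3L,7L,1L),
  c(1L,10L,2L,3L,5L,9L,7L,5L,3L,4L,3L,9L),
  c(3L,10L,2L,5L,10L,3L,7L,5L,3L),
  c(2L,9L,4L,7L,9L,2L,5L,9L,7L,2L,11L,7L),
  c(7L,2L,11L,1L,2L,7L,5L,1L,7L),
  c(4L,10L,11L,1L,10L,4L,4L,11L,7L,5L,9L,4L,4L,7L,5L),
  c(10L,7L,5L,10L,11L,7L),
  c(7L,8L,12L,10L,5L,6L),
  c(1L,4L,9L,7L,8L,12L,6L,10L,5L),
  c(1L,5L,2L,2L,5L,6L,12L,7L,8L),
  c(12L,7L,8L,9L,5L,6L,9L,6L,4L,4L,6L,2L),
  c(10L,5L,6L,12L,7L,8L,3L,2L,11L),
  c(2L,11L,3L,7L,8L,12L,4L,9L,1L,6L,10L,5L),
  c(7L,8L,12L,3L,5L,6L,1L,5L,3L,11L,3L,6L),
  c(4L,9L,3L,3L,9L,11L,11L,9L,5L,5L,6L,11L,7L,8L,12L),
  c(3L,7L,4L,4L,7L,8L,10L,5L,6L),
  c(6L,10L,5L,8L,9L,1L,8L,1L,7L,7L,1L,3L),
  c(1L,5L,6L,2L,1L,6L,4L,7L,8L,3L,7L,4L),
  c(9L,6L,2L,5L,6L,9L,9L,2L,3L,7L,8L,9L,9L,3L,7L),
  c(10L,5L,6L,11L,7L,8L,11L,8L,2L,2L,8L,4L),
  c(7L,8L,11L,11L,8L,2L,2L,8L,9L,9L,1L,2L,10L,5L,6L),
  c(11L,8L,4L,7L,8L,11L,11L,4L,1L,5L,6L,11L,11L,1L,5L),
  c(9L,7L,8L,11L,7L,9L,9L,5L,6L,9L,6L,11L),
  c(7L,6L,12L,12L,6L,10L,12L,10L,9L),
  c(6L,12L,7L,6L,4L,12L,10L,4L,6L,1L,4L,10L),
  c(12L,1L,9L,6L,12L,1L,2L,1L,6L,12L,7L,6L),
  c(6L,12L,7L,4L,12L,6L,2L,4L,6L),
  c(3L,2L,11L,7L,6L,10L,7L,10L,12L,12L,10L,9L),
  c(1L,4L,10L,10L,4L,6L,6L,4L,12L,12L,7L,6L,11L,3L,2L),
  c(6L,3L,1L,11L,3L,6L,6L,1L,9L,12L,7L,6L,6L,9L,12L),
  c(4L,11L,3L,6L,11L,4L,4L,12L,7L,4L,7L,6L),
  c(9L,6L,10L,3L,6L,9L,7L,6L,3L,4L,3L,9L),
  c(1L,6L,10L,7L,6L,1L,3L,7L,1L),
  c(9L,3L,7L,4L,3L,9L,9L,7L,6L,2L,1L,9L,9L,6L,2L),
  c(6L,3L,7L,6L,2L,3L),
  c(7L,10L,9L,6L,10L,7L,7L,9L,4L,2L,11L,7L,7L,4L,2L),
  c(7L,2L,11L,1L,2L,7L,7L,6L,10L,7L,10L,1L),
  c(1L,9L,4L,7L,6L,11L),
  c(11L,7L,6L),
  c(6L,8L,11L,8L,12L,11L),
  c(6L,8L,11L,11L,8L,12L,1L,4L,9L),
  c(12L,11L,8L,8L,11L,6L,1L,10L,2L),
  c(6L,8L,12L,11L,6L,12L,10L,4L,9L,2L,4L,10L),
  c(12L,3L,8L,8L,3L,2L,8L,2L,6L),
  c(4L,9L,1L,2L,8L,12L,6L,8L,2L,3L,2L,12L),
  c(8L,12L,6L,6L,12L,1L,1L,12L,3L,1L,10L,6L),
  c(3L,9L,10L,4L,9L,3L,3L,10L,6L,8L,12L,3L,3L,6L,8L),
  c(3L,11L,4L,4L,11L,6L,4L,6L,8L),
  c(3L,9L,1L,6L,3L,9L,8L,9L,6L,11L,6L,3L),
  c(2L,1L,10L,6L,4L,3L,8L,4L,6L,11L,6L,3L),
  c(3L,6L,8L,11L,6L,3L,3L,8L,9L,10L,2L,3L,3L,9L,10L),
  c(6L,8L,4L,6L,4L,2L),
  c(2L,9L,1L,8L,9L,2L,6L,8L,2L),
  c(6L,1L,10L,4L,1L,6L,8L,4L,6L),
  c(6L,9L,10L,6L,8L,9L),
  c(6L,5L,11L,11L,5L,9L,11L,9L,12L),
  c(1L,6L,5L,12L,6L,1L,11L,6L,12L,1L,4L,12L),
  c(2L,1L,10L,6L,5L,9L,6L,9L,11L,11L,9L,12L),
  c(5L,2L,4L,10L,2L,5L,5L,4L,12L,11L,6L,5L,5L,12L,11L),
  c(6L,5L,2L,2L,5L,12L,12L,5L,9L,2L,12L,3L),
  c(12L,2L,6L,3L,2L,12L,12L,6L,5L,1L,4L,12L,12L,5L,1L),
  c(6L,9L,12L,5L,9L,6L,6L,12L,3L,1L,10L,6L,6L,3L,1L),
  c(6L,5L,10L,4L,12L,3L),
  c(11L,4L,3L,11L,9L,4L,6L,9L,11L,5L,9L,6L),
  c(5L,11L,6L,3L,11L,5L,1L,3L,5L),
  c(5L,9L,6L,6L,9L,11L,11L,9L,4L,4L,3L,11L,2L,1L,10L),
  c(5L,11L,6L,3L,11L,5L,5L,10L,2L,5L,2L,3L),
  c(4L,5L,9L,6L,5L,4L,2L,6L,4L),
  c(2L,5L,1L,2L,6L,5L),
  c(6L,1L,10L,4L,1L,6L,6L,5L,9L,6L,9L,4L),
  c(6L,5L,10L),
  c(5L,8L,10L,10L,8L,12L,10L,12L,11L),
  c(1L,4L,9L,5L,8L,12L,5L,12L,10L,10L,12L,11L),
  c(11L,8L,12L,1L,8L,11L,5L,8L,1L,2L,1L,11L),
  c(5L,12L,11L,8L,12L,5L,5L,11L,2L,4L,9L,5L,5L,2L,4L),
  c(2L,10L,3L,10L,5L,3L,3L,5L,12L,12L,5L,8L),
  c(10L,5L,2L,2L,5L,3L,3L,5L,8L,8L,12L,3L,4L,9L,1L),
  c(3L,8L,12L,5L,8L,3L,1L,5L,3L),
  c(5L,4L,9L,3L,4L,5L,5L,8L,12L,5L,12L,3L),
  c(10L,5L,11L,11L,5L,4L,4L,5L,8L,4L,3L,11L),
  c(8L,1L,3L,9L,1L,8L,8L,3L,11L,10L,5L,8L,8L,11L,10L),
  c(11L,1L,5L,2L,1L,11L,11L,5L,8L,4L,3L,11L,11L,8L,4L),
  c(8L,9L,5L,2L,3L,11L),
  c(8L,10L,5L,2L,10L,8L,4L,2L,8L),
  c(8L,10L,5L,2L,10L,8L,8L,9L,1L,8L,1L,2L),
  c(1L,8L,4L,1L,5L,8L),
  c(8L,9L,5L),
  c(10L,9L,12L,11L,10L,12L),
  c(12L,1L,4L,10L,1L,12L,11L,10L,12L),
  c(9L,2L,1L,11L,2L,9L,12L,11L,9L),
  c(12L,2L,4L,12L,11L,2L),
  c(10L,3L,2L,12L,3L,10L,9L,12L,10L),
  c(10L,3L,2L,12L,3L,10L,10L,1L,4L,10L,4L,12L),
  c(3L,9L,12L,3L,1L,9L),
  c(3L,4L,12L),
  c(11L,4L,3L,9L,4L,11L,10L,9L,11L),
  c(1L,11L,10L,1L,3L,11L),
  c(9L,2L,1L,11L,2L,9L,9L,4L,3L,9L,3L,11L),
  c(11L,2L,3L),
  c(4L,10L,9L,4L,2L,10L),
  c(2L,10L,1L),
  c(1L,9L,4L),
  integer(0)
)
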