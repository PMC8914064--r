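disc_of <- function(levels) {
  structure(list(levels = levels), class = "rad_discretized")
}

test_that("extract_all returns 107 features with the documented family counts", {
  vm <- make_phantom(phantom_spec(lesion_kind = "textured_blob",
                                  radii = c(9, 8, 7), noise_sd = 5, seed = 11))
  fv <- extract_all(vm)
  expect_equal(ncol(fv) - 1L, 107L)
  fam <- table(sub("_.*", "", names(fv)[-1]))
  expect_equal(fam[["shape"]], 14L)
  expect_equal(fam[["firstorder"]], 18L)
  expect_equal(fam[["glcm"]], 24L)
  expect_equal(fam[["glrlm"]], 16L)
  expect_equal(fam[["glszm"]], 16L)
  expect_equal(fam[["gldm"]], 14L)
  expect_equal(fam[["ngtdm"]], 5L)
  expect_identical(names(fv)[-1], radiomics_feature_names())
  expect_true(all(is.finite(as.numeric(fv[1, -1]))))
  # bitwise determinism
  fv2 <- extract_all(vm)
  expect_identical(fv, fv2)
})

test_that("digital sphere shape features approach their analytic limits", {
  vm <- make_phantom(phantom_spec(grid_shape = c(31, 31, 31), radii = 10))
  sh <- extract_shape(vm)
  expect_equal(sh[["shape_VoxelVolume"]], sum(vm$mask))
  expect_equal(sh[["shape_MeshVolume"]], 4 / 3 * pi * 1000, tolerance = 0.03)
  # binary-mask meshes overestimate the surface area (staircase bias), so
  # sphericity sits below but near 1; it is still maximal for the sphere
  expect_gt(sh[["shape_Sphericity"]], 0.9)
  expect_lt(sh[["shape_Sphericity"]], 1.0)
  el <- extract_shape(make_phantom(phantom_spec(grid_shape = c(41, 31, 31),
                                                lesion_kind = "ellipsoid",
                                                radii = c(14, 7, 7))))
  expect_lt(el[["shape_Sphericity"]], sh[["shape_Sphericity"]])
  expect_equal(sh[["shape_Maximum3DDiameter"]], 21, tolerance = 0.03)
  expect_equal(sh[["shape_Elongation"]], 1, tolerance = 0.02)
  expect_equal(el[["shape_Elongation"]], 0.5, tolerance = 0.06)
})

test_that("shape features ignore intensity; first-order statistics shift with HU", {
  vm <- make_phantom(phantom_spec(lesion_kind = "textured_blob", radii = 8,
                                  noise_sd = 8, seed = 5))
  vm_shift <- rad_volume(vm$image + 120, vm$mask, vm$spacing)
  vm_scale <- rad_volume(vm$image * 3, vm$mask, vm$spacing)
  expect_identical(extract_shape(vm), extract_shape(vm_shift))
  expect_identical(extract_shape(vm), extract_shape(vm_scale))
  fo <- extract_firstorder(vm)
  fo_s <- extract_firstorder(vm_shift)
  for (nm in c("Mean", "Median", "Minimum", "Maximum",
               "10Percentile", "90Percentile")) {
    expect_equal(fo_s[[paste0("firstorder_", nm)]],
                 fo[[paste0("firstorder_", nm)]] + 120, tolerance = 1e-10)
  }
  expect_equal(fo_s[["firstorder_Variance"]], fo[["firstorder_Variance"]],
               tolerance = 1e-9)
})

test_that("texture families are invariant to adding a constant (min-referenced bins)", {
  vm <- make_phantom(phantom_spec(lesion_kind = "textured_blob", radii = 8,
                                  noise_sd = 10, seed = 6))
  vm_shift <- rad_volume(vm$image + 77, vm$mask, vm$spacing)
  d1 <- discretize_volume(vm, 25)
  d2 <- discretize_volume(vm_shift, 25)
  expect_identical(d1$levels, d2$levels)
  expect_identical(extract_glcm(d1), extract_glcm(d2))
  expect_identical(extract_ngtdm(d1), extract_ngtdm(d2))
})

test_that("constant ROIs yield the documented degenerate texture values", {
  img <- array(30, dim = c(4, 4, 4))
  vm <- rad_volume(img, array(TRUE, dim = c(4, 4, 4)), c(1, 1, 1))
  disc <- discretize_volume(vm, 25)
  fo <- extract_firstorder(vm, disc)
  expect_equal(fo[["firstorder_Variance"]], 0)
  expect_equal(fo[["firstorder_Entropy"]], 0)
  expect_equal(fo[["firstorder_Skewness"]], 0)
  g <- extract_glcm(disc)
  expect_equal(g[["glcm_Contrast"]], 0)
  expect_equal(g[["glcm_Correlation"]], 1)
  expect_equal(g[["glcm_JointEntropy"]], 0)
  expect_equal(g[["glcm_MCC"]], 1)
  rl <- extract_glrlm(disc)
  # single grey level: the level marginal is trivial in every direction
  expect_equal(rl[["glrlm_GrayLevelNonUniformityNormalized"]], 1)
  expect_equal(rl[["glrlm_LowGrayLevelRunEmphasis"]], 1)
  sz <- extract_glszm(disc)
  expect_equal(sz[["glszm_ZonePercentage"]], 1 / 64)
})

test_that("a two-voxel ROI with levels 1,2 gives the hand-enumerated GLCM", {
  img <- array(0, dim = c(2, 1, 1)); img[2, 1, 1] <- 25
  vm <- rad_volume(img, array(TRUE, dim = c(2, 1, 1)), c(1, 1, 1))
  disc <- discretize_volume(vm, 25)
  g <- extract_glcm(disc)
  # one offset joins the voxels: two symmetric co-occurrences of (1,2)
  expect_equal(g[["glcm_Contrast"]], 1)
  expect_equal(g[["glcm_MaximumProbability"]], 0.5)
  expect_equal(g[["glcm_JointEntropy"]], 1) # -2 * 0.5 log2 0.5
  expect_equal(g[["glcm_DifferenceAverage"]], 1)
})

test_that("a single-voxel ROI returns degenerate GLCM values with a warning", {
  img <- array(5, dim = c(3, 3, 3))
  msk <- array(FALSE, dim = c(3, 3, 3)); msk[2, 2, 2] <- TRUE
  vm <- rad_volume(img, msk, c(1, 1, 1))
  disc <- discretize_volume(vm, 25)
  expect_warning(g <- extract_glcm(disc), "degenerate")
  expect_equal(g[["glcm_Correlation"]], 1)
  expect_true(all(is.finite(g)))
})

test_that("GLCM aggregation matches a naive pair-count oracle", {
  lv <- random_level_array(c(5, 5, 3), n_levels = 4, seed = 31)
  offs <- radnmf:::tex_offsets()
  contr <- ent <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    P <- oracle_glcm_counts(lv, offs[r, ])
    if (sum(P) == 0) next
    p <- P / sum(P)
    vals <- as.numeric(rownames(P))
    ij <- outer(vals, vals, `-`)
    contr <- c(contr, sum(ij^2 * p))
    ent <- c(ent, -sum(ifelse(p > 0, p * log2(p), 0)))
  }
  g <- extract_glcm(disc_of(lv))
  expect_equal(g[["glcm_Contrast"]], mean(contr), tolerance = 1e-12)
  expect_equal(g[["glcm_JointEntropy"]], mean(ent), tolerance = 1e-12)
})

test_that("run extraction matches a naive line-walking oracle", {
  lv <- random_level_array(c(5, 4, 3), n_levels = 3, seed = 17)
  offs <- radnmf:::tex_offsets()
  for (r in seq_len(nrow(offs))) {
    mine <- radnmf:::glrlm_runs(lv, offs[r, ])
    ref <- oracle_glrlm_runs(lv, offs[r, ])
    mine <- mine[order(mine[, 1], mine[, 2]), , drop = FALSE]
    ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
    expect_equal(unname(mine), unname(ref))
  }
})

test_that("size zones are 26-connected components of equal level", {
  lv <- array(NA_integer_, dim = c(3, 3, 1))
  lv[1, 1, 1] <- 1L; lv[2, 2, 1] <- 1L  # diagonal touch: one zone of 2
  lv[3, 1, 1] <- 2L
  lv[1, 3, 1] <- 2L; lv[2, 3, 1] <- 2L  # zone of 2
  zones <- radnmf:::glszm_zones_cpp(as.vector(lv), dim(lv))
  zones <- zones[order(zones[, 1], zones[, 2]), ]
  expect_equal(unname(zones), rbind(c(1L, 2L), c(2L, 1L), c(2L, 2L)))
  sz <- extract_glszm(disc_of(lv))
  expect_equal(sz[["glszm_ZonePercentage"]], 3 / 5)
})

test_that("GLDM dependence sizes are hand-verifiable on a small line ROI", {
  # 1x3x1 ROI, levels 1,1,2 and alpha 0: voxel 1 depends on voxel 2 (j=2),
  # voxel 2 on voxel 1 (j=2), voxel 3 on nothing (j=1)
  lv <- array(c(1L, 1L, 2L), dim = c(3, 1, 1))
  g <- extract_gldm(disc_of(lv))
  # P: (i=1,j=2):2 entries; (i=2,j=1):1; Nz=3
  expect_equal(g[["gldm_LargeDependenceEmphasis"]], (2 * 4 + 1 * 1) / 3)
  expect_equal(g[["gldm_GrayLevelNonUniformity"]], (2^2 + 1^2) / 3)
  expect_equal(g[["gldm_DependenceEntropy"]],
               -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3)))
})

test_that("NGTDM features on a 3-voxel line match the closed forms", {
  lv <- array(c(1L, 2L, 3L), dim = c(3, 1, 1))
  g <- extract_ngtdm(disc_of(lv))
  expect_equal(g[["ngtdm_Coarseness"]], 1.5)
  expect_equal(g[["ngtdm_Contrast"]], (12 / 9 / 6) * (2 / 3))
  expect_equal(g[["ngtdm_Busyness"]], (2 / 3) / (8 / 3))
  expect_equal(g[["ngtdm_Complexity"]], 2)
  expect_equal(g[["ngtdm_Strength"]], 4)
})
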