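# Grey-level texture families on the discretized ROI: GLCM, GLRLM, GLSZM,
# GLDM, NGTDM. Conventions: 3D neighbourhoods at Chebyshev distance 1
# (13 unique directions for pairwise/run families, 26-connectivity for
# zone/dependence/neighbourhood families); matrices are built over the grey
# levels present in the ROI and feature weights use the actual bin numbers.
# GLCM and GLRLM features are computed per direction and averaged.

# the 13 unique direction offsets of the 3D 26-neighbourhood
tex_offsets <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- off[, 3] > 0 |
    (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  unname(off[keep, , drop = FALSE])
}

# crop the level array to the mask bounding box (texture is translation
# invariant; this only trims empty planes)
crop_levels <- function(levels) {
  idx <- which(!is.na(levels), arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  levels[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
         drop = FALSE]
}

# index ranges such that both a voxel and its `off` neighbour are in bounds
# (NULL when the offset exceeds the array extent)
offset_ranges <- function(d, off) {
  lo <- pmax(1L, 1L - off)
  hi <- pmin(d, d - off)
  if (any(hi < lo)) return(NULL)
  list(seq.int(lo[1], hi[1]), seq.int(lo[2], hi[2]), seq.int(lo[3], hi[3]))
}

# grey-level pairs (a, b) for voxels separated by `off`, both inside the ROI
offset_pairs <- function(levels, off) {
  d <- dim(levels)
  rg <- offset_ranges(d, off)
  if (is.null(rg)) return(matrix(integer(0), 0, 2))
  rx <- rg[[1]]; ry <- rg[[2]]; rz <- rg[[3]]
  a <- levels[rx, ry, rz]
  b <- levels[rx + off[1], ry + off[2], rz + off[3]]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

## ---- GLCM ------------------------------------------------------------------

glcm_features_one <- function(P, vals) {
  # P: symmetric co-occurrence counts over present levels, vals: bin numbers
  Ns <- sum(P)
  Ng <- length(vals)
  p <- P / Ns
  px <- rowSums(p)
  i <- matrix(vals, Ng, Ng)
  j <- t(i)
  mu <- sum(vals * px)
  sig2 <- sum((vals - mu)^2 * px)
  sig <- sqrt(sig2)

  dvals <- abs(i - j)
  dlev <- sort(unique(as.vector(dvals)))
  pxy_d <- vapply(dlev, function(k) sum(p[dvals == k]), numeric(1))
  svals <- i + j
  slev <- sort(unique(as.vector(svals)))
  pxy_s <- vapply(slev, function(k) sum(p[svals == k]), numeric(1))

  DA <- sum(dlev * pxy_d)
  HXY <- -sum(xlog2(p) * p)
  HX <- -sum(xlog2(px) * px)
  pxpy <- outer(px, px)
  HXY1 <- -sum(p * xlog2(pxpy))
  HXY2 <- -sum(pxpy * xlog2(pxpy))

  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))

  # maximal correlation coefficient: sqrt of the second eigenvalue of
  # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) px(k))
  if (Ng > 1) {
    Q <- (p / px) %*% (t(p) / px)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(0, ev[2]))
  } else {
    mcc <- 1
  }

  inv_var <- sum(p[dvals > 0] / dvals[dvals > 0]^2)

  c(
    glcm_Autocorrelation = sum(i * j * p),
    glcm_JointAverage = mu,
    glcm_ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    glcm_ClusterShade = sum((i + j - 2 * mu)^3 * p),
    glcm_ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    glcm_Contrast = sum((i - j)^2 * p),
    glcm_Correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1,
    glcm_DifferenceAverage = DA,
    glcm_DifferenceEntropy = -sum(xlog2(pxy_d) * pxy_d),
    glcm_DifferenceVariance = sum((dlev - DA)^2 * pxy_d),
    glcm_Id = sum(p / (1 + dvals)),
    glcm_Idm = sum(p / (1 + dvals^2)),
    glcm_Idmn = sum(p / (1 + (dvals / Ng)^2)),
    glcm_Idn = sum(p / (1 + dvals / Ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = inv_var,
    glcm_JointEnergy = sum(p^2),
    glcm_JointEntropy = HXY,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(p),
    glcm_SumAverage = sum(slev * pxy_s),
    glcm_SumEntropy = -sum(xlog2(pxy_s) * pxy_s),
    glcm_SumSquares = sig2
  )
}

glcm_degenerate <- function() {
  out <- c(
    glcm_Autocorrelation = 0, glcm_JointAverage = 0,
    glcm_ClusterProminence = 0, glcm_ClusterShade = 0,
    glcm_ClusterTendency = 0, glcm_Contrast = 0, glcm_Correlation = 1,
    glcm_DifferenceAverage = 0, glcm_DifferenceEntropy = 0,
    glcm_DifferenceVariance = 0, glcm_Id = 0, glcm_Idm = 0, glcm_Idmn = 0,
    glcm_Idn = 0, glcm_Imc1 = 0, glcm_Imc2 = 0, glcm_InverseVariance = 0,
    glcm_JointEnergy = 0, glcm_JointEntropy = 0, glcm_MCC = 1,
    glcm_MaximumProbability = 0, glcm_SumAverage = 0, glcm_SumEntropy = 0,
    glcm_SumSquares = 0
  )
  out
}

#' Grey-level co-occurrence features
#'
#' Symmetric co-occurrence matrices at distance 1 are built for each of the
#' 13 unique 3D directions; the 24 features are computed per direction and
#' averaged. A ROI with no in-mask voxel pairs (a single voxel) returns the
#' documented degenerate values (0, with Correlation and MCC 1) and emits a
#' warning.
#'
#' @param disc A `rad_discretized` from [discretize_volume()].
#' @return Named numeric vector of the 24 `glcm_*` features.
#' @export
extract_glcm <- function(disc) {
  levels <- crop_levels(disc$levels)
  lv <- sort(unique(levels[!is.na(levels)]))
  Ng <- length(lv)
  offs <- tex_offsets()
  acc <- NULL
  n_used <- 0L
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(levels, offs[r, ])
    if (nrow(pr) == 0L) next
    ai <- match(pr[, 1], lv)
    bi <- match(pr[, 2], lv)
    P <- matrix(tabulate((bi - 1L) * Ng + ai, nbins = Ng * Ng), Ng, Ng)
    P <- P + t(P)
    f <- glcm_features_one(P, lv)
    acc <- if (is.null(acc)) f else acc + f
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    warn("GLCM: no co-occurring voxel pairs in the ROI; returning degenerate values.")
    return(glcm_degenerate())
  }
  acc / n_used
}

## ---- GLRLM -----------------------------------------------------------------

# run-length triplets (level, run length, count) along one direction
glrlm_runs <- function(levels, off) {
  d <- dim(levels)
  idx <- arrayInd(seq_along(levels), d)
  ax <- which(off == 1L)
  ax <- ax[length(ax)] # an axis stepping +1 per move along the line
  s <- idx[, ax]
  key <- idx - (s - 1L) %o% as.integer(off)
  o <- order(key[, 1], key[, 2], key[, 3], s)
  v <- as.vector(levels)[o]
  newline <- c(TRUE, diff(key[o, 1]) != 0 | diff(key[o, 2]) != 0 |
                 diff(key[o, 3]) != 0)
  vv <- ifelse(is.na(v), -1L, v)
  brk <- newline | c(TRUE, vv[-1] != vv[-length(vv)])
  run_id <- cumsum(brk)
  len <- tabulate(run_id)
  first <- which(brk)
  run_lv <- vv[first]
  keep <- run_lv > 0
  cbind(level = run_lv[keep], len = len[keep])
}

glrlm_features_one <- function(iv, jv, cnt, Np) {
  Nr <- sum(cnt)
  p <- cnt / Nr
  pg <- tapply(cnt, iv, sum)
  pr <- tapply(cnt, jv, sum)
  mu_i <- sum(p * iv); mu_j <- sum(p * jv)
  c(
    glrlm_GrayLevelNonUniformity = sum(pg^2) / Nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(pg^2) / Nr^2,
    glrlm_GrayLevelVariance = sum(p * (iv - mu_i)^2),
    glrlm_HighGrayLevelRunEmphasis = sum(cnt * iv^2) / Nr,
    glrlm_LongRunEmphasis = sum(cnt * jv^2) / Nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum(cnt * iv^2 * jv^2) / Nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum(cnt * jv^2 / iv^2) / Nr,
    glrlm_LowGrayLevelRunEmphasis = sum(cnt / iv^2) / Nr,
    glrlm_RunEntropy = -sum(xlog2(p) * p),
    glrlm_RunLengthNonUniformity = sum(pr^2) / Nr,
    glrlm_RunLengthNonUniformityNormalized = sum(pr^2) / Nr^2,
    glrlm_RunPercentage = Nr / Np,
    glrlm_RunVariance = sum(p * (jv - mu_j)^2),
    glrlm_ShortRunEmphasis = sum(cnt / jv^2) / Nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum(cnt * iv^2 / jv^2) / Nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum(cnt / (iv^2 * jv^2)) / Nr
  )
}

#' Grey-level run-length features
#'
#' Runs of equal grey level are extracted along each of the 13 unique 3D
#' directions; the 16 features are computed per direction and averaged.
#'
#' @inheritParams extract_glcm
#' @return Named numeric vector of the 16 `glrlm_*` features.
#' @export
extract_glrlm <- function(disc) {
  levels <- crop_levels(disc$levels)
  Np <- sum(!is.na(levels))
  offs <- tex_offsets()
  acc <- NULL
  for (r in seq_len(nrow(offs))) {
    runs <- glrlm_runs(levels, offs[r, ])
    agg <- tapply(rep(1L, nrow(runs)),
                  list(runs[, "level"], runs[, "len"]), sum)
    tri <- which(!is.na(agg), arr.ind = TRUE)
    iv <- as.numeric(rownames(agg))[tri[, 1]]
    jv <- as.numeric(colnames(agg))[tri[, 2]]
    cnt <- agg[tri]
    f <- glrlm_features_one(iv, jv, cnt, Np)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(offs)
}

## ---- GLSZM -----------------------------------------------------------------

#' Grey-level size-zone features
#'
#' Zones are maximal 26-connected sets of voxels sharing a grey level; the
#' single size-zone matrix yields 16 features.
#'
#' @inheritParams extract_glcm
#' @return Named numeric vector of the 16 `glszm_*` features.
#' @export
extract_glszm <- function(disc) {
  levels <- crop_levels(disc$levels)
  Np <- sum(!is.na(levels))
  zones <- glszm_zones_cpp(as.vector(levels), dim(levels))
  key <- paste(zones[, 1], zones[, 2])
  agg <- tapply(rep(1L, nrow(zones)), key, sum)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  iv <- as.numeric(parts[, 1])
  jv <- as.numeric(parts[, 2])
  cnt <- as.numeric(agg)
  Nz <- sum(cnt)
  p <- cnt / Nz
  pg <- tapply(cnt, iv, sum)
  ps <- tapply(cnt, jv, sum)
  mu_i <- sum(p * iv); mu_j <- sum(p * jv)
  c(
    glszm_GrayLevelNonUniformity = sum(pg^2) / Nz,
    glszm_GrayLevelNonUniformityNormalized = sum(pg^2) / Nz^2,
    glszm_GrayLevelVariance = sum(p * (iv - mu_i)^2),
    glszm_HighGrayLevelZoneEmphasis = sum(cnt * iv^2) / Nz,
    glszm_LargeAreaEmphasis = sum(cnt * jv^2) / Nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum(cnt * iv^2 * jv^2) / Nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum(cnt * jv^2 / iv^2) / Nz,
    glszm_LowGrayLevelZoneEmphasis = sum(cnt / iv^2) / Nz,
    glszm_SizeZoneNonUniformity = sum(ps^2) / Nz,
    glszm_SizeZoneNonUniformityNormalized = sum(ps^2) / Nz^2,
    glszm_SmallAreaEmphasis = sum(cnt / jv^2) / Nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum(cnt * iv^2 / jv^2) / Nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum(cnt / (iv^2 * jv^2)) / Nz,
    glszm_ZoneEntropy = -sum(xlog2(p) * p),
    glszm_ZonePercentage = Nz / Np,
    glszm_ZoneVariance = sum(p * (jv - mu_j)^2)
  )
}

## ---- GLDM ------------------------------------------------------------------

#' Grey-level dependence features
#'
#' For every ROI voxel the dependence size is one plus the number of
#' 26-neighbours inside the ROI whose grey level differs by at most `alpha`
#' from the centre. The dependence matrix yields 14 features.
#'
#' @inheritParams extract_glcm
#' @param alpha Dependence tolerance on the grey-level difference (default 0).
#' @return Named numeric vector of the 14 `gldm_*` features.
#' @export
extract_gldm <- function(disc, alpha = 0) {
  levels <- crop_levels(disc$levels)
  d <- dim(levels)
  offs <- tex_offsets()
  offs <- rbind(offs, -offs)
  dep <- array(0L, dim = d)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    rg <- offset_ranges(d, off)
    if (is.null(rg)) next
    rx <- rg[[1]]; ry <- rg[[2]]; rz <- rg[[3]]
    a <- levels[rx, ry, rz]
    b <- levels[rx + off[1], ry + off[2], rz + off[3]]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    sub <- array(0L, dim = d)
    sub[rx, ry, rz] <- hit
    dep <- dep + sub
  }
  inroi <- !is.na(levels)
  iv_all <- levels[inroi]
  jv_all <- dep[inroi] + 1L
  key <- paste(iv_all, jv_all)
  agg <- tapply(rep(1L, length(key)), key, sum)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  iv <- as.numeric(parts[, 1]); jv <- as.numeric(parts[, 2])
  cnt <- as.numeric(agg)
  Nz <- sum(cnt)
  p <- cnt / Nz
  pg <- tapply(cnt, iv, sum)
  pd <- tapply(cnt, jv, sum)
  mu_i <- sum(p * iv); mu_j <- sum(p * jv)
  c(
    gldm_DependenceEntropy = -sum(xlog2(p) * p),
    gldm_DependenceNonUniformity = sum(pd^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    gldm_DependenceVariance = sum(p * (jv - mu_j)^2),
    gldm_GrayLevelNonUniformity = sum(pg^2) / Nz,
    gldm_GrayLevelVariance = sum(p * (iv - mu_i)^2),
    gldm_HighGrayLevelEmphasis = sum(cnt * iv^2) / Nz,
    gldm_LargeDependenceEmphasis = sum(cnt * jv^2) / Nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(cnt * iv^2 * jv^2) / Nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(cnt * jv^2 / iv^2) / Nz,
    gldm_LowGrayLevelEmphasis = sum(cnt / iv^2) / Nz,
    gldm_SmallDependenceEmphasis = sum(cnt / jv^2) / Nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(cnt * iv^2 / jv^2) / Nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(cnt / (iv^2 * jv^2)) / Nz
  )
}

## ---- NGTDM -----------------------------------------------------------------

#' Neighbourhood grey-tone difference features
#'
#' Each ROI voxel with at least one in-ROI 26-neighbour contributes the
#' absolute difference between its grey level and the mean level of those
#' neighbours. Coarseness is capped at 1e6 when its denominator vanishes
#' (a constant ROI).
#'
#' @inheritParams extract_glcm
#' @return Named numeric vector of the 5 `ngtdm_*` features.
#' @export
extract_ngtdm <- function(disc) {
  levels <- crop_levels(disc$levels)
  d <- dim(levels)
  offs <- tex_offsets()
  offs <- rbind(offs, -offs)
  nsum <- array(0, dim = d)
  ncnt <- array(0L, dim = d)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    rg <- offset_ranges(d, off)
    if (is.null(rg)) next
    rx <- rg[[1]]; ry <- rg[[2]]; rz <- rg[[3]]
    b <- levels[rx + off[1], ry + off[2], rz + off[3]]
    ok <- !is.na(b)
    subs <- array(0, dim = d); subc <- array(0L, dim = d)
    subs[rx, ry, rz] <- ifelse(ok, b, 0)
    subc[rx, ry, rz] <- ok
    nsum <- nsum + subs
    ncnt <- ncnt + subc
  }
  use <- !is.na(levels) & ncnt > 0L
  if (!any(use)) {
    warn("NGTDM: no voxel has an in-ROI neighbour; returning degenerate values.")
    return(c(ngtdm_Busyness = 0, ngtdm_Coarseness = 1e6, ngtdm_Complexity = 0,
             ngtdm_Contrast = 0, ngtdm_Strength = 0))
  }
  lv_use <- levels[use]
  diffv <- abs(lv_use - nsum[use] / ncnt[use])
  s_by <- tapply(diffv, lv_use, sum)
  n_by <- tapply(rep(1L, length(lv_use)), lv_use, sum)
  ivals <- as.numeric(names(s_by))
  Np <- sum(n_by)
  p <- as.numeric(n_by) / Np
  s <- as.numeric(s_by)
  Ngp <- length(ivals)

  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else 1e6
  contrast <- if (Ngp > 1) {
    (sum(outer(p, p) * outer(ivals, ivals, `-`)^2) / (Ngp * (Ngp - 1))) *
      (sum(s) / Np)
  } else 0
  ipi <- ivals * p
  denom_busy <- sum(abs(outer(ipi, ipi, `-`)))
  busy <- if (denom_busy > 0) ps / denom_busy else 0
  cplx <- sum(abs(outer(ivals, ivals, `-`)) *
                outer(p * s, p * s, `+`) / outer(p, p, `+`)) / Np
  strength <- if (sum(s) > 0) {
    sum(outer(p, p, `+`) * outer(ivals, ivals, `-`)^2) / sum(s)
  } else 0
  c(ngtdm_Busyness = busy, ngtdm_Coarseness = min(coarse, 1e6),
    ngtdm_Complexity = cplx, ngtdm_Contrast = contrast,
    ngtdm_Strength = strength)
}
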