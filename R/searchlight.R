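# Searchlight RSA: per-voxel neural RDMs in spherical neighborhoods and
# their Fisher-z partial Spearman correlation with each behavioral RDM,
# controlling the other two.

#' Low-variation voxel filter
#'
#' Discards voxels whose response variation across trials is less than a
#' fraction of the mean response magnitude, emulating the exclusion of
#' voxels with flat signals. "Variation" is read as the across-trial
#' standard deviation of the beta values, the magnitude as the absolute
#' across-trial mean; the default fraction is 1/8.
#'
#' @param beta a [beta_set()].
#' @param fraction positive threshold fraction (default `1/8`).
#' @return 3D logical mask: input mask voxels with
#'   `sd >= fraction * |mean|`.
#' @export
variation_filter <- function(beta, fraction = 1 / 8) {
  stopifnot(fraction > 0)
  d <- dim(beta$data)
  X <- matrix(beta$data, prod(d[1:3]), d[4L])
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (d[4L] - 1L))
  keep <- array(s >= fraction * abs(m), d[1:3]) & beta$mask
  if (!any(keep)) {
    stop("variation_filter: every voxel discarded at fraction ", fraction)
  }
  keep
}

#' Integer voxel offsets within a sphere
#'
#' All integer grid offsets whose centre-to-centre Euclidean distance in
#' mm is at most `radius_mm` (boundary inclusive). On a 2-mm isotropic
#' grid with a 6-mm radius these are exactly the lattice offsets with
#' `i^2 + j^2 + k^2 <= 9`.
#'
#' @param radius_mm sphere radius in mm (> 0).
#' @param voxel_mm voxel size per axis (scalar or length-3).
#' @return Integer matrix, one offset per row, the zero offset included.
#' @export
sphere_offsets <- function(radius_mm, voxel_mm) {
  stopifnot(radius_mm > 0)
  voxel_mm <- rep_len(voxel_mm, 3L)
  r <- floor(radius_mm / voxel_mm)
  off <- as.matrix(expand.grid(i = -r[1]:r[1], j = -r[2]:r[2],
                               k = -r[3]:r[3]))
  d2 <- (off[, 1] * voxel_mm[1])^2 + (off[, 2] * voxel_mm[2])^2 +
    (off[, 3] * voxel_mm[3])^2
  off[d2 <= radius_mm^2, , drop = FALSE]
}

#' In-mask voxels of one searchlight sphere
#'
#' @param center integer voxel coordinate (1-based, length 3).
#' @param radius_mm sphere radius in mm.
#' @param affine 4x4 voxel-to-mm map (voxel sizes taken from its columns).
#' @param mask 3D logical mask.
#' @return Integer matrix of in-mask voxel coordinates within the sphere,
#'   centre included.
#' @export
sphere_indices <- function(center, radius_mm, affine, mask) {
  stopifnot(length(center) == 3L, mask[matrix(center, 1L)])
  voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  off <- sphere_offsets(radius_mm, voxel_mm)
  pts <- sweep(off, 2L, as.integer(center), "+")
  g <- dim(mask)
  ok <- pts[, 1] >= 1L & pts[, 1] <= g[1] &
    pts[, 2] >= 1L & pts[, 2] <= g[2] &
    pts[, 3] >= 1L & pts[, 3] <= g[3]
  pts <- pts[ok, , drop = FALSE]
  pts[mask[pts], , drop = FALSE]
}

#' Neural RDM from a local pattern matrix
#'
#' Pairwise dissimilarity between trial patterns: one minus Spearman's
#' rho between the response patterns of any two stimuli across the
#' voxels of one searchlight sphere.
#'
#' @param patterns numeric matrix voxels x trials (>= 2 voxels).
#' @param item_ids optional trial ids.
#' @param condition condition label carried on the result.
#' @return An [rdm()] with `component = "neural"`, entries in `[0, 2]`.
#'   A constant pattern makes the affected entries `NA` with a warning.
#' @export
neural_rdm <- function(patterns, item_ids = NULL, condition = NA_character_) {
  stopifnot(is.matrix(patterns), nrow(patterns) >= 2L, ncol(patterns) >= 3L)
  const <- apply(patterns, 2L, stats::sd) == 0
  rho <- suppressWarnings(stats::cor(patterns, method = "spearman"))
  if (any(const)) {
    warning("neural_rdm: ", sum(const), " constant pattern(s); ",
            "their dissimilarities are undefined")
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  v <- 1 - rho
  diag(v) <- 0
  rdm(v, item_ids = item_ids, component = "neural", condition = condition)
}

#' Fisher r-to-z transform
#'
#' `atanh(r)`, applied to correlation coefficients to improve normality
#' before across-subject t-tests. Values at or beyond +/-1 are clamped to
#' `+/-(1 - 1e-7)` with a warning.
#'
#' @param r correlation value(s).
#' @return Transformed value(s), same shape as `r`.
#' @export
fisher_z <- function(r) {
  out_of_range <- is.finite(r) & abs(r) >= 1
  if (any(out_of_range)) {
    warning("fisher_z: |r| >= 1 clamped to 1 - 1e-7")
    r[out_of_range] <- sign(r[out_of_range]) * (1 - 1e-7)
  }
  atanh(r)
}

# residual-regression partial correlation of ranked vectors; returns
# c(rho, p_one_tailed). Q is the qr of cbind(1, ranked controls).
partial_from_qr <- function(rx, ry, Q, n_controls) {
  ex <- qr.resid(Q, rx)
  ey <- qr.resid(Q, ry)
  sx <- sqrt(sum(ex^2)); sy <- sqrt(sum(ey^2))
  # degenerate neural vector: undefined; target fully explained by the
  # controls: partial correlation is zero by convention
  if (sx <= 1e-8 * sqrt(sum((rx - mean(rx))^2))) {
    return(c(NA_real_, NA_real_))
  }
  if (sy <= 1e-8 * sqrt(sum((ry - mean(ry))^2))) {
    return(c(0, 0.5))
  }
  rho <- sum(ex * ey) / (sx * sy)
  df <- length(rx) - 2L - n_controls
  tt <- rho * sqrt(df / max(1 - rho^2, 1e-12))
  c(rho, stats::pt(tt, df, lower.tail = FALSE))
}

qr_controls <- function(controls_ranked) {
  X <- cbind(1, controls_ranked)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    stop("partial_spearman: control RDMs are collinear ",
         "(singular control correlation structure)")
  }
  q
}

#' Partial Spearman correlation between RDMs
#'
#' Correlation between the lower-triangle vectors of a neural RDM and one
#' target behavioral RDM, with the other behavioral RDMs partialled out:
#' each vector is rank-transformed (average ranks on ties) and the
#' partial Pearson correlation of the ranked neural and target vectors
#' given the ranked controls is computed by residual regression. The
#' one-tailed p (positive correlation) comes from the t approximation
#' with `df = m - 2 - k` over the `m = n(n-1)/2` pairs, or from a
#' permutation null (joint row/column shuffles of the neural RDM) when
#' `perm > 0`.
#'
#' @param neural,target [rdm()]s with identical item order.
#' @param controls list of control [rdm()]s (possibly empty).
#' @param perm number of permutations for a permutation p-value
#'   (0 = parametric t approximation).
#' @param seed seed for the permutation draws.
#' @return List with `rho` and one-tailed `p`.
#' @export
partial_spearman <- function(neural, target, controls = list(), perm = 0L,
                             seed = 1L) {
  n <- nrow(neural)
  sizes <- vapply(c(list(target), controls), nrow, 0L)
  if (any(sizes != n)) stop("partial_spearman: RDM sizes differ")
  rx <- rank(rdm_vec(neural))
  ry <- rank(rdm_vec(target))
  ctrl <- if (length(controls) > 0L) {
    vapply(controls, function(cc) rank(rdm_vec(cc)), numeric(length(rx)))
  } else {
    matrix(0, length(rx), 0L)
  }
  Q <- qr_controls(ctrl)
  res <- partial_from_qr(rx, ry, Q, ncol(ctrl))
  rho <- res[1L]; p <- res[2L]
  if (perm > 0L) {
    nm <- unclass(as.matrix(neural))
    null <- with_seed(seed, vapply(seq_len(perm), function(i) {
      pm <- sample(n)
      partial_from_qr(rank(nm[pm, pm][lower.tri(nm)]), ry, Q, ncol(ctrl))[1L]
    }, 0))
    p <- (1 + sum(null >= rho)) / (1 + perm)
  }
  list(rho = rho, p = p)
}

#' Whole-volume searchlight maps for one subject and condition
#'
#' For every retained voxel (input mask intersected with the
#' [variation_filter()]), extracts the trial patterns of the 6-mm sphere
#' around it, forms the neural RDM for the requested condition, and
#' correlates it with each of the three behavioral RDMs controlling the
#' other two (partial Spearman, Fisher r-to-z). Subject-level
#' significance masks keep voxels with one-tailed `p < alpha` in
#' connected clusters larger than `cluster_min`.
#'
#' @param beta a [beta_set()].
#' @param behavioral named list of the three behavioral [rdm()]s for the
#'   condition (`logo`, `phonology`, `semantics`), items ordered as in
#'   the RDMs.
#' @param condition condition label to analyse.
#' @param radius_mm searchlight radius (default 6 mm).
#' @param alpha subject-level voxel threshold (default 0.05).
#' @param cluster_min minimum cluster extent, strictly exceeded
#'   (default 10).
#' @param min_voxels spheres with fewer in-mask voxels are skipped
#'   (map value `NaN`).
#' @param fraction variation-filter fraction.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param centers optional logical 3D array restricting where searchlight
#'   statistics are computed (patterns are still drawn from the full
#'   retained mask); default everywhere.
#' @return Named list of three `rep_map` objects (one per component),
#'   each with 3D `z`, `p`, `sig` and the subject/condition/component
#'   labels.
#' @export
searchlight_map <- function(beta, behavioral, condition, radius_mm = 6,
                            alpha = 0.05, cluster_min = 10L,
                            min_voxels = 10L, fraction = 1 / 8,
                            connectivity = 18L, centers = NULL) {
  stopifnot(all(components() %in% names(behavioral)))
  tt <- beta$trial_table
  if (!condition %in% tt$condition) {
    stop("searchlight_map: condition '", condition,
         "' absent from trial table")
  }
  retained <- variation_filter(beta, fraction)
  g <- dim(retained)
  item_order <- rownames(behavioral$logo)
  trials <- which(tt$condition == condition)
  trials <- trials[match(item_order, tt$item_id[trials])]
  if (any(is.na(trials))) {
    stop("searchlight_map: trial table does not cover the RDM's items")
  }
  n <- length(trials)
  m <- n * (n - 1L) / 2L

  # pattern matrix over retained voxels
  X <- matrix(beta$data, prod(g), dim(beta$data)[4L])[, trials, drop = FALSE]
  vox_row <- array(0L, g)
  keep_idx <- which(retained)
  vox_row[keep_idx] <- seq_along(keep_idx)
  P <- X[keep_idx, , drop = FALSE]

  # ranked behavioral vectors and per-component control projections
  ranked <- lapply(behavioral[components()],
                   function(r) rank(rdm_vec(r)))
  Qs <- lapply(components(), function(comp) {
    qr_controls(vapply(ranked[setdiff(components(), comp)], identity,
                       numeric(m)))
  })
  names(Qs) <- components()

  voxel_mm <- sqrt(colSums(beta$affine[1:3, 1:3]^2))
  off <- sphere_offsets(radius_mm, voxel_mm)

  centers_idx <- if (is.null(centers)) keep_idx else
    which(retained & centers)
  coords <- arrayInd(centers_idx, g)
  zs <- matrix(NaN, length(centers_idx), 3L)
  ps <- matrix(NaN, length(centers_idx), 3L)
  n_skipped <- 0L
  lt <- lower.tri(matrix(0, n, n))
  for (v in seq_along(centers_idx)) {
    pts <- sweep(off, 2L, coords[v, ], "+")
    ok <- pts[, 1] >= 1L & pts[, 1] <= g[1] &
      pts[, 2] >= 1L & pts[, 2] <= g[2] &
      pts[, 3] >= 1L & pts[, 3] <= g[3]
    rows <- vox_row[pts[ok, , drop = FALSE]]
    rows <- rows[rows > 0L]
    if (length(rows) < min_voxels) {
      n_skipped <- n_skipped + 1L
      next
    }
    sphere <- P[rows, , drop = FALSE]
    rho_nn <- suppressWarnings(stats::cor(sphere, method = "spearman"))
    nv <- 1 - rho_nn[lt]
    if (anyNA(nv)) next
    rx <- rank(nv)
    for (ci in 1:3) {
      comp <- components()[ci]
      res <- partial_from_qr(rx, ranked[[comp]], Qs[[comp]], 2L)
      zs[v, ci] <- fisher_z(res[1L])
      ps[v, ci] <- res[2L]
    }
  }
  if (n_skipped > 0L) {
    message("searchlight_map: ", n_skipped, " voxel(s) skipped ",
            "(sphere smaller than ", min_voxels, " in-mask voxels)")
  }
  out <- lapply(1:3, function(ci) {
    z <- array(NaN, g); p <- array(NaN, g)
    z[centers_idx] <- zs[, ci]
    p[centers_idx] <- ps[, ci]
    sig <- threshold_clusters(p, alpha, cluster_min, connectivity)
    structure(list(z = z, p = p, sig = sig, subject = beta$subject,
                   condition = condition, component = components()[ci],
                   affine = beta$affine, mask = retained),
              class = "rep_map")
  })
  setNames(out, components())
}

#' Searchlight maps for all subjects and conditions
#'
#' Runs [searchlight_map()] over every subject of a dataset and every
#' condition, against the dataset's behavioral RDMs.
#'
#' @param ds a `synthetic_dataset` (or any list with `beta` and `rdms`).
#' @param ... passed to [searchlight_map()].
#' @return Nested list `maps[[subject]][[condition]][[component]]`.
#' @export
searchlight_all <- function(ds, ...) {
  lapply(ds$beta, function(bs) {
    setNames(lapply(conditions(), function(cond) {
      searchlight_map(bs, ds$rdms[[cond]], cond, ...)
    }), conditions())
  })
}
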