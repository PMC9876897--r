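# Group-level inference: one-sample t maps across subjects,
# cluster-extent thresholding, cognitive load, cross-language overlap,
# subsample stability and group-extent permutation testing.

connectivity_offsets <- function(connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  off <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  s <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1L, "18" = s >= 1L & s <= 2L, "26" = s >= 1L)
  off[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary mask
#'
#' Union-find connected-component labeling under face (6), face+edge (18)
#' or full (26) neighbor connectivity. Labels are assigned in order of
#' each component's smallest linear index.
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 outside the mask,
#'   components numbered from 1.
#' @export
label_clusters <- function(mask, connectivity = 18L) {
  g <- dim(mask)
  stopifnot(length(g) == 3L)
  idx <- which(mask)
  labels <- array(0L, g)
  n <- length(idx)
  if (n == 0L) return(labels)
  row_of <- array(0L, g)
  row_of[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]; parent[i] <<- root; i <- nxt
    }
    root
  }
  coords <- arrayInd(idx, g)
  off <- connectivity_offsets(connectivity)
  # half neighborhood suffices: unions are symmetric
  off <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, , drop = FALSE]
  for (oi in seq_len(nrow(off))) {
    pts <- sweep(coords, 2L, off[oi, ], "+")
    ok <- pts[, 1] >= 1L & pts[, 1] <= g[1] &
      pts[, 2] >= 1L & pts[, 2] <= g[2] &
      pts[, 3] >= 1L & pts[, 3] <= g[3]
    nb <- integer(n)
    nb[ok] <- row_of[pts[ok, , drop = FALSE]]
    for (v in which(nb > 0L)) {
      ra <- find(v); rb <- find(nb[v])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  labels[idx] <- match(roots, sort(unique(roots)))
  labels
}

#' Cluster-extent threshold of a p map
#'
#' Retains suprathreshold voxels (`p < alpha`) that belong to connected
#' components strictly larger than `cluster_min` voxels (the ">10 voxels"
#' convention, applied identically at subject and group level).
#'
#' @param p_map 3D array of p-values (`NaN`/`NA` treated as
#'   non-significant).
#' @param alpha voxel threshold in (0, 1).
#' @param cluster_min minimum extent, strictly exceeded.
#' @param connectivity 6, 18 or 26 (default 18).
#' @return 3D logical significance mask (possibly empty).
#' @export
threshold_clusters <- function(p_map, alpha, cluster_min = 10L,
                               connectivity = 18L) {
  stopifnot(alpha > 0, alpha <= 1, cluster_min >= 0)
  supra <- !is.na(p_map) & p_map < alpha
  if (cluster_min == 0L) return(supra)
  lab <- label_clusters(supra, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  array(lab > 0L & sizes[pmax(lab, 1L)] > cluster_min, dim(p_map))
}

#' Voxel-wise one-sample t map across subjects
#'
#' One-tailed one-sample t-test for positive mean at every voxel with at
#' least `n_min` subjects contributing a finite value. A zero
#' across-subject SD yields a `+/-Inf` t sentinel (p = 0 for positive
#' mean, 1 for negative).
#'
#' @param z_maps list of 3D subject maps (Fisher-z), same shape.
#' @param n_min minimum subjects per voxel (default 3).
#' @param alpha,cluster_min,connectivity cluster-extent threshold applied
#'   to the p map.
#' @return List of class `"group_map"`: 3D `t`, `p`, `sig`, `n` (subjects
#'   per voxel) and `n_subjects`.
#' @export
one_sample_t_map <- function(z_maps, n_min = 3L, alpha = 0.05,
                             cluster_min = 10L, connectivity = 18L) {
  stopifnot(length(z_maps) >= 1L)
  g <- dim(z_maps[[1L]])
  Z <- vapply(z_maps, as.vector, numeric(prod(g)))
  fin <- is.finite(Z)
  nv <- rowSums(fin)
  Zf <- ifelse(fin, Z, 0)
  mu <- rowSums(Zf) / pmax(nv, 1L)
  ss <- rowSums((Zf - mu * fin)^2 * fin)
  sdv <- sqrt(ss / pmax(nv - 1L, 1L))
  tv <- rep(NaN, length(mu))
  pv <- rep(NaN, length(mu))
  ok <- nv >= n_min
  zero_sd <- ok & sdv == 0
  reg <- ok & sdv > 0
  tv[reg] <- mu[reg] / (sdv[reg] / sqrt(nv[reg]))
  pv[reg] <- stats::pt(tv[reg], nv[reg] - 1L, lower.tail = FALSE)
  if (any(zero_sd)) {
    tv[zero_sd] <- ifelse(mu[zero_sd] > 0, Inf,
                          ifelse(mu[zero_sd] < 0, -Inf, 0))
    pv[zero_sd] <- ifelse(mu[zero_sd] > 0, 0,
                          ifelse(mu[zero_sd] < 0, 1, 0.5))
    message("one_sample_t_map: ", sum(zero_sd),
            " voxel(s) with zero across-subject SD")
  }
  p_map <- array(pv, g)
  structure(list(t = array(tv, g), p = p_map,
                 sig = threshold_clusters(p_map, alpha, cluster_min,
                                          connectivity),
                 n = array(as.integer(nv), g),
                 n_subjects = length(z_maps)),
            class = "group_map")
}

#' Cognitive load of one representation map
#'
#' The cognitive load is the sum of Fisher-z values over the voxels whose
#' neural RDM correlates significantly positively with the behavioral
#' RDM; the voxel count is returned alongside as the validation variant.
#'
#' @param z_map 3D Fisher-z map.
#' @param sig_mask 3D logical significance mask (subset of the map's
#'   finite support).
#' @return List `load` (sum of z, 0 for an empty mask) and
#'   `n_sig_voxels`.
#' @export
cognitive_load <- function(z_map, sig_mask) {
  z <- z_map[sig_mask]
  if (anyNA(z) || any(!is.finite(z))) {
    stop("cognitive_load: non-finite z inside the significance mask")
  }
  list(load = sum(z), n_sig_voxels = sum(sig_mask))
}

#' Long-format table of subject-level cognitive loads
#'
#' @param maps nested subject maps from [searchlight_all()].
#' @param behavior optional behavior table supplying `aoa_group`.
#' @return Data frame `subject`, `condition`, `component`, `load`,
#'   `n_sig_voxels` (+ `aoa_group` when available).
#' @export
load_table <- function(maps, behavior = NULL) {
  rows <- do.call(rbind, lapply(names(maps), function(s) {
    do.call(rbind, lapply(conditions(), function(cond) {
      do.call(rbind, lapply(components(), function(comp) {
        rm_ <- maps[[s]][[cond]][[comp]]
        # positive-significance contract: load sums only positive z
        sig <- rm_$sig & is.finite(rm_$z)
        cl <- cognitive_load(rm_$z, sig)
        data.frame(subject = s, condition = cond, component = comp,
                   load = cl$load, n_sig_voxels = cl$n_sig_voxels)
      }))
    }))
  }))
  if (!is.null(behavior) && "aoa_group" %in% names(behavior)) {
    key <- unique(behavior[, c("subject", "aoa_group")])
    rows$aoa_group <- key$aoa_group[match(rows$subject, key$subject)]
  }
  rownames(rows) <- NULL
  rows
}

#' Overlap of two significance masks with per-region counts
#'
#' Voxel-wise intersection of two significance masks (e.g. the same
#' component in two languages), summarised per atlas region, with the
#' peak coordinate of each overlap cluster in mm.
#'
#' @param sig_a,sig_b 3D logical masks on the same grid.
#' @param atlas 3D integer label volume.
#' @param labels optional label table (`index`, `name`).
#' @param affine 4x4 voxel-to-mm map for peak coordinates.
#' @param stat_map optional 3D map whose maximum defines each cluster's
#'   peak (defaults to the first voxel).
#' @param connectivity cluster connectivity.
#' @return List: `mask` (the intersection), `roi_counts` data frame, and
#'   `peaks` data frame (cluster, size, peak mm coordinates).
#' @export
overlap_map <- function(sig_a, sig_b, atlas, labels = NULL,
                        affine = diag(4), stat_map = NULL,
                        connectivity = 18L) {
  if (!all(dim(sig_a) == dim(sig_b)) || !all(dim(sig_a) == dim(atlas))) {
    stop("overlap_map: grids do not match")
  }
  ov <- sig_a & sig_b
  idx <- sort(unique(as.integer(atlas[atlas > 0L])))
  counts <- vapply(idx, function(k) sum(ov & atlas == k), 0L)
  roi <- data.frame(index = idx, n_voxels = counts)
  if (!is.null(labels)) {
    roi$name <- labels$name[match(roi$index, labels$index)]
  }
  lab <- label_clusters(ov, connectivity)
  peaks <- NULL
  if (any(lab > 0L)) {
    peaks <- do.call(rbind, lapply(seq_len(max(lab)), function(k) {
      vox <- which(lab == k)
      pick <- if (is.null(stat_map)) vox[1L] else
        vox[which.max(stat_map[vox])]
      ijk <- arrayInd(pick, dim(ov))
      mm <- affine %*% c(ijk - 1L, 1)
      data.frame(cluster = k, size = length(vox),
                 x_mm = mm[1L], y_mm = mm[2L], z_mm = mm[3L])
    }))
  }
  list(mask = ov, roi_counts = roi, peaks = peaks)
}

#' Stability of group loads under subject subsampling
#'
#' Repeatedly draws subject subsamples, recomputes the group-mean load
#' per (condition, component) cell, and correlates the 9-cell vector with
#' the full-sample one — the replicability check for the load profile.
#'
#' @param loads a [load_table()].
#' @param sizes subsample sizes (each >= 3, <= number of subjects).
#' @param n_rep replicates per size.
#' @param seed RNG seed.
#' @return Data frame `size`, `replicate`, `correlation`.
#' @export
subsample_stability <- function(loads, sizes, n_rep = 100L, seed = 1L) {
  subjects <- unique(loads$subject)
  if (any(sizes < 3L)) stop("subsample_stability: sizes must be >= 3")
  if (any(sizes > length(subjects))) {
    stop("subsample_stability: size exceeds number of subjects")
  }
  cell_means <- function(sub) {
    d <- loads[loads$subject %in% sub, ]
    ag <- stats::aggregate(load ~ condition + component, d, mean)
    ag <- ag[order(ag$condition, ag$component), ]
    ag$load
  }
  full <- cell_means(subjects)
  with_seed(seed, {
    do.call(rbind, lapply(sizes, function(sz) {
      data.frame(size = sz, replicate = seq_len(n_rep),
                 correlation = vapply(seq_len(n_rep), function(r) {
                   stats::cor(cell_means(sample(subjects, sz)), full)
                 }, 0))
    }))
  })
}

group_extent <- function(z_maps, alpha, cluster_min, connectivity) {
  gm <- one_sample_t_map(z_maps, alpha = alpha, cluster_min = cluster_min,
                         connectivity = connectivity)
  sum(gm$sig)
}

#' Permutation test of group-level map extent between two groups
#'
#' Compares the extent (significant-voxel count) of the two groups'
#' group-level maps, each computed from its own subjects' z maps. The
#' null distribution comes from shuffling group labels; the one-tailed p
#' is `(1 + #{null >= observed}) / (1 + n_perm)`. The choice of
#' extent difference as the statistic is an assumption and is recorded
#' on the result.
#'
#' @param z_maps_g1,z_maps_g2 lists of subject z maps for the two groups.
#' @param n_perm permutations (warns below 100).
#' @param alpha,cluster_min,connectivity group-map thresholding.
#' @param seed RNG seed.
#' @return List: `p`, `observed` (extent g2 minus extent g1), `extents`,
#'   `statistic` description.
#' @export
permutation_extent_test <- function(z_maps_g1, z_maps_g2, n_perm = 1000L,
                                    alpha = 0.05, cluster_min = 10L,
                                    connectivity = 18L, seed = 1L) {
  if (length(z_maps_g1) == 0L || length(z_maps_g2) == 0L) {
    stop("permutation_extent_test: both groups must be non-empty")
  }
  if (n_perm < 100L) {
    warning("permutation_extent_test: n_perm < 100 gives a coarse p-value")
  }
  n1 <- length(z_maps_g1)
  all_maps <- c(z_maps_g1, z_maps_g2)
  ext <- function(sel) {
    c(group_extent(all_maps[sel], alpha, cluster_min, connectivity),
      group_extent(all_maps[-sel], alpha, cluster_min, connectivity))
  }
  obs_ext <- ext(seq_len(n1))
  observed <- obs_ext[2L] - obs_ext[1L]
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sel <- sample(length(all_maps), n1)
    e <- ext(sel)
    e[2L] - e[1L]
  }, 0))
  list(p = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed,
       extents = c(group1 = obs_ext[1L], group2 = obs_ext[2L]),
       statistic = "difference in group-map significant-voxel extent (group2 - group1); assumed statistic")
}
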