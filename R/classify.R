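# Language-type classification from (region, component) load features:
# leave-one-subject-out support vector regression with fold-specific
# group masks, and absence-rMSE recursive feature elimination.

label_codes <- function() {
  c(chinese_word = 1, english_word = 2, chinese_pinyin = 3)
}

#' Build (region, component) load features from representation maps
#'
#' For each linguistic component a group-level significance mask is
#' computed from the *training* subjects only (one-sample t over their
#' z maps pooled across conditions, cluster-extent thresholded). Each
#' sample — one condition of one subject — then gets one feature per
#' (region, component): the sum of that subject's z values inside the
#' region intersected with the component's group mask. The held-out
#' subject's features use the same training-derived mask, so no
#' information leaks from test to train.
#'
#' @param maps nested subject maps from [searchlight_all()].
#' @param atlas 3D integer region labels.
#' @param train_subjects subjects whose maps define the group masks
#'   (default: all).
#' @param alpha,cluster_min,connectivity group-mask thresholding.
#' @return List of class `"feature_matrix"`: `X` (samples x features),
#'   `y` (labels 1/2/3), `subject`, `condition`, `feature_names`,
#'   `masks` (per-component group masks).
#' @export
build_features <- function(maps, atlas, train_subjects = names(maps),
                           alpha = 0.05, cluster_min = 10L,
                           connectivity = 18L) {
  stopifnot(length(train_subjects) >= 3L,
            all(train_subjects %in% names(maps)))
  regions <- sort(unique(as.integer(atlas[atlas > 0L])))
  masks <- setNames(lapply(components(), function(comp) {
    zs <- unlist(lapply(train_subjects, function(s) {
      lapply(conditions(), function(cond) maps[[s]][[cond]][[comp]]$z)
    }), recursive = FALSE)
    one_sample_t_map(zs, alpha = alpha, cluster_min = cluster_min,
                     connectivity = connectivity)$sig
  }), components())
  feature_names <- as.vector(t(outer(components(), regions,
                                     function(cp, rg) {
                                       sprintf("%s_region_%02d", cp, rg)
                                     })))
  feature_names <- sort(feature_names)
  subjects <- names(maps)
  rows <- expand.grid(condition = conditions(), subject = subjects,
                      stringsAsFactors = FALSE)[, c(2L, 1L)]
  X <- matrix(0, nrow(rows), length(feature_names),
              dimnames = list(NULL, feature_names))
  region_vox <- split(which(atlas > 0L), atlas[atlas > 0L])
  mask_vox <- lapply(masks, function(m) {
    lapply(region_vox[as.character(regions)], intersect, x = which(m))
  })
  for (i in seq_len(nrow(rows))) {
    for (comp in components()) {
      z <- maps[[rows$subject[i]]][[rows$condition[i]]][[comp]]$z
      for (ri in seq_along(regions)) {
        zz <- z[mask_vox[[comp]][[ri]]]
        X[i, sprintf("%s_region_%02d", comp, regions[ri])] <-
          sum(zz[is.finite(zz)])
      }
    }
  }
  structure(list(X = X, y = unname(label_codes()[rows$condition]),
                 subject = rows$subject, condition = rows$condition,
                 feature_names = feature_names, masks = masks),
            class = "feature_matrix")
}

# linear eps-SVR with training-fold standardization
fit_predict_svr <- function(X_train, y_train, X_test) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(X_train, 2L, mu), 2L, sdv, "/")
  Xte <- sweep(sweep(X_test, 2L, mu), 2L, sdv, "/")
  fit <- e1071::svm(Xtr, y_train, type = "eps-regression",
                    kernel = "linear", cost = 1, epsilon = 0.1,
                    scale = FALSE)
  as.numeric(stats::predict(fit, Xte))
}

nearest_label <- function(pred, allowed) {
  allowed[max.col(-abs(outer(pred, allowed, "-")), ties.method = "first")]
}

#' Leave-one-subject-out SVR classification of language type
#'
#' Each subject's three samples are held out together; a linear support
#' vector regression (cost 1, epsilon 0.1, features standardized on the
#' training fold) is fitted on the remaining subjects' samples and its
#' continuous prediction is mapped to the nearest valid label. With
#' `pair` given, training and test are restricted to the two conditions
#' (midpoint decision between their labels).
#'
#' @param features a `feature_matrix` (or list with `X`, `y`, `subject`).
#' @param pair optional character pair of conditions.
#' @return List: `accuracy`, and `predictions` data frame (subject,
#'   condition, true and predicted label, raw regression output).
#' @export
loso_svr <- function(features, pair = NULL) {
  X <- features$X; y <- features$y; subj <- features$subject
  subjects <- unique(subj)
  if (length(subjects) < 5L) stop("loso_svr: need at least 5 subjects")
  allowed <- sort(unique(y))
  keep <- rep(TRUE, length(y))
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L, all(pair %in% names(label_codes())))
    allowed <- sort(unname(label_codes()[pair]))
    keep <- y %in% allowed
  }
  preds <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    te <- keep & subj == subjects[si]
    tr <- keep & subj != subjects[si]
    if (length(unique(y[tr])) < 2L) {
      stop("loso_svr: single-class training fold for subject ",
           subjects[si])
    }
    raw <- fit_predict_svr(X[tr, , drop = FALSE], y[tr],
                           X[te, , drop = FALSE])
    preds[[si]] <- data.frame(subject = subjects[si],
                              condition = features$condition[te],
                              y_true = y[te],
                              y_pred = nearest_label(raw, allowed),
                              raw = raw)
  }
  preds <- do.call(rbind, preds)
  list(accuracy = mean(preds$y_pred == preds$y_true), predictions = preds)
}

#' Full LOSO pipeline with fold-specific group masks
#'
#' For every fold, group masks and features are rebuilt from the
#' remaining subjects' maps only ([build_features()]), then a linear SVR
#' is trained on those subjects and evaluated on the held-out subject.
#'
#' @param maps nested subject maps from [searchlight_all()].
#' @param atlas 3D integer region labels.
#' @param pair optional condition pair.
#' @param fold_features optional precomputed per-fold feature matrices
#'   from [fold_feature_matrices()], reused across condition pairs.
#' @param ... passed to [build_features()].
#' @return As [loso_svr()].
#' @export
loso_svr_foldwise <- function(maps, atlas, pair = NULL,
                              fold_features = NULL, ...) {
  subjects <- names(maps)
  if (length(subjects) < 5L) stop("loso_svr_foldwise: need >= 5 subjects")
  if (is.null(fold_features)) {
    fold_features <- fold_feature_matrices(maps, atlas, ...)
  }
  allowed <- if (is.null(pair)) unname(label_codes()) else
    sort(unname(label_codes()[pair]))
  preds <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    fm <- fold_features[[subjects[si]]]
    keep <- if (is.null(pair)) rep(TRUE, length(fm$y)) else
      fm$condition %in% pair
    tr <- keep & fm$subject != subjects[si]
    te <- keep & fm$subject == subjects[si]
    if (length(unique(fm$y[tr])) < 2L) {
      stop("loso_svr_foldwise: single-class training fold")
    }
    raw <- fit_predict_svr(fm$X[tr, , drop = FALSE], fm$y[tr],
                           fm$X[te, , drop = FALSE])
    preds[[si]] <- data.frame(subject = subjects[si],
                              condition = fm$condition[te],
                              y_true = fm$y[te],
                              y_pred = nearest_label(raw, allowed),
                              raw = raw)
  }
  preds <- do.call(rbind, preds)
  list(accuracy = mean(preds$y_pred == preds$y_true), predictions = preds)
}

#' Per-fold feature matrices with leave-one-subject-out group masks
#'
#' One [build_features()] call per held-out subject, each using only the
#' remaining subjects' maps for the group masks.
#'
#' @param maps nested subject maps.
#' @param atlas 3D integer region labels.
#' @param ... passed to [build_features()].
#' @return Named list (held-out subject -> `feature_matrix`).
#' @export
fold_feature_matrices <- function(maps, atlas, ...) {
  subjects <- names(maps)
  setNames(lapply(seq_along(subjects), function(si) {
    build_features(maps, atlas, train_subjects = subjects[-si], ...)
  }), subjects)
}

# leave-one-sample-out root mean squared error of the linear SVR
rmse_loso_sample <- function(X, y) {
  pred <- vapply(seq_along(y), function(i) {
    fit_predict_svr(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE])
  }, 0)
  sqrt(mean((pred - y)^2))
}

#' Knee point of a curve
#'
#' The point of maximum perpendicular distance from the chord joining the
#' curve's endpoints, after normalizing both axes to `[0, 1]`. When no
#' point deviates from the chord by more than `flat_tol` the curve is
#' considered knee-free.
#'
#' @param x,y curve coordinates (x increasing).
#' @param flat_tol flatness tolerance on the normalized distance.
#' @return List: `index`, `x` of the knee (both `NA` when knee-free) and
#'   `has_knee`.
#' @export
find_knee <- function(x, y, flat_tol = 0.02) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  xr <- diff(range(x)); yr <- diff(range(y))
  if (xr == 0 || yr == 0) return(list(index = NA_integer_, x = NA_real_,
                                      has_knee = FALSE))
  xn <- (x - min(x)) / xr
  yn <- (y - min(y)) / yr
  x1 <- xn[1L]; y1 <- yn[1L]; x2 <- xn[length(xn)]; y2 <- yn[length(yn)]
  d <- abs((y2 - y1) * xn - (x2 - x1) * yn + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  if (max(d) < flat_tol) {
    return(list(index = NA_integer_, x = NA_real_, has_knee = FALSE))
  }
  i <- which.max(d)
  list(index = i, x = x[i], has_knee = TRUE)
}

#' Absence-rMSE recursive feature elimination
#'
#' Importance of each feature is the leave-one-sample-out rMSE of the SVR
#' fitted *without* it (absence-incurred rMSE): the larger the error its
#' absence incurs, the more important the feature. Features whose absence
#' lowers the error below the full-model rMSE are flagged for initial
#' elimination; all features are then removed one by one in ascending
#' absence-rMSE order, the model refitted and scored by negative rMSE at
#' every remaining-feature count, and the knee of that curve selects the
#' best feature count. Per protocol this runs on features built with a
#' unified (all-subject) group mask and leave-one-sample-out validation.
#'
#' @param features a `feature_matrix` (unified mask).
#' @param flat_tol knee flatness tolerance (see [find_knee()]).
#' @return List of class `"rfe_result"`: `absence_rmse` (named, full
#'   feature set), `full_rmse`, `initial_eliminate` flags, `ranking`
#'   (descending importance), `curve` (data frame `n_features`,
#'   `neg_rmse`), `knee` (selected count), `has_knee`,
#'   `selected_features`.
#' @export
rfe_rank_and_select <- function(features, flat_tol = 0.02) {
  X <- features$X; y <- features$y
  nf <- ncol(X)
  stopifnot(nf >= 3L)
  full_rmse <- rmse_loso_sample(X, y)
  absence <- vapply(seq_len(nf), function(j) {
    rmse_loso_sample(X[, -j, drop = FALSE], y)
  }, 0)
  names(absence) <- colnames(X)
  if (any(!is.finite(absence)) || !is.finite(full_rmse)) {
    stop("rfe_rank_and_select: non-finite rMSE for feature(s) ",
         paste(names(absence)[!is.finite(absence)], collapse = ", "))
  }
  # descending importance; ties broken by feature name order
  ord_desc <- order(-absence, names(absence))
  ranking <- names(absence)[ord_desc]
  removal_order <- rev(ranking)  # ascending absence-rMSE
  remaining <- colnames(X)
  counts <- integer(nf)
  neg_rmse <- numeric(nf)
  for (step in seq_len(nf)) {
    counts[step] <- length(remaining)
    neg_rmse[step] <- if (length(remaining) >= 1L) {
      -rmse_loso_sample(X[, remaining, drop = FALSE], y)
    } else {
      NA_real_
    }
    remaining <- setdiff(remaining, removal_order[step])
  }
  curve <- data.frame(n_features = counts, neg_rmse = neg_rmse)
  curve <- curve[order(curve$n_features), ]
  kn <- find_knee(curve$n_features, curve$neg_rmse, flat_tol)
  knee <- if (kn$has_knee) as.integer(kn$x) else nf
  structure(list(absence_rmse = absence, full_rmse = full_rmse,
                 initial_eliminate = absence < full_rmse,
                 ranking = ranking,
                 curve = curve, knee = knee, has_knee = kn$has_knee,
                 selected_features = ranking[seq_len(knee)]),
            class = "rfe_result")
}
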