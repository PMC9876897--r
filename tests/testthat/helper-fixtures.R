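# Shared fixtures and independent oracles. Expensive fixtures are built
# once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Independent connected-component oracle: stack-based flood fill, one seed
# voxel at a time (structurally unlike the union-find implementation).
flood_fill_labels <- function(mask, connectivity = 18L) {
  g <- dim(mask)
  off <- switch(as.character(connectivity),
                "6" = 1L, "18" = 2L, "26" = 3L)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) >= 1L & rowSums(abs(nb)) <= off, , drop = FALSE]
  labels <- array(0L, g)
  lab <- 0L
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    stack <- list(arrayInd(seed, g)[1L, ])
    labels[seed] <- lab
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(nb))) {
        p <- cur + nb[r, ]
        if (any(p < 1L) || any(p > g)) next
        pm <- matrix(p, 1L)
        if (mask[pm] && labels[pm] == 0L) {
          labels[pm] <- lab
          stack[[length(stack) + 1L]] <- p
        }
      }
    }
  }
  labels
}

# same-partition comparison (label ids may differ between algorithms)
same_partition <- function(a, b) {
  if (!all((a > 0L) == (b > 0L))) return(FALSE)
  ia <- a[a > 0L]; ib <- b[b > 0L]
  if (length(ia) == 0L) return(TRUE)
  all(tapply(ib, ia, function(v) length(unique(v))) == 1L) &&
    all(tapply(ia, ib, function(v) length(unique(v))) == 1L)
}

# small planted dataset reused across searchlight/group tests:
# one region carrying logo-grapheme geometry for Chinese words at 0.8
tiny_planted <- function() {
  fixture("tiny_planted", function() {
    cfg <- sim_config(
      n_subjects = 4L, n_trials_per_condition = 15L,
      grid_shape = c(12L, 12L, 12L), n_regions = 2L,
      region_radius_vox = 2L, n_background = 125L,
      effect_map = data.frame(region = 1L, condition = "chinese_word",
                              component = "logo", r = 0.8),
      subject_sd = 0, seed = 11L)
    ds <- simulate_dataset(cfg)
    maps <- searchlight_all(ds)
    list(cfg = cfg, ds = ds, maps = maps)
  })
}

# a random RDM with continuous entries
rand_rdm <- function(n, component = "neural", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2, 0.2, 1.8)
  rdm(m + t(m), component = component)
}

# synthetic subject maps (no searchlight): per condition/component a 3D z
# map, optionally with an elevated blob so conditions separate
fake_maps <- function(n_subjects, grid = c(10L, 10L, 10L), blobs = NULL,
                      seed = 1L) {
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  conds <- c("chinese_word", "english_word", "chinese_pinyin")
  comps <- c("logo", "phonology", "semantics")
  setNames(lapply(subjects, function(s) {
    setNames(lapply(conds, function(cond) {
      setNames(lapply(comps, function(comp) {
        z <- array(rnorm(prod(grid), 0, 0.05), grid)
        if (!is.null(blobs)) {
          b <- blobs[blobs$condition == cond & blobs$component == comp, ]
          if (nrow(b) == 1L) z[b$x1:b$x2, b$y1:b$y2, b$z1:b$z2] <-
              z[b$x1:b$x2, b$y1:b$y2, b$z1:b$z2] + b$height
        }
        p <- array(pnorm(z, sd = 0.05, lower.tail = FALSE), grid)
        list(z = z, p = p,
             sig = threshold_clusters(p, 0.05, 10L),
             subject = s, condition = cond, component = comp)
      }), comps)
    }), conds)
  }), subjects)
}

# synthetic long-format load table with additive structure + noise
make_loads <- function(n_subjects, effects = NULL, noise = 0.5,
                       seed = 1L) {
  set.seed(seed)
  conds <- c("chinese_word", "english_word", "chinese_pinyin")
  comps <- c("logo", "phonology", "semantics")
  d <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   condition = conds, component = comps,
                   stringsAsFactors = FALSE)
  d$load <- 5 + abs(rnorm(n_subjects))[match(d$subject,
                                             unique(d$subject))] +
    rnorm(nrow(d), 0, noise)
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      sel <- d$condition == effects$condition[i] &
        d$component == effects$component[i]
      d$load[sel] <- d$load[sel] + effects$delta[i]
    }
  }
  d$n_sig_voxels <- pmax(0L, round(d$load * 3))
  d
}

# independent oracle: direct balanced two-way within-subject sums of
# squares decomposition
rm_anova_oracle <- function(d) {
  ybar <- mean(d$load)
  ns <- length(unique(d$subject))
  nc <- length(unique(d$condition))
  nk <- length(unique(d$component))
  m_s <- tapply(d$load, d$subject, mean)
  m_c <- tapply(d$load, d$condition, mean)
  m_k <- tapply(d$load, d$component, mean)
  m_sc <- tapply(d$load, list(d$subject, d$condition), mean)
  m_sk <- tapply(d$load, list(d$subject, d$component), mean)
  m_ck <- tapply(d$load, list(d$condition, d$component), mean)
  ss_s <- nc * nk * sum((m_s - ybar)^2)
  ss_c <- ns * nk * sum((m_c - ybar)^2)
  ss_k <- ns * nc * sum((m_k - ybar)^2)
  ss_sc <- nk * sum((m_sc - outer(m_s, rep(1, nc)) -
                       outer(rep(1, ns), m_c) + ybar)^2)
  ss_sk <- nc * sum((m_sk - outer(m_s, rep(1, nk)) -
                       outer(rep(1, ns), m_k) + ybar)^2)
  ss_ck <- ns * sum((m_ck - outer(m_c, rep(1, nk)) -
                       outer(rep(1, nc), m_k) + ybar)^2)
  ss_tot <- sum((d$load - ybar)^2)
  ss_res <- ss_tot - ss_s - ss_c - ss_k - ss_sc - ss_sk - ss_ck
  list(
    F_c = (ss_c / (nc - 1)) / (ss_sc / ((ns - 1) * (nc - 1))),
    F_k = (ss_k / (nk - 1)) / (ss_sk / ((ns - 1) * (nk - 1))),
    F_ck = (ss_ck / ((nc - 1) * (nk - 1))) /
      (ss_res / ((ns - 1) * (nc - 1) * (nk - 1))),
    ss = c(ss_s, ss_c, ss_k, ss_sc, ss_sk, ss_ck, ss_res),
    ss_tot = ss_tot)
}

# feature fixture: one near-deterministic label feature + noise features
label_feature_fixture <- function(n_subjects = 12L, n_noise = 9L,
                                  label_sd = 0.05, seed = 91L) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = 3L)
  cond <- rep(c("chinese_word", "english_word", "chinese_pinyin"),
              n_subjects)
  y <- rep(1:3, n_subjects)
  X <- cbind(y + rnorm(length(y), 0, label_sd),
             matrix(rnorm(length(y) * n_noise), length(y), n_noise))
  colnames(X) <- c("label_feature",
                   sprintf("noise_%02d", seq_len(n_noise)))
  list(X = X, y = y, subject = subj, condition = cond,
       feature_names = colnames(X))
}
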