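# Repeated-measures ANOVA on cognitive loads, adjusted reaction times,
# and partial correlations between loads and reaction times.

#' Partial Pearson correlation
#'
#' Correlation between `x` and `y` with the columns of `controls`
#' partialled out by residual regression. With an empty control set this
#' is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param controls numeric matrix of control variables (0 columns
#'   allowed).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List `r`, `p`, `df`.
#' @export
partial_pearson <- function(x, y, controls = NULL,
                            alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  if (is.null(controls)) controls <- matrix(0, length(x), 0L)
  controls <- as.matrix(controls)
  k <- ncol(controls)
  n <- length(x)
  if (n < k + 3L) {
    stop("partial_pearson: need n >= number of controls + 3")
  }
  q <- qr(cbind(1, controls))
  ex <- qr.resid(q, x)
  ey <- qr.resid(q, y)
  sx <- sqrt(sum(ex^2)); sy <- sqrt(sum(ey^2))
  # a variable fully explained by the controls has nothing left to
  # correlate (numerical-zero residual norm)
  if (sx <= 1e-8 * sqrt(sum((x - mean(x))^2)) ||
      sy <= 1e-8 * sqrt(sum((y - mean(y))^2))) {
    return(list(r = 0, p = 1, df = n - 2L - k))
  }
  r <- sum(ex * ey) / (sx * sy)
  df <- n - 2L - k
  tt <- r * sqrt(df / max(1 - r^2, 1e-12))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
              greater = stats::pt(tt, df, lower.tail = FALSE),
              less = stats::pt(tt, df))
  list(r = r, p = min(p, 1), df = df)
}

#' Two-way repeated-measures ANOVA on cognitive loads
#'
#' Classical within-subject decomposition of load by condition (writing
#' system) and linguistic component, both within-subject factors, with
#' their interaction, via the standard `aov` error strata
#' `Error(subject/(condition*component))`. Post hoc: paired t-tests
#' between components within each condition, Bonferroni-corrected over
#' the whole pairwise family. An optional Greenhouse-Geisser correction
#' of the within-subject p-values is available; by default sphericity is
#' assumed.
#'
#' @param loads a [load_table()] (complete 3x3 cells per subject);
#'   alternatively any long data frame with columns `subject`,
#'   `condition`, `component` and a response named by `value`.
#' @param value response column name (default `"load"`).
#' @param gg apply Greenhouse-Geisser correction to within-subject
#'   effects.
#' @return List of class `"anova_result"`: `effects` (term, df1, df2, F,
#'   p), `cell_means`, `posthoc` (with Bonferroni-adjusted p and the
#'   family size), `gg`.
#' @export
rm_anova_two_way <- function(loads, value = "load", gg = FALSE) {
  d <- data.frame(subject = factor(loads$subject),
                  condition = factor(loads$condition),
                  component = factor(loads$component),
                  y = loads[[value]])
  counts <- table(d$subject, d$condition, d$component)
  if (any(counts != 1L)) {
    bad <- levels(d$subject)[apply(counts, 1L, function(m) any(m != 1L))]
    stop("rm_anova_two_way: incomplete condition x component cells for ",
         "subject(s): ", paste(bad, collapse = ", "))
  }
  fit <- stats::aov(y ~ condition * component +
                      Error(subject / (condition * component)), data = d)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1L]]
    i <- match(term, trimws(rownames(tab)))
    resid <- match("Residuals", trimws(rownames(tab)))
    Fv <- tab$`F value`[i]
    pv <- tab$`Pr(>F)`[i]
    # an effect sum of squares at numerical zero is a zero F, even when
    # aov reports roundoff/roundoff as a finite ratio
    if (tab$`Sum Sq`[i] <= 1e-12 * max(1, sum(d$y^2))) {
      Fv <- 0
      pv <- 1
    }
    data.frame(term = term, df1 = tab$Df[i], df2 = tab$Df[resid],
               F = Fv, p = pv)
  }
  effects <- rbind(grab("subject:condition", "condition"),
                   grab("subject:component", "component"),
                   grab("subject:condition:component",
                        "condition:component"))
  if (gg) {
    effects$epsilon_gg <- vapply(effects$term, function(tm) {
      gg_epsilon(d, tm)
    }, 0)
    effects$p <- stats::pf(effects$F,
                           effects$df1 * effects$epsilon_gg,
                           effects$df2 * effects$epsilon_gg,
                           lower.tail = FALSE)
  }
  cells <- stats::aggregate(y ~ condition + component, d, function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  })
  cell_means <- data.frame(condition = cells$condition,
                           component = cells$component,
                           mean = cells$y[, "mean"], se = cells$y[, "se"])
  # post hoc: components within each condition, paired t, Bonferroni
  ph <- do.call(rbind, lapply(levels(d$condition), function(cond) {
    do.call(rbind, utils::combn(levels(d$component), 2L,
                                simplify = FALSE, function(pr) {
      a <- d$y[d$condition == cond & d$component == pr[1L]]
      b <- d$y[d$condition == cond & d$component == pr[2L]]
      a <- a[order(d$subject[d$condition == cond &
                               d$component == pr[1L]])]
      b <- b[order(d$subject[d$condition == cond &
                               d$component == pr[2L]])]
      if (stats::sd(a - b) == 0) {
        tt <- list(statistic = c(t = ifelse(mean(a - b) == 0, 0,
                                            sign(mean(a - b)) * Inf)),
                   p.value = ifelse(mean(a - b) == 0, 1, 0))
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
      }
      data.frame(condition = cond, component_a = pr[1L],
                 component_b = pr[2L], mean_diff = mean(a - b),
                 t = unname(tt$statistic), p_raw = tt$p.value)
    }))
  }))
  m <- nrow(ph)
  ph$p_bonferroni <- pmin(1, ph$p_raw * m)
  ph$family_size <- m
  structure(list(effects = effects, cell_means = cell_means,
                 posthoc = ph, gg = gg),
            class = "anova_result")
}

# Greenhouse-Geisser epsilon for one within-subject term, from the
# covariance of the subject x cell matrix projected on the term's
# orthonormal effect contrasts.
gg_epsilon <- function(d, term) {
  d2 <- d[order(d$subject, d$condition, d$component), ]
  nc <- nlevels(d$condition); nk <- nlevels(d$component)
  # one row per subject, cells ordered condition (slow) x component (fast)
  Y <- matrix(d2$y, nrow = nlevels(d$subject), ncol = nc * nk,
              byrow = TRUE)
  Cc <- stats::contr.helmert(nc); Ck <- stats::contr.helmert(nk)
  Jc <- matrix(1, nc, 1L); Jk <- matrix(1, nk, 1L)
  M <- switch(term,
              condition = kronecker(Cc, Jk),
              component = kronecker(Jc, Ck),
              `condition:component` = kronecker(Cc, Ck))
  M <- qr.Q(qr(M))
  S <- stats::cov(Y %*% M)
  k <- ncol(S)
  min(1, sum(diag(S))^2 / (k * sum(S^2)))
}

#' Adjusted reaction times
#'
#' Removes stable between-subject speed differences from reaction times
#' by fitting an additive model with a fixed condition effect and a
#' per-subject offset, and subtracting each subject's estimated offset.
#' In the balanced complete case this equals subject-mean-centering plus
#' the grand mean. (This is the unshrunken limit of a random-intercept
#' mixed model. A constant shift of one subject's times is absorbed into
#' their offset up to the uniform grand-mean update of shift/n, a common
#' constant that no downstream correlation sees.)
#'
#' @param behavior data frame with `subject`, `condition`, `rt_ms`.
#' @return Data frame `subject`, `condition`, `rt_ms`, `adjusted_rt`.
#'   Subjects observed in fewer than 2 conditions are dropped with a
#'   warning.
#' @export
adjusted_rt <- function(behavior) {
  d <- behavior[, c("subject", "condition", "rt_ms")]
  n_cond <- tapply(d$condition, d$subject, function(x) length(unique(x)))
  drop <- names(n_cond)[n_cond < 2L]
  if (length(drop) > 0L) {
    warning("adjusted_rt: dropping subject(s) with < 2 conditions: ",
            paste(drop, collapse = ", "))
    d <- d[!d$subject %in% drop, ]
  }
  d$subject <- factor(d$subject)
  d$condition <- factor(d$condition)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::lm(rt_ms ~ condition + subject, data = d)
  co <- stats::coef(fit)
  subj_terms <- grep("^subject", names(co))
  eff <- c(co[subj_terms], -sum(co[subj_terms]))  # sum-to-zero offsets
  names(eff) <- levels(d$subject)
  d$adjusted_rt <- d$rt_ms - eff[as.character(d$subject)]
  rownames(d) <- NULL
  d
}

#' Partial correlation between cognitive loads and reaction times
#'
#' For each (condition, component) cell: the partial Pearson correlation
#' across subjects between the component's load and the condition's
#' adjusted reaction time, controlling the other two components' loads in
#' the same condition (an assumption, recorded on the output), with
#' Bonferroni adjustment over the stated family.
#'
#' @param loads a [load_table()].
#' @param adj_rt output of [adjusted_rt()].
#' @param family Bonferroni family size (default 3: the components
#'   within a condition).
#' @return Data frame of class `"association_result"`: per cell `r`,
#'   `p_raw`, `p_bonferroni`, `n`, plus `family_size` and `controls`
#'   columns describing the correction and covariates.
#' @export
load_rt_partial_correlation <- function(loads, adj_rt, family = 3L) {
  stopifnot(family >= 1L)
  subjects <- sort(intersect(unique(loads$subject),
                             unique(adj_rt$subject)))
  out <- do.call(rbind, lapply(conditions(), function(cond) {
    rt <- adj_rt$adjusted_rt[match(paste(subjects, cond),
                                   paste(adj_rt$subject,
                                         adj_rt$condition))]
    lw <- vapply(components(), function(comp) {
      loads$load[match(paste(subjects, cond, comp),
                       paste(loads$subject, loads$condition,
                             loads$component))]
    }, numeric(length(subjects)))
    do.call(rbind, lapply(components(), function(comp) {
      others <- setdiff(components(), comp)
      pc <- partial_pearson(lw[, comp], rt, lw[, others, drop = FALSE])
      data.frame(condition = cond, component = comp, r = pc$r,
                 p_raw = pc$p, p_bonferroni = min(1, pc$p * family),
                 n = length(subjects),
                 controls = paste(others, collapse = "+"))
    }))
  }))
  out$family_size <- family
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}
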