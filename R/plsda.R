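#' Fit a PLS-DA model by NIPALS
#'
#' Partial least-squares discriminant analysis of a processed metabolite
#' table against a one-hot class matrix (infection phase by default, time
#' point optionally). The fit is a plain iterative NIPALS PLS2: per
#' component, weights `w` (unit norm), X-scores `t = Xw`, X-loadings `p`,
#' Y-loadings `q`, followed by deflation of both blocks. Initialization is
#' the first column of the (centered) class matrix, so the fit is fully
#' deterministic given input order. No cross-validation is performed;
#' explained percentages are in-sample.
#'
#' For each component the model records the explained class sum of squares
#' \eqn{SSY_a = (t_a't_a)(q_a'q_a)} and the percent of X variance
#' \eqn{(t_a't_a)(p_a'p_a)/\|X\|^2}; these feed the VIP scores.
#'
#' @param table a pareto-stage [metab_table()], or a plain numeric matrix of
#'   samples x features (already centered/scaled as desired).
#' @param labels `"phase"` or `"time_point"` to take classes from the table
#'   metadata, or a vector of class labels, one per sample.
#' @param n_components number of latent components (default 3). Reduced with
#'   a warning if it exceeds the rank of the data.
#' @param tol,max_iter NIPALS convergence tolerance and iteration cap.
#' @return an object of class `plsda_fit` with elements `weights`, `scores`,
#'   `x_loadings`, `y_loadings`, `explained_y_ss`, `explained_x_pct`, `vip`
#'   (features x components, cumulative; see [vip_scores()]), `classes`,
#'   `labels`, `feature_ids`.
#' @export
fit_plsda <- function(table, labels = "phase", n_components = 3,
                      tol = 1e-10, max_iter = 500) {
  if (is_metab_table(table)) {
    if (table$stage != "pareto")
      stopf("fit_plsda expects a pareto-stage table, got '%s'", table$stage)
    X <- t(table$values)
    if (is.character(labels) && length(labels) == 1) {
      if (!labels %in% c("phase", "time_point"))
        stopf("`labels` must be 'phase', 'time_point', or a vector of classes")
      labels <- as.character(table$sample_meta[[labels]])
    }
  } else if (is.matrix(table)) {
    X <- table
  } else stopf("`table` must be a metab_table or a samples x features matrix")
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stopf("need one class label per sample")
  classes <- unique(labels)
  if (length(classes) < 2) stopf("PLS-DA needs at least 2 classes")
  Y <- outer(labels, classes, `==`) * 1
  colnames(Y) <- classes

  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  rank_x <- qr(Xc)$rank
  A <- min(n_components, rank_x)
  if (A < n_components)
    warnf("n_components reduced from %d to the data rank %d",
          n_components, A)

  p <- ncol(Xc)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, nrow(Xc), A)
  Q <- matrix(0, ncol(Yc), A)
  ssy <- ssx_pct <- numeric(A)
  ssx_tot <- sum(Xc^2)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(A)) {
    u <- Yd[, 1]
    t_old <- rep(0, nrow(Xd))
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pl <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pl; Q[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)
    ssx_pct[a] <- 100 * sum(tt^2) * sum(pl^2) / ssx_tot
    Xd <- Xd - tt %*% t(pl)
    Yd <- Yd - tt %*% t(q)
  }
  feature_ids <- colnames(X)
  if (is.null(feature_ids)) feature_ids <- sprintf("x%d", seq_len(p))
  rownames(W) <- rownames(P) <- feature_ids

  # cumulative VIP through each depth a
  vip <- vapply(seq_len(A), function(a) {
    num <- colSums(ssy[seq_len(a)] * t(W[, seq_len(a), drop = FALSE]^2))
    sqrt(p * num / sum(ssy[seq_len(a)]))
  }, numeric(p))
  vip <- matrix(vip, nrow = p,
                dimnames = list(feature_ids, paste0("comp", seq_len(A))))

  structure(list(weights = W, scores = Tm, x_loadings = P, y_loadings = Q,
                 explained_y_ss = ssy, explained_x_pct = ssx_pct,
                 vip = vip, n_components = A, classes = classes,
                 labels = labels, feature_ids = feature_ids),
            class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("PLS-DA fit: %d features, %d samples, %d classes, %d components\n",
              length(x$feature_ids), nrow(x$scores), length(x$classes),
              x$n_components))
  cat("  explained X variance (%):",
      paste(sprintf("%.1f", x$explained_x_pct), collapse = " "), "\n")
  cat(sprintf("  features with VIP > 1 (component 1): %d\n",
              sum(x$vip[, 1] > 1)))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP is a weighted sum of squares of the PLS weights in which each
#' component is weighted by the class variation it explains; through
#' component `a`:
#' \deqn{VIP_j = \sqrt{p \; \frac{\sum_{b \le a} SSY_b w_{bj}^2}{\sum_{b \le a} SSY_b}}}
#' with `p` the number of features, so the mean squared VIP is always 1
#' (\eqn{\sum_j VIP_j^2 = p}). When several components are considered jointly
#' the importance is reported as the average of the per-depth VIP scores.
#'
#' @param model a [fit_plsda()] result.
#' @param component cumulative depth `a` (1 to `n_components`).
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model, component = 1) {
  stopifnot(inherits(model, "plsda_fit"))
  if (component < 1 || component > model$n_components)
    stopf("`component` must be between 1 and %d", model$n_components)
  model$vip[, component]
}

#' @rdname vip_scores
#' @description `vip_importance()` is the multi-component importance: the
#'   average of the VIP scores across all fitted component depths.
#' @export
vip_importance <- function(model) {
  stopifnot(inherits(model, "plsda_fit"))
  rowMeans(model$vip)
}

#' Features contributing significantly to class separation
#'
#' A VIP score above 1 marks a metabolite as contributing more than an
#' average feature to the separation; the cutoff is strict (exactly 1 is
#' excluded).
#'
#' @param vip named vector of VIP scores (e.g. [vip_scores()]).
#' @param threshold strict cutoff (> 0), default 1.
#' @return character vector of feature ids with VIP strictly above the
#'   threshold, ordered by decreasing VIP.
#' @export
vip_significant <- function(vip, threshold = 1) {
  if (threshold <= 0) stopf("`threshold` must be positive")
  sel <- vip[vip > threshold]
  names(sel)[order(-sel)]
}

#' Score plot of a PLS-DA fit
#'
#' @param x a [fit_plsda()] result.
#' @param comps which two components to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda_fit <- function(x, comps = c(1, 2), ...) {
  stopifnot(length(comps) == 2, all(comps <= x$n_components))
  cls <- factor(x$labels)
  cols <- grDevices::hcl.colors(nlevels(cls), "Dark 3")
  graphics::plot(x$scores[, comps[1]], x$scores[, comps[2]],
                 col = cols[as.integer(cls)], pch = 19,
                 xlab = sprintf("Component %d (%.1f%% X var)", comps[1],
                                x$explained_x_pct[comps[1]]),
                 ylab = sprintf("Component %d (%.1f%% X var)", comps[2],
                                x$explained_x_pct[comps[2]]), ...)
  graphics::legend("topright", legend = levels(cls), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
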