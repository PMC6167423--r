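## Multivariate engine: PCA screening, orthogonal signal correction,
## NIPALS PLS-DA with cross-validated Q2, permutation validation, VIP.

# Column-centered class-indicator (dummy) matrix, one column per group.
# Multi-group models (4- and 7-group comparisons) use one column per group,
# the standard PLS2 discriminant setup.
dummy_y <- function(design) {
  groups <- sort(unique(design$group))
  if (length(groups) < 2) stop("need >= 2 groups")
  y <- outer(design$group, groups, `==`) * 1
  colnames(y) <- groups
  means <- colMeans(y)
  list(y = sweep(y, 2, means), means = means, groups = groups)
}

# Extract the numeric matrix from a spectra_matrix or pass a matrix through.
as_X <- function(x) {
  if (inherits(x, "spectra_matrix")) x$intensities else as.matrix(x)
}

#' PCA screening for clusters and outliers
#'
#' Principal component analysis by SVD of the (already centered) data,
#' with Hotelling T2 outlier flagging over the retained components: sample
#' `i` is flagged when its T2 exceeds the critical value of the scaled
#' F distribution at level `alpha`.
#'
#' @param X Centered numeric matrix (or a centered [spectra_matrix()]).
#' @param n_components Number of components to retain (>= 1).
#' @param alpha Significance level for the T2 cut-off.
#' @return List with `scores`, `loadings`, `explained_variance` (fractions),
#'   `t2`, `t2_critical` and logical `outlier_flags`.
#' @export
pca_screen <- function(X, n_components = 2, alpha = 0.05) {
  X <- as_X(X)
  n <- nrow(X)
  if (n < 3) stop("PCA screening requires n >= 3")
  a <- n_components
  if (a < 1 || a > min(n - 1, ncol(X)))
    stop("n_components must be in [1, min(n-1, p)]")
  sv <- svd(X, nu = a, nv = a)
  scores <- sv$u %*% diag(sv$d[seq_len(a)], a, a)
  lambda <- sv$d^2 / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda[seq_len(a)], "/"))
  crit <- if (alpha >= 1) 0
  else a * (n - 1) / (n - a) * stats::qf(1 - alpha, a, n - a)
  list(scores = scores, loadings = sv$v,
       explained_variance = lambda / sum(lambda),
       t2 = t2, t2_critical = crit, outlier_flags = t2 > crit)
}

#' Orthogonal signal correction (OSC) filtering
#'
#' Removes from the data the dominant variation orthogonal to the class
#' structure -- confounding experimental or instrumental variation that can
#' overshadow treatment effects. Per removed component: the score is seeded
#' with the first principal component, orthogonalized against the centered
#' class dummy matrix, refined by finding the unit weight vector `w`
#' minimizing `||Xw - t||` (via the pseudoinverse of `X`) and recomputing
#' `t = Xw`, iterating to convergence; `X` is then deflated by `t p'` with
#' `p = X't/(t't)`.
#'
#' The returned scores are exactly uncorrelated with every dummy column, and
#' the filtered matrix plus the removed components reconstructs the input.
#'
#' @param X Centered numeric matrix (or centered/scaled [spectra_matrix()]).
#' @param design A [sample_design()].
#' @param n_osc Number of orthogonal components to remove (default 1, the
#'   conservative choice).
#' @param tol Relative score-change convergence tolerance.
#' @param max_iter Iteration cap per component.
#' @return List of class `osc_result`: `filtered_X`, `removed_scores`
#'   (n x k), `removed_loadings` (p x k), `variance_removed` (fraction of
#'   total sum of squares per component).
#' @export
osc_filter <- function(X, design, n_osc = 1, tol = 1e-10, max_iter = 100) {
  sm <- if (inherits(X, "spectra_matrix")) X else NULL
  X <- as_X(X)
  if (n_osc < 1) stop("n_osc must be >= 1")
  dy <- dummy_y(design)
  Y <- dy$y
  if (qr(Y)$rank < ncol(Y) - 1)
    stop("rank-deficient class dummy matrix")
  # projector onto the orthogonal complement of the dummy space
  qy <- qr.Q(qr(Y))
  orth <- function(t) t - qy %*% crossprod(qy, t)
  total_ss <- sum(X^2)
  n <- nrow(X)
  removed_t <- matrix(0, n, n_osc)
  removed_p <- matrix(0, ncol(X), n_osc)
  var_removed <- numeric(n_osc)
  for (k in seq_len(n_osc)) {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    t_cur <- sv$u[, 1] * sv$d[1]
    rel <- Inf
    for (it in seq_len(max_iter)) {
      t_orth <- orth(t_cur)
      # unit w minimizing ||Xw - t||: least-squares via the pseudoinverse
      w <- sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], t_orth) / sv$d[pos])
      w <- w / sqrt(sum(w^2))
      t_new <- X %*% w
      rel <- sqrt(sum((t_new - t_cur)^2)) / sqrt(sum(t_new^2))
      t_cur <- t_new
      if (rel < tol) break
    }
    if (rel >= tol)
      stop(sprintf(
        "OSC component %d did not converge in %d iterations (relative change %.3g)",
        k, max_iter, rel))
    # enforce exact orthogonality to the class space before deflation
    t_cur <- orth(t_cur)
    p <- crossprod(X, t_cur) / sum(t_cur^2)
    X <- X - t_cur %*% t(p)
    removed_t[, k] <- t_cur
    removed_p[, k] <- p
    var_removed[k] <- sum((t_cur %*% t(p))^2) / total_ss
  }
  if (!is.null(sm)) sm$intensities <- X
  structure(list(filtered_X = if (is.null(sm)) X else sm,
                 removed_scores = removed_t, removed_loadings = removed_p,
                 variance_removed = var_removed),
            class = "osc_result")
}

#' Fit a PLS-DA model (NIPALS)
#'
#' Two-block NIPALS partial least squares against the column-centered class
#' dummy matrix. Per component: the X-weight/Y-loading pair is iterated to
#' convergence, the score is `t = Xw` with unit-norm `w`, and both blocks
#' are deflated on `t`. R2Y is the cumulative fraction of dummy-matrix
#' variance explained.
#'
#' @param X Centered (and typically Pareto-scaled) matrix or
#'   [spectra_matrix()].
#' @param design A [sample_design()].
#' @param A Number of latent components.
#' @param tol,max_iter NIPALS convergence controls.
#' @return Object of class `pls_model` with `W` (unit-norm X-weights), `P`
#'   (X-loadings), `T` (orthogonal X-scores), `C` (Y-loadings),
#'   `ssy_explained` (Y sum of squares captured per component), `r2y`
#'   (cumulative fraction), `groups`, `y_means`, `design`.
#' @export
fit_plsda <- function(X, design, A = 2, tol = 1e-12, max_iter = 500) {
  X <- as_X(X)
  n <- nrow(X)
  if (n != nrow(design)) stop("X rows and design rows differ")
  dy <- dummy_y(design)
  Y <- dy$y
  if (A < 1) stop("A must be >= 1")
  rank_x <- qr(X)$rank
  if (A > min(n - 1, ncol(X)))
    stop("A exceeds min(n-1, p) = ", min(n - 1, ncol(X)))
  if (A > rank_x)
    stop("A exceeds the rank of X (attained rank ", rank_x, ")")
  ssy_total <- sum(Y^2)
  W <- matrix(0, ncol(X), A); P <- matrix(0, ncol(X), A)
  Tm <- matrix(0, n, A); C <- matrix(0, ncol(Y), A)
  ssy <- numeric(A)
  Xd <- X; Yd <- Y
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      cc <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% cc / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    p <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(p)
    Yd <- Yd - tt %*% t(cc)
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; C[, a] <- cc
    ssy[a] <- sum(tt^2) * sum(cc^2)
  }
  structure(list(A = A, W = W, P = P, T = Tm, C = C,
                 ssy_explained = ssy, r2y = 1 - sum(Yd^2) / ssy_total,
                 groups = dy$groups, y_means = dy$means,
                 x_means = rep(0, ncol(X)), design = design),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> A = %d, %d groups, R2Y = %.3f\n",
              x$A, length(x$groups), x$r2y))
  invisible(x)
}

# Predict centered-dummy responses for new observations, using up to A
# components of a fitted model. new_X must be on the same scale as the
# training X (same centering/scaling applied).
predict_plsda <- function(model, new_X, A = model$A) {
  Xd <- as_X(new_X)
  yhat <- matrix(0, nrow(Xd), length(model$groups))
  for (a in seq_len(A)) {
    tt <- Xd %*% model$W[, a]
    Xd <- Xd - tt %*% t(model$P[, a])
    yhat <- yhat + tt %*% t(model$C[, a])
  }
  yhat
}

# Stratified fold assignment: samples of each group are dealt round-robin
# over folds in a seeded random order.
stratified_folds <- function(design, folds, seed) {
  if (folds < 2) stop("folds must be >= 2")
  if (folds > nrow(design)) stop("more folds than samples")
  assign_f <- integer(nrow(design))
  with_local_seed(seed, {
    offset <- 0
    for (g in sort(unique(design$group))) {
      idx <- sample(which(design$group == g))
      assign_f[idx] <- ((seq_along(idx) - 1 + offset) %% folds) + 1
      offset <- offset + length(idx)
    }
  })
  assign_f
}

#' Cross-validated Q2 of a PLS-DA model
#'
#' Stratified k-fold cross-validation (default 7-fold) of the dummy-matrix
#' prediction: `Q2 = 1 - PRESS/SS`, with PRESS summing squared held-out
#' prediction errors over folds and SS the squared deviations of the
#' held-out responses from the training-fold means. Per-component values are
#' computed sequentially, supporting the selection rule "add components
#' while the cumulative Q2 increases".
#'
#' @inheritParams fit_plsda
#' @param folds Number of folds (default 7).
#' @param seed Seed for the fold assignment.
#' @return List with `q2_cumulative` (at `A` components), `q2_per_component`
#'   (cumulative Q2 after 1..A components), `folds`, `seed`.
#' @export
cross_validated_q2 <- function(X, design, A = 2, folds = 7, seed = 1) {
  X <- as_X(X)
  fold_of <- stratified_folds(design, folds, seed)
  press <- numeric(A)
  ss <- 0
  for (f in seq_len(folds)) {
    test <- fold_of == f
    if (!any(test)) next
    tr_design <- design[!test, , drop = FALSE]
    if (length(unique(tr_design$group)) < 2) next
    mu <- colMeans(X[!test, , drop = FALSE])
    Xtr <- sweep(X[!test, , drop = FALSE], 2, mu)
    Xte <- sweep(X[test, , drop = FALSE], 2, mu)
    a_max <- min(A, qr(Xtr)$rank, nrow(Xtr) - 1)
    fit <- fit_plsda(Xtr, tr_design, A = a_max)
    # held-out dummy responses, centered by training-fold means
    groups <- fit$groups
    yte <- outer(design$group[test], groups, `==`) * 1
    yte <- sweep(yte, 2, fit$y_means)
    ss <- ss + sum(yte^2)
    for (a in seq_len(A)) {
      pred <- predict_plsda(fit, Xte, A = min(a, a_max))
      press[a] <- press[a] + sum((yte - pred)^2)
    }
  }
  q2 <- 1 - press / ss
  list(q2_cumulative = q2[A], q2_per_component = q2,
       folds = folds, seed = seed)
}

#' Choose the number of PLS components by cross-validation
#'
#' Adds components while the cumulative cross-validated Q2 keeps improving
#' by at least `min_improvement`, with a hard cap. The default margin of
#' 0.05 is the classic chemometrics significance limit for an additional
#' component; a bare "any increase" rule (`min_improvement = 0`) readily
#' admits components that model cross-validation noise.
#'
#' @inheritParams cross_validated_q2
#' @param max_A Cap on the number of components (default 10).
#' @param min_improvement Minimum cumulative-Q2 gain required to accept an
#'   additional component (default 0.05).
#' @return List with `A` (selected), `q2_per_component`.
#' @export
select_components <- function(X, design, folds = 7, seed = 1, max_A = 10,
                              min_improvement = 0.05) {
  X <- as_X(X)
  cap <- min(max_A, nrow(X) - 1, ncol(X), qr(X)$rank)
  cv <- cross_validated_q2(X, design, A = cap, folds = folds, seed = seed)
  q2 <- cv$q2_per_component
  A <- 1
  while (A < length(q2) && q2[A + 1] >= q2[A] + min_improvement) A <- A + 1
  list(A = A, q2_per_component = q2[seq_len(A)])
}

#' Permutation test of a PLS-DA model
#'
#' Refits the model under `n_perm` uniformly random permutations of the
#' class labels, recomputing R2Y and cross-validated Q2 each time with the
#' same number of components and folds. The empirical p-value is
#' `(1 + #(permuted Q2 >= observed Q2)) / (n_perm + 1)`, so the attainable
#' minimum is `1/(n_perm + 1)`.
#'
#' @inheritParams cross_validated_q2
#' @param n_perm Number of permutations (default 200).
#' @return Object of class `permutation_result`: `observed_r2y`,
#'   `observed_q2`, `permuted_r2y`, `permuted_q2`, `empirical_p_q2`.
#' @export
permutation_test <- function(X, design, A = 2, folds = 7, n_perm = 200,
                             seed = 1) {
  X <- as_X(X)
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs_fit <- fit_plsda(X, design, A = A)
  obs_q2 <- cross_validated_q2(X, design, A = A, folds = folds,
                               seed = seed)$q2_cumulative
  perm_r2y <- numeric(n_perm)
  perm_q2 <- numeric(n_perm)
  perms <- with_local_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample(nrow(design)))
  })
  for (i in seq_len(n_perm)) {
    pd <- design
    pd$group <- design$group[perms[[i]]]
    pd$compound <- design$compound[perms[[i]]]
    pd$dose_label <- design$dose_label[perms[[i]]]
    res <- tryCatch({
      fit <- fit_plsda(X, pd, A = A)
      q2 <- cross_validated_q2(X, pd, A = A, folds = folds,
                               seed = seed + i)$q2_cumulative
      c(fit$r2y, q2)
    }, error = function(e)
      stop("permutation ", i, " failed: ", conditionMessage(e)))
    perm_r2y[i] <- res[1]
    perm_q2[i] <- res[2]
  }
  structure(list(observed_r2y = obs_fit$r2y, observed_q2 = obs_q2,
                 permuted_r2y = perm_r2y, permuted_q2 = perm_q2,
                 empirical_p_q2 = (1 + sum(perm_q2 >= obs_q2)) / (n_perm + 1)),
            class = "permutation_result")
}

#' Variable importance in the projection (VIP)
#'
#' Per-variable summary of contribution across the PLS components:
#' `VIP_j = sqrt(p * sum_a ssy_a * (w_ja / ||w_a||)^2 / sum_a ssy_a)`,
#' where `ssy_a` is the Y sum of squares captured by component `a`. The
#' scores are mean-square normalized: `sum_j VIP_j^2 = p`.
#'
#' @param model A fitted [fit_plsda()] model.
#' @return Object of class `vip_result` with numeric `vip` (one per
#'   variable).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$A < 1) stop("model has no components")
  ssy <- model$ssy_explained
  if (sum(ssy) <= 0) stop("zero explained Y sum of squares")
  wnorm2 <- colSums(model$W^2)
  p <- nrow(model$W)
  vip <- sqrt(p * as.numeric((model$W^2 %*% (ssy / wnorm2))) / sum(ssy))
  structure(list(vip = vip), class = "vip_result")
}

#' Kruskal-Wallis rank test across design groups
#'
#' Non-parametric one-way analysis of variance on ranks with the standard
#' tie correction, p-value from the chi-square approximation with g-1
#' degrees of freedom. The degenerate all-identical case returns H = 0,
#' p = 1 rather than an error.
#'
#' @param values Numeric vector, one value per sample.
#' @param design A [sample_design()] (or any data frame with a `group`
#'   column) aligned with `values`.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(values, design) {
  g <- factor(design$group)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (length(values) != length(g)) stop("values and design lengths differ")
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' PLS-DA score plot
#'
#' The standard two-component score plot with group colouring, the visual
#' check that exposed groups separate from controls.
#'
#' @param model A fitted [fit_plsda()] model.
#' @param components Length-2 integer vector of components to display.
#' @return A ggplot object.
#' @export
plot_scores <- function(model, components = c(1, 2)) {
  stopifnot(inherits(model, "pls_model"), model$A >= max(components))
  df <- data.frame(t1 = model$T[, components[1]],
                   t2 = model$T[, components[2]],
                   group = model$design$group)
  ggplot2::ggplot(df, ggplot2::aes(x = t1, y = t2, colour = group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("t[%d]", components[1]),
                  y = sprintf("t[%d]", components[2]),
                  colour = "group") +
    ggplot2::theme_minimal()
}
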