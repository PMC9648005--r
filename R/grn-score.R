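#' Score TF-to-gene regulatory edges
#'
#' Three independent scorer families, re-implemented rather than bound, each
#' returning a TF x gene score matrix (self-scores `NA`):
#'
#' * `mi_dpi` (ARACNE family): pairwise mutual information on equal-frequency
#'   rank bins, followed by data-processing-inequality pruning -- in every
#'   triangle the weakest edge is removed (within a relative tolerance) as
#'   presumably indirect. Pruned edges are reported as `NA`: they are absent
#'   from the method's results and can never pass a threshold.
#' * `tree_importance` (GENIE3 family): per-target extremely-randomized
#'   regression trees; a TF's score is its total variance-reduction
#'   importance, normalized per target to sum to 1.
#' * `stability_regression` (TIGRESS family): selection frequency of each TF
#'   across subsampled, feature-reweighted L1 regularization paths
#'   (half-sample subsamples, glmnet lasso path, a TF counts as selected when
#'   it enters among the first `L` lambdas).
#'
#' All scores are nonnegative and deterministic given `seed`. Constant
#' (zero-variance) genes score 0 against everything, with a warning.
#'
#' @param m an [expression_matrix()] with at least 10 samples.
#' @param tfs character vector of regulator gene ids (subset of rownames).
#' @param method one of `"mi_dpi"`, `"tree_importance"`,
#'   `"stability_regression"`.
#' @param seed RNG seed for the stochastic scorers.
#' @param mi_bins number of equal-frequency bins (default
#'   `ceiling(log2(n)) + 1`).
#' @param dpi_tolerance relative DPI tolerance (default 0.05): edge (i,j) is
#'   pruned when `MI(i,j) < (1 - tol) * min(MI(i,k), MI(j,k))` for some k.
#' @param n_trees trees per target for `tree_importance` (default 100).
#' @param min_node minimal node size for tree splits (default 5).
#' @param n_subsample subsamples for `stability_regression` (default 50).
#' @param top_lambdas number of leading lambdas of the path in which a TF
#'   counts as selected (default 5).
#' @return numeric matrix (TFs x genes) of class `edge_score_matrix` with
#'   attribute `method`.
#' @export
score_edges <- function(m, tfs,
                        method = c("mi_dpi", "tree_importance",
                                   "stability_regression"),
                        seed = 1, mi_bins = NULL, dpi_tolerance = 0.05,
                        n_trees = 100, min_node = 5,
                        n_subsample = 50, top_lambdas = 5) {
  method <- match.arg(method)
  x <- m$values
  genes <- rownames(x)
  if (!all(tfs %in% genes)) {
    stop("unknown TF id(s): ", paste(setdiff(tfs, genes), collapse = ", "))
  }
  if (ncol(x) < 10) stop("edge scoring needs >= 10 samples")
  const <- apply(x, 1, stats::sd) == 0
  if (any(const)) {
    warning("constant gene(s) scored 0: ",
            paste(genes[const], collapse = ", "))
  }
  scores <- switch(method,
                   mi_dpi = score_mi_dpi(x, tfs, mi_bins, dpi_tolerance),
                   tree_importance = score_trees(x, tfs, seed, n_trees, min_node),
                   stability_regression = score_stability(x, tfs, seed,
                                                          n_subsample,
                                                          top_lambdas))
  scores[tfs[tfs %in% genes[const]], ] <- 0
  scores[, genes[const]][!is.na(scores[, genes[const]])] <- 0
  for (tf in tfs) scores[tf, tf] <- NA  # self-edges undefined
  structure(scores, method = method, class = c("edge_score_matrix", "matrix",
                                               "array"))
}

# Plug-in mutual information on equal-frequency bins, all gene pairs; DPI
# pruning uses the full gene-gene MI matrix so indirect TF->grandchild edges
# can be explained away by the intermediate gene.
score_mi_dpi <- function(x, tfs, mi_bins, dpi_tolerance) {
  n <- ncol(x)
  g <- nrow(x)
  b <- mi_bins %||% (ceiling(log2(n)) + 1)
  disc <- t(apply(x, 1, function(v) {
    as.integer(cut(rank(v, ties.method = "first"),
                   breaks = seq(0, n, length.out = b + 1), labels = FALSE))
  }))
  mi <- matrix(0, g, g, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    tab <- table(disc[i, ], disc[j, ]) / n
    pi_ <- rowSums(tab); pj <- colSums(tab)
    nz <- tab > 0
    mi[i, j] <- mi[j, i] <- sum(tab[nz] * log(tab[nz] / outer(pi_, pj)[nz]))
  }
  keep <- matrix(TRUE, g, g)
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    others <- setdiff(seq_len(g), c(i, j))
    if (any(mi[i, j] < (1 - dpi_tolerance) * pmin(mi[i, others], mi[j, others]))) {
      keep[i, j] <- keep[j, i] <- FALSE
    }
  }
  mi[!keep] <- NA
  mi[tfs, , drop = FALSE]
}

# Extremely randomized trees, regression mode: split candidates are `mtry`
# random features with one uniform random threshold each; the best by
# variance reduction wins. Importance = summed variance reduction.
score_trees <- function(x, tfs, seed, n_trees, min_node) {
  genes <- rownames(x)
  out <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  for (gi in seq_along(genes)) {
    target <- genes[gi]
    preds <- setdiff(tfs, target)
    if (length(preds) == 0) next
    set.seed(derive_seed(seed, gi))
    X <- t(x[preds, , drop = FALSE])
    y <- x[target, ]
    imp <- stats::setNames(numeric(length(preds)), preds)
    mtry <- max(1L, floor(sqrt(length(preds))))
    for (t in seq_len(n_trees)) {
      idx <- sample.int(length(y), replace = TRUE)
      imp <- imp + grow_tree(X[idx, , drop = FALSE], y[idx], mtry, min_node)
    }
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    out[preds, gi] <- imp
  }
  out
}

# One extra-tree; returns per-feature variance reduction. Iterative stack to
# avoid deep recursion.
grow_tree <- function(X, y, mtry, min_node) {
  p <- ncol(X)
  imp <- stats::setNames(numeric(p), colnames(X))
  stack <- list(seq_along(y))
  while (length(stack)) {
    rows <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- length(rows)
    if (n < min_node) next
    yv <- y[rows]
    v0 <- stats::var(yv) * (n - 1)
    if (!is.finite(v0) || v0 <= 0) next
    feats <- sample.int(p, min(mtry, p))
    best <- NULL
    for (f in feats) {
      xv <- X[rows, f]
      r <- range(xv)
      if (r[1] == r[2]) next
      thr <- stats::runif(1, r[1], r[2])
      left <- xv <= thr
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      vl <- if (nl > 1) stats::var(yv[left]) * (nl - 1) else 0
      vr <- if (n - nl > 1) stats::var(yv[!left]) * (n - nl - 1) else 0
      gain <- v0 - vl - vr
      if (is.null(best) || gain > best$gain) {
        best <- list(f = f, thr = thr, left = left, gain = gain)
      }
    }
    if (is.null(best) || best$gain <= 0) next
    imp[best$f] <- imp[best$f] + best$gain
    stack[[length(stack) + 1]] <- rows[best$left]
    stack[[length(stack) + 1]] <- rows[!best$left]
  }
  imp
}

# Stability selection on the lasso path: half-sample subsamples with random
# feature reweighting; a TF is selected in one subsample when its coefficient
# is nonzero in any of the first `top_lambdas` lambdas of the path.
score_stability <- function(x, tfs, seed, n_subsample, top_lambdas) {
  genes <- rownames(x)
  n <- ncol(x)
  out <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  for (gi in seq_along(genes)) {
    target <- genes[gi]
    preds <- setdiff(tfs, target)
    if (length(preds) < 2) next  # glmnet needs >= 2 predictors
    set.seed(derive_seed(seed, gi))
    X <- t(x[preds, , drop = FALSE])
    y <- x[target, ]
    if (stats::sd(y) == 0) next
    freq <- stats::setNames(numeric(length(preds)), preds)
    for (s in seq_len(n_subsample)) {
      rows <- sample.int(n, floor(n / 2))
      wts <- stats::runif(length(preds), 0.2, 1)
      Xs <- sweep(X[rows, , drop = FALSE], 2, wts, `*`)
      fit <- tryCatch(
        glmnet::glmnet(Xs, y[rows], family = "gaussian", nlambda = 25,
                       standardize = TRUE),
        error = function(e) NULL)
      if (is.null(fit)) next
      k <- min(top_lambdas, length(fit$lambda))
      beta <- fit$beta[, seq_len(k), drop = FALSE]
      freq <- freq + (Matrix::rowSums(abs(beta)) > 0)
    }
    out[preds, gi] <- freq / n_subsample
  }
  out
}
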