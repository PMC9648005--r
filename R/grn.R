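#' Gene-by-sample expression matrix with batch/phenotype annotations
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @param batch per-sample batch labels (factor or character).
#' @param phenotype optional per-sample phenotype labels (e.g. `"OA"` /
#'   `"WT"`).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, batch = NULL, phenotype = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (anyNA(values)) stop("no missing values allowed after assembly")
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  n <- ncol(values)
  if (is.null(batch)) batch <- rep("batch1", n)
  batch <- factor(batch)
  if (length(batch) != n) stop("batch must have one label per sample")
  if (!is.null(phenotype)) {
    phenotype <- factor(phenotype)
    if (length(phenotype) != n) stop("phenotype must have one label per sample")
  }
  structure(list(values = values, batch = batch, phenotype = phenotype),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, %d batch(es)%s\n",
              nrow(x$values), ncol(x$values), nlevels(x$batch),
              if (is.null(x$phenotype)) "" else
                paste0(", phenotypes: ",
                       paste(levels(x$phenotype), collapse = "/"))))
  invisible(x)
}

#' Read an expression matrix from CSV/TSV with an annotation sidecar
#'
#' The main file holds genes in rows and samples in columns (first column =
#' gene id). The sidecar CSV has columns `sample`, `batch` and optionally
#' `phenotype`.
#'
#' @param path matrix file (.csv or .tsv by extension).
#' @param annotation path to the sample-annotation CSV (optional).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, annotation = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE)
  batch <- NULL; phenotype <- NULL
  if (!is.null(annotation)) {
    ann <- utils::read.csv(annotation, stringsAsFactors = FALSE)
    idx <- match(colnames(tab), ann$sample)
    if (anyNA(idx)) stop("annotation is missing sample(s): ",
                         paste(colnames(tab)[is.na(idx)], collapse = ", "))
    batch <- ann$batch[idx]
    phenotype <- ann$phenotype[idx]
  }
  expression_matrix(as.matrix(tab), batch = batch, phenotype = phenotype)
}

#' Write an expression matrix (and its annotation sidecar)
#'
#' @param m an [expression_matrix()].
#' @param path output matrix file (.csv or .tsv by extension).
#' @param annotation output annotation CSV path (default `<stem>.samples.csv`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, annotation = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  annotation <- annotation %||% paste0(sub("\\.[^.]+$", "", path), ".samples.csv")
  ann <- data.frame(sample = colnames(m$values), batch = as.character(m$batch))
  if (!is.null(m$phenotype)) ann$phenotype <- as.character(m$phenotype)
  utils::write.csv(ann, annotation, row.names = FALSE)
  invisible(path)
}

#' Quantile normalization
#'
#' Forces every sample column onto the identical empirical distribution: the
#' reference distribution of mean order statistics. Ties within a column
#' receive the average of the reference values they span.
#'
#' @param m an [expression_matrix()] with at least 2 samples.
#' @return the normalized `expression_matrix`.
#' @export
quantile_normalize <- function(m) {
  x <- m$values
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  if (nrow(x) == 0) stop("empty matrix")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # fractional ranks from ties: average the two flanking reference values
    lo <- ref[floor(rk)]
    hi <- ref[ceiling(rk)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(x)
  m$values <- out
  m
}

#' Empirical-Bayes batch correction (ComBat-style)
#'
#' Removes additive (location) and multiplicative (scale) batch effects per
#' gene: genes are standardized against a batch-design fit, per-batch
#' location and scale parameters are shrunk towards their across-gene priors
#' (normal prior for location, inverse-gamma for scale, both fit by the
#' method of moments), and the adjusted values are returned on the original
#' scale. After adjustment every gene is re-anchored to its pooled
#' (pre-correction) mean, so the pooled mean is preserved exactly.
#' Single-batch input is returned unchanged.
#'
#' @param m an [expression_matrix()] with batch labels; every batch needs at
#'   least 2 samples.
#' @param eb use empirical-Bayes shrinkage (default); `FALSE` uses the raw
#'   per-batch estimates.
#' @return the corrected `expression_matrix`.
#' @export
correct_batch <- function(m, eb = TRUE) {
  batch <- m$batch
  if (nlevels(batch) < 2) return(m)
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop("batch(es) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  x <- m$values
  g <- nrow(x)
  batches <- levels(batch)
  nb <- length(batches)
  n <- ncol(x)

  pooled_mean <- rowMeans(x)
  # grand mean as the batch-size weighted mean of batch means
  bm <- sapply(batches, function(b) rowMeans(x[, batch == b, drop = FALSE]))
  bm <- matrix(bm, nrow = g)
  w <- as.numeric(sizes[batches]) / n
  alpha <- as.vector(bm %*% w)
  # pooled within-design variance
  resid <- x - bm[, as.integer(factor(batch, levels = batches)), drop = FALSE]
  sigma2 <- rowSums(resid^2) / n
  sigma2[sigma2 <= 0] <- min(sigma2[sigma2 > 0], 1e-8)
  z <- (x - alpha) / sqrt(sigma2)

  out_z <- z
  for (b in batches) {
    cols <- batch == b
    nbatch <- sum(cols)
    gamma_hat <- rowMeans(z[, cols, drop = FALSE])
    delta_hat <- apply(z[, cols, drop = FALSE], 1, stats::var)
    delta_hat[delta_hat <= 0] <- 1e-8
    if (eb && g >= 2) {
      # normal prior on location
      gbar <- mean(gamma_hat)
      t2 <- stats::var(gamma_hat)
      # inverse-gamma prior on scale, method of moments
      dbar <- mean(delta_hat)
      s2 <- stats::var(delta_hat)
      a_prior <- if (s2 > 0) (2 * s2 + dbar^2) / s2 else Inf
      b_prior <- if (s2 > 0) (dbar * s2 + dbar^3) / s2 else 0
      # one-step parametric EB (non-iterative posterior estimates)
      if (t2 > 0) {
        gamma_star <- (nbatch * t2 * gamma_hat + delta_hat * gbar) /
          (nbatch * t2 + delta_hat)
      } else gamma_star <- rep(gbar, g)
      ss <- rowSums((z[, cols, drop = FALSE] - gamma_star)^2)
      delta_star <- if (is.finite(a_prior)) {
        (b_prior + ss / 2) / (a_prior + nbatch / 2 - 1)
      } else delta_hat
      delta_star[delta_star <= 0] <- 1e-8
    } else {
      gamma_star <- gamma_hat
      delta_star <- delta_hat
    }
    out_z[, cols] <- (z[, cols, drop = FALSE] - gamma_star) / sqrt(delta_star)
  }
  out <- out_z * sqrt(sigma2) + alpha
  out <- out - (rowMeans(out) - pooled_mean)  # exact pooled-mean anchor
  m$values <- out
  m
}

#' Clustering quality control of a merged expression matrix
#'
#' Hierarchical clustering of samples (Euclidean distance, complete linkage),
#' tree cut into `n_groups` groups, each group labeled by its majority
#' phenotype. Reports, per phenotype, the fraction of its samples landing in
#' groups labeled with that phenotype -- the "correctly identified" rate used
#' to check that biological signal survives merging and correction.
#'
#' @param m an [expression_matrix()] with phenotype labels.
#' @param n_groups number of groups to cut the tree into (default 3).
#' @return list with `accuracy` (named per-phenotype fraction), `groups`
#'   (per-sample group index) and `group_labels` (majority phenotype per
#'   group).
#' @export
cluster_qc <- function(m, n_groups = 3) {
  if (is.null(m$phenotype)) stop("phenotype labels required")
  if (n_groups > ncol(m$values)) stop("n_groups exceeds the number of samples")
  hc <- stats::hclust(stats::dist(t(m$values), method = "euclidean"),
                      method = "complete")
  grp <- stats::cutree(hc, k = n_groups)
  glab <- vapply(seq_len(n_groups), function(k) {
    tab <- table(m$phenotype[grp == k])
    names(tab)[which.max(tab)]
  }, "")
  acc <- vapply(levels(m$phenotype), function(ph) {
    inph <- m$phenotype == ph
    mean(glab[grp[inph]] == ph)
  }, 0)
  list(accuracy = acc, groups = grp, group_labels = glab)
}
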