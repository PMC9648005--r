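#' Built-in toy networks
#'
#' Small, fully ruled networks with known dynamics, used throughout the test
#' suite and as worked examples.
#'
#' * `toggle_switch`: two components A, B (fast layer only), each
#'   self-activating and inhibiting the other, saturation 0.5 (gain 2).
#'   Exactly three fixed points: (0,0), (1,0) and (0,1); the all-zero state
#'   has a measure-zero basin (only the diagonal A = B reaches it), so random
#'   initializations split between the two polarized states.
#' * `chain`: a directed activation chain C1 -> C2 -> ... -> Cn (fast layer),
#'   C1 an input; for a clamped input level there is a unique fixed point with
#'   every downstream component at the clamped level.
#' * `random_layered`: a seed-deterministic random two-layer network: every
#'   component has a fast rule with 1-3 random signed regulators, a random
#'   subset also carries a slow rule.
#'
#' @param kind one of `"toggle_switch"`, `"chain"`, `"random_layered"`.
#' @param n_components number of components (`chain`/`random_layered`).
#' @param seed RNG seed (`random_layered`).
#' @param saturation saturation constant for synthesized rules.
#' @param slow_fraction fraction of components given a slow-layer rule
#'   (`random_layered`).
#' @return a [layered_network()].
#' @export
make_fixture <- function(kind = c("toggle_switch", "chain", "random_layered"),
                         n_components = 3, seed = 1, saturation = NULL,
                         slow_fraction = 0.5) {
  kind <- match.arg(kind)
  switch(kind,
    toggle_switch = {
      sat <- saturation %||% 0.5
      comp <- data.frame(id = c("A", "B"), role = "transcription_factor",
                         stringsAsFactors = FALSE)
      ints <- data.frame(
        source = c("A", "B", "B", "A"),
        target = c("A", "A", "B", "B"),
        sign = c(1L, -1L, 1L, -1L),
        layer = "fast", provenance = "curated", stringsAsFactors = FALSE)
      layered_network(comp, ints, metadata = list(name = "toggle_switch"),
                      saturation_default = sat)
    },
    chain = {
      stopifnot(n_components >= 1)
      sat <- saturation %||% 1
      ids <- paste0("C", seq_len(n_components))
      comp <- data.frame(id = ids, stringsAsFactors = FALSE)
      ints <- if (n_components > 1) {
        data.frame(source = ids[-n_components], target = ids[-1],
                   sign = 1L, layer = "fast", provenance = "curated",
                   stringsAsFactors = FALSE)
      } else NULL
      layered_network(comp, ints, metadata = list(name = "chain"),
                      saturation_default = sat)
    },
    random_layered = {
      stopifnot(n_components >= 2)
      sat <- saturation %||% 1
      set.seed(seed)
      ids <- paste0("G", seq_len(n_components))
      has_slow <- c(TRUE, stats::runif(n_components - 1) < slow_fraction)
      rows <- list()
      for (i in seq_len(n_components)) {
        k <- sample(1:min(3, n_components - 1), 1)
        src <- sample(setdiff(seq_len(n_components), i), k)
        rows[[length(rows) + 1]] <- data.frame(
          source = ids[src], target = ids[i],
          sign = sample(c(1L, -1L), k, replace = TRUE, prob = c(0.7, 0.3)),
          layer = "fast", provenance = "curated", stringsAsFactors = FALSE)
        if (has_slow[i]) {
          j <- sample(setdiff(seq_len(n_components), i), 1)
          rows[[length(rows) + 1]] <- data.frame(
            source = ids[j], target = ids[i],
            sign = sample(c(1L, -1L), 1, prob = c(0.8, 0.2)),
            layer = "slow", provenance = "curated", stringsAsFactors = FALSE)
        }
      }
      layered_network(data.frame(id = ids, stringsAsFactors = FALSE),
                      do.call(rbind, rows),
                      metadata = list(name = sprintf("random_layered_s%d", seed)),
                      saturation_default = sat)
    })
}

#' Exhaustive grid search for stable states
#'
#' Brute-force oracle for the Monte Carlo attractor machinery: enumerates the
#' full grid over all free sub-variables (non-input, unclamped, present
#' layers) and returns every grid point that passes [is_stable()]. Inputs
#' must be clamped (an unclamped input holds any value, giving a continuum of
#' fixed points). Intentionally limited to 4 free sub-variables so the grid
#' stays small; fixed points that do not lie on the grid are missed -- a
#' documented limitation of the oracle.
#'
#' @param net a `layered_network`.
#' @param grid_step grid resolution in `[0, 1]` (default 0.05).
#' @param clamps named clamp vector; must cover all input components.
#' @param config an [engine_config()].
#' @return list of stable `system_state` objects.
#' @export
brute_force_attractors <- function(net, grid_step = 0.05, clamps = NULL,
                                   config = engine_config()) {
  unclamped <- Filter(function(r) !(r$target %in% names(clamps)), net$rules)
  if (length(unclamped) > 4) {
    stop("network too large for the grid oracle (> 4 free sub-variables)")
  }
  free <- list()
  for (r in unclamped) {
    if (nrow(r$terms) == 0) {
      stop("input component '", r$target, "' must be clamped for the grid oracle")
    }
    free[[length(free) + 1]] <- c(r$target, r$layer)
  }
  grid <- seq(0, 1, by = grid_step)
  pts <- do.call(expand.grid, rep(list(grid), length(free)))
  out <- list()
  for (i in seq_len(nrow(pts))) {
    fast <- numeric(0); slow <- numeric(0)
    for (j in seq_along(free)) {
      if (free[[j]][2] == "fast") fast[free[[j]][1]] <- pts[i, j]
      else slow[free[[j]][1]] <- pts[i, j]
    }
    st <- system_state(net, fast = fast, slow = slow, clamp = clamps, default = 1)
    if (is_stable(net, st, config)) out[[length(out) + 1]] <- st
  }
  out
}

#' Synthetic multi-batch expression data with known regulatory structure
#'
#' Emulates a cross-platform merged microarray compendium: a linear-Gaussian
#' network (TFs as roots, signed weighted edges, acyclic by construction)
#' generates gene profiles; a phenotype contrast (OA-like vs WT-like) shifts
#' designated components; per-batch location and scale distortions mimic
#' platform effects. The generator returns the planted edge list, so
#' inference recovery can be scored against ground truth.
#'
#' @param n_genes total genes (first `n_tfs` are transcription factors).
#' @param n_tfs number of regulator genes.
#' @param n_samples number of samples.
#' @param n_batches number of batches (samples split evenly).
#' @param noise_sd intrinsic Gaussian noise sd on every gene (signal scale 1).
#' @param batch_shift sd of per-gene per-batch location offsets.
#' @param batch_scale sd of per-gene per-batch log-scale distortions.
#' @param phenotype_effect mean shift applied to `phenotype_components` in
#'   OA-like samples.
#' @param phenotype_components gene indices carrying the group signal
#'   (defaults to the first two TFs).
#' @param parents_per_gene 1 or 2 TF parents per non-TF gene (sampled).
#' @param seed RNG seed.
#' @return list with `matrix` (an [expression_matrix()]) and `edges`
#'   (data.frame `source`, `target`, `sign`, `weight` of planted direct
#'   regulations).
#' @export
simulate_expression <- function(n_genes = 20, n_tfs = 5, n_samples = 200,
                                n_batches = 2, noise_sd = 0.3,
                                batch_shift = 1, batch_scale = 0.25,
                                phenotype_effect = 1,
                                phenotype_components = seq_len(min(2, n_tfs)),
                                parents_per_gene = c(1, 2), seed = 1) {
  stopifnot(n_tfs >= 1, n_genes > n_tfs, n_samples >= 4, n_batches >= 1,
            noise_sd >= 0)
  set.seed(seed)
  genes <- c(paste0("TF", seq_len(n_tfs)),
             paste0("G", seq_len(n_genes - n_tfs)))
  batch <- factor(rep_len(paste0("batch", seq_len(n_batches)), n_samples))
  phenotype <- factor(rep_len(c("WT", "OA"), n_samples), levels = c("WT", "OA"))

  # planted DAG: TF -> TF chain edge (if >= 2 TFs), TFs -> target genes
  edges <- list()
  if (n_tfs >= 2) {
    edges[[1]] <- data.frame(source = "TF1", target = "TF2",
                             sign = 1L, stringsAsFactors = FALSE)
  }
  for (g in genes[(n_tfs + 1):n_genes]) {
    k <- sample(parents_per_gene, 1)
    pa <- sample(genes[seq_len(n_tfs)], k)
    edges[[length(edges) + 1]] <- data.frame(
      source = pa, target = g,
      sign = sample(c(1L, -1L), k, replace = TRUE, prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  edges$weight <- stats::runif(nrow(edges), 0.7, 1.2)

  x <- matrix(0, n_genes, n_samples, dimnames = list(genes, NULL))
  shift <- ifelse(phenotype == "OA", phenotype_effect, 0)
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    pa <- edges[edges$target == g, , drop = FALSE]
    base <- if (nrow(pa) == 0) stats::rnorm(n_samples) else {
      colSums(x[pa$source, , drop = FALSE] * (pa$sign * pa$weight)) +
        stats::rnorm(n_samples, sd = noise_sd)
    }
    if (i %in% phenotype_components) base <- base + shift
    x[i, ] <- base
  }

  # per-batch location/scale distortion (platform effect); the first batch
  # is the undistorted reference, so single-batch data stays on the clean
  # generative scale
  for (b in levels(batch)[-1]) {
    cols <- batch == b
    loc <- stats::rnorm(n_genes, 0, batch_shift)
    scl <- exp(stats::rnorm(n_genes, 0, batch_scale))
    x[, cols] <- x[, cols] * scl + loc
  }
  colnames(x) <- paste0("s", seq_len(n_samples))

  list(matrix = expression_matrix(x, batch = batch, phenotype = phenotype),
       edges = edges)
}
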