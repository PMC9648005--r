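#' Phenotype signature
#'
#' A phenotype is recognized on an attractor's global-activity profile by a
#' set of marker components required near 1 (`high`) and a set required near
#' 0 (`low`), with a band defining "near": high markers must exceed
#' `1 - band`, low markers must fall below `band`.
#'
#' @param label phenotype name (e.g. `"Healthy"`, `"Hypertrophic"`, `"None"`).
#' @param high,low character vectors of component ids (disjoint).
#' @param band tolerance for "near" (default 0.2).
#' @return a list of class `phenotype_signature`.
#' @export
phenotype_signature <- function(label, high = character(), low = character(),
                                band = 0.2) {
  if (length(intersect(high, low))) stop("high and low marker sets must be disjoint")
  stopifnot(band > 0, band < 0.5)
  structure(list(label = label, high = high, low = low, band = band),
            class = "phenotype_signature")
}

#' Read phenotype signatures from a YAML file
#'
#' The file is a list of entries with fields `label`, `high`, `low` and
#' optional `band`. Signatures are configuration, not code: the chondrocyte
#' defaults (SOX9/NKX3.2/COL-II high for Healthy; RUNX2/COL-X/MMP13/IHH high
#' for Hypertrophic; everything low for None) ship as
#' `inst/extdata/chondrocyte_signatures.yaml` and can be edited freely.
#'
#' @param path YAML file.
#' @return list of [phenotype_signature()] objects.
#' @export
read_signatures <- function(path) {
  lapply(yaml::read_yaml(path), function(x) {
    phenotype_signature(x$label, unlist(x$high) %||% character(),
                        unlist(x$low) %||% character(), x$band %||% 0.2)
  })
}

#' Classify an attractor profile against phenotype signatures
#'
#' Returns the unique signature satisfied by the profile, `"Unknown"` when
#' none matches, and errors when two or more match (ambiguous signatures).
#'
#' @param attractor an attractor (list with a `global` named vector) or a
#'   plain named numeric profile of global activities.
#' @param signatures list of [phenotype_signature()] objects.
#' @return the matching label (character).
#' @export
classify_attractor <- function(attractor, signatures) {
  profile <- if (is.numeric(attractor)) attractor else attractor$global
  hits <- vapply(signatures, function(sg) {
    miss <- setdiff(c(sg$high, sg$low), names(profile))
    if (length(miss)) stop("signature '", sg$label,
                           "' references unknown component(s): ",
                           paste(miss, collapse = ", "))
    all(profile[sg$high] > 1 - sg$band) && all(profile[sg$low] < sg$band)
  }, TRUE)
  if (sum(hits) > 1) {
    stop("ambiguous classification: profile satisfies ",
         paste(vapply(signatures[hits], `[[`, "", "label"), collapse = " and "))
  }
  if (any(hits)) signatures[[which(hits)]]$label else "Unknown"
}

#' Group stable states by profile similarity
#'
#' Single-linkage grouping under the criterion "max componentwise absolute
#' difference of global activities <= tol" (the same tolerance used for
#' convergence). States are first collapsed onto a tol/10 grid -- converged
#' finals pile up on their attractors, so the number of distinct rounded
#' profiles stays small -- then linked exactly. The representative of a group
#' is the componentwise (count-weighted) mean of its members.
#'
#' @param states list of `system_state` objects (or named global-activity
#'   vectors).
#' @param tol grouping tolerance (default 1e-2).
#' @param profile `"global"` groups on global activities (default);
#'   `"sub"` on the concatenated fast/slow sub-variables.
#' @return list of groups, each a list with `representative` (named numeric),
#'   `fast`/`slow` mean sub-profiles when available, and `count`.
#' @export
group_states <- function(states, tol = 1e-2, profile = c("global", "sub")) {
  profile <- match.arg(profile)
  if (length(states) == 0) return(list())
  as_prof <- function(st) {
    if (is.numeric(st)) return(st)
    if (profile == "global") global_activity(st)
    else c(stats::setNames(st$fast, paste0(names(st$fast), ".fast")),
           stats::setNames(st$slow, paste0(names(st$slow), ".slow")))
  }
  profs <- do.call(rbind, lapply(states, as_prof))
  keys <- apply(round(profs / (tol / 10)), 1, paste, collapse = ",")
  uk <- !duplicated(keys)
  reps <- profs[uk, , drop = FALSE]
  map <- match(keys, keys[uk])
  counts <- tabulate(map, nbins = nrow(reps))

  # exact single linkage on the collapsed representatives
  m <- nrow(reps)
  cluster <- seq_len(m)
  if (m > 1) {
    d <- as.matrix(stats::dist(reps, method = "maximum"))
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (d[i, j] <= tol && cluster[i] != cluster[j]) {
        cluster[cluster == cluster[j]] <- cluster[i]
      }
    }
  }
  out <- list()
  for (cl in unique(cluster)) {
    sel <- which(map %in% which(cluster == cl))
    w <- length(sel)
    rep_prof <- colSums(profs[sel, , drop = FALSE]) / w
    grp <- list(representative = rep_prof, count = w)
    if (!is.numeric(states[[1]])) {
      fmat <- do.call(rbind, lapply(states[sel], function(s) global_activity(s)))
      grp$representative <- colMeans(fmat)
      grp$fast <- colMeans(do.call(rbind, lapply(states[sel], `[[`, "fast")))
      grp$slow <- colMeans(do.call(rbind, lapply(states[sel], `[[`, "slow")))
    }
    out[[length(out) + 1]] <- grp
  }
  out[order(vapply(out, `[[`, 0L, "count"), decreasing = TRUE)]
}

#' Monte Carlo attractor discovery (canalization analysis)
#'
#' Samples `n_init` random initial states (each unclamped sub-variable i.i.d.
#' uniform on `[0, 1]`), simulates each to convergence, groups the converged
#' finals with [group_states()] and reports each attractor's basin fraction.
#' Clamped components (e.g. growth-factor profiles) keep their clamp level
#' throughout. Unconverged runs are counted in `unconverged_fraction`, never
#' raised. Deterministic given the master seed: replicate `i` uses the child
#' seed `derive_seed(seed, i)`.
#'
#' @param net a `layered_network`.
#' @param n_init number of random initializations (the reference analysis
#'   uses 10,000; basin estimates are insensitive to `n_init` well below
#'   that).
#' @param clamps named clamp vector (input profile), or `NULL`.
#' @param config an [engine_config()]; its `seed` is the master seed.
#' @param signatures optional list of [phenotype_signature()]; when given,
#'   each attractor is labeled, otherwise labels are `"Unknown"`.
#' @param group_tol grouping tolerance (default: the engine tolerance).
#' @return list of class `canalization_result`: `attractors` (each with
#'   `label`, `global`, `fast`, `slow`, `basin_fraction`, `support`),
#'   `n_init`, `clamps`, `unconverged_fraction`.
#' @export
monte_carlo <- function(net, n_init = 1000, clamps = NULL,
                        config = engine_config(), signatures = NULL,
                        group_tol = config$tolerance) {
  stopifnot(n_init >= 1)
  master <- config$seed %||% 1L
  finals <- list()
  n_unconv <- 0L
  for (i in seq_len(n_init)) {
    cfg <- config
    cfg$seed <- derive_seed(master, i)
    set.seed(cfg$seed)
    init <- random_state(net, clamps)
    cfg$seed <- NULL  # RNG already seeded; keep the sampling stream
    tr <- simulate_network(net, init, clamps = clamps, config = cfg)
    if (tr$converged) finals[[length(finals) + 1]] <- tr$final
    else n_unconv <- n_unconv + 1L
  }
  groups <- group_states(finals, tol = group_tol)
  attractors <- lapply(groups, function(g) {
    label <- if (is.null(signatures)) "Unknown"
             else classify_attractor(g$representative, signatures)
    list(label = label, global = g$representative,
         fast = g$fast, slow = g$slow,
         basin_fraction = g$count / n_init, support = g$count)
  })
  structure(list(attractors = attractors, n_init = n_init,
                 clamps = clamps, unconverged_fraction = n_unconv / n_init),
            class = "canalization_result")
}

# Random initial state: unclamped present-layer sub-variables ~ U[0,1].
random_state <- function(net, clamps = NULL) {
  comp <- net$components
  free <- !(comp$id %in% names(clamps))
  fast <- stats::setNames(stats::runif(sum(comp$has_fast & free)),
                          comp$id[comp$has_fast & free])
  slow <- stats::setNames(stats::runif(sum(comp$has_slow & free)),
                          comp$id[comp$has_slow & free])
  system_state(net, fast = fast, slow = slow, clamp = clamps, default = 1)
}

#' @export
print.canalization_result <- function(x, ...) {
  cat(sprintf("<canalization_result> %d initializations, %d attractor(s), %.1f%% unconverged\n",
              x$n_init, length(x$attractors), 100 * x$unconverged_fraction))
  for (a in x$attractors) {
    cat(sprintf("  %-14s basin %5.1f%%  (n=%d)\n", a$label,
                100 * a$basin_fraction, a$support))
  }
  invisible(x)
}

#' Turn a canalization result into a basin table
#'
#' @param x a `canalization_result`.
#' @return data.frame with columns `label`, `basin_pct`, `support`.
#' @export
basin_table <- function(x) {
  data.frame(label = vapply(x$attractors, `[[`, "", "label"),
             basin_pct = 100 * vapply(x$attractors, `[[`, 0, "basin_fraction"),
             support = vapply(x$attractors, `[[`, 0L, "support"),
             stringsAsFactors = FALSE)
}
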