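#' Perturbation condition
#'
#' A set of components clamped to fixed global-activity levels for a finite
#' number of update steps (0 = inhibition, 1 = activation, intermediate
#' levels allowed), after which the system is released and left to evolve
#' freely.
#'
#' @param clamps named numeric vector of clamp levels in `[0, 1]`.
#' @param duration number of update steps the clamp is held (default 1000;
#'   the perturbed regime is typically reached well within 200 steps, so
#'   longer clamps do not change the outcome).
#' @param source_state label or profile of the attractor the perturbation
#'   starts from (informational).
#' @return a list of class `perturbation_condition`.
#' @export
perturbation_condition <- function(clamps, duration = 1000, source_state = NULL) {
  stopifnot(length(clamps) >= 1, !is.null(names(clamps)),
            all(clamps >= 0 & clamps <= 1), duration > 0)
  structure(list(clamps = clamps, duration = duration,
                 source_state = source_state),
            class = "perturbation_condition")
}

condition_id <- function(cond) {
  paste0(names(cond$clamps), "=", format(cond$clamps, trim = TRUE),
         collapse = ",")
}

# Match a final state to one of the known basal attractors (max-norm within
# tol on global activities); "Unknown" for unconverged runs or novel states.
match_destination <- function(final, attractors, tol) {
  ga <- global_activity(final)
  for (a in attractors) {
    if (max(abs(ga[names(a$global)] - a$global)) <= tol) return(a$label)
  }
  "Unknown"
}

attractor_state <- function(net, attractor) {
  system_state(net, fast = attractor$fast, slow = attractor$slow)
}

# Release a perturbation: drop the clamp overrides and leave each released
# component at its imposed level. If the frozen sub-variables already realize
# the clamp level (a no-op perturbation), they are kept untouched -- which
# makes "clamp at the attractor value" an exact identity; otherwise the fast
# sub-variable takes the level (slow-only components take it on the slow
# side) so the forced activity carries into the free phase.
release_clamps <- function(net, state, clamps) {
  comp <- net$components
  for (nm in names(clamps)) {
    lv <- clamps[[nm]]
    if (abs(state$fast[[nm]] * state$slow[[nm]] - lv) < 1e-12) next
    if (comp$has_fast[comp$id == nm]) {
      state$fast[[nm]] <- lv
      state$slow[[nm]] <- 1
    } else {
      state$slow[[nm]] <- lv
    }
  }
  state$clamp <- state$clamp[setdiff(names(state$clamp), names(clamps))]
  state
}

#' Run one perturbation condition
#'
#' Each repetition starts at the source attractor, holds the clamps for
#' `duration` update steps (stopping early if the clamped system stabilizes,
#' which is equivalent: further clamped updates are no-ops), releases the
#' clamps, simulates to convergence, and matches the final state to one of
#' the basal attractors. Percentages of repetitions per destination are
#' returned; the whole block of `n_reps` repetitions is repeated
#' `n_experiments` times to report mean and standard deviation.
#'
#' @param net a `layered_network`.
#' @param attractor the source attractor (list with `label`, `fast`, `slow`,
#'   `global`), e.g. from [monte_carlo()].
#' @param cond a [perturbation_condition()].
#' @param attractors list of all basal attractors used to classify
#'   destinations.
#' @param n_reps repetitions per experiment (default 100).
#' @param n_experiments independent repetitions of the whole block
#'   (default 3).
#' @param config an [engine_config()]; its `seed` seeds the condition.
#' @param group_tol destination-matching tolerance.
#' @return a list of class `transition_outcome`: `condition`, `n_reps`,
#'   `n_experiments`, `pct_to` (mean percentage per destination label, sums
#'   to 100), `sd_to` (SD over experiments), `per_experiment` matrix.
#' @export
run_condition <- function(net, attractor, cond, attractors,
                          n_reps = 100, n_experiments = 3,
                          config = engine_config(),
                          group_tol = config$tolerance) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  stopifnot(n_experiments >= 1, inherits(cond, "perturbation_condition"))
  check_components(names(cond$clamps), net$components$id)
  labels <- unique(c(vapply(attractors, `[[`, "", "label"), "Unknown"))
  master <- config$seed %||% 1L
  src <- attractor_state(net, attractor)

  per_exp <- matrix(0, n_experiments, length(labels),
                    dimnames = list(NULL, labels))
  for (e in seq_len(n_experiments)) {
    counts <- stats::setNames(numeric(length(labels)), labels)
    for (r in seq_len(n_reps)) {
      set.seed(derive_seed(master, (e - 1L) * n_reps + r))
      cfg1 <- config
      cfg1$seed <- NULL
      cfg1$max_total_steps <- cond$duration
      ph1 <- simulate_network(net, src, clamps = cond$clamps, config = cfg1)
      released <- release_clamps(net, ph1$final, cond$clamps)
      cfg2 <- config
      cfg2$seed <- NULL
      ph2 <- simulate_network(net, released, config = cfg2)
      dest <- if (!ph2$converged) "Unknown"
              else match_destination(ph2$final, attractors, group_tol)
      counts[dest] <- counts[dest] + 1
    }
    per_exp[e, ] <- 100 * counts / n_reps
  }
  structure(list(condition = cond,
                 source = attractor$label,
                 n_reps = n_reps, n_experiments = n_experiments,
                 pct_to = colMeans(per_exp),
                 sd_to = apply(per_exp, 2, stats::sd),
                 per_experiment = per_exp),
            class = "transition_outcome")
}

#' @export
print.transition_outcome <- function(x, ...) {
  cat(sprintf("<transition_outcome> %s from %s (%d reps x %d experiments)\n",
              condition_id(x$condition), x$source %||% "?", x$n_reps,
              x$n_experiments))
  for (l in names(x$pct_to)) {
    cat(sprintf("  -> %-14s %5.1f%% (sd %.1f)\n", l, x$pct_to[l], x$sd_to[l]))
  }
  invisible(x)
}

#' Enumerate single-perturbation conditions
#'
#' Every component clamped to each level (default 0 and 1): `2N` conditions.
#'
#' @param net a `layered_network`.
#' @param levels clamp levels per component.
#' @return data.frame with columns `component`, `level`, `id`.
#' @export
enumerate_single_conditions <- function(net, levels = c(0, 1)) {
  g <- expand.grid(component = net$components$id, level = levels,
                   stringsAsFactors = FALSE)
  g$id <- paste0(g$component, "=", format(g$level, trim = TRUE))
  g
}

#' Enumerate pairwise perturbation conditions
#'
#' Every unordered component pair times the four clamp-level combinations
#' {00, 01, 10, 11}: `C(N, 2) * 4 = 2N(N-1)` conditions.
#'
#' @inheritParams enumerate_single_conditions
#' @return data.frame with columns `comp1`, `comp2`, `level1`, `level2`, `id`.
#' @export
enumerate_pairwise_conditions <- function(net, levels = c(0, 1)) {
  ids <- net$components$id
  prs <- utils::combn(ids, 2)
  lv <- expand.grid(level1 = levels, level2 = levels)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    data.frame(comp1 = prs[1, i], comp2 = prs[2, i],
               level1 = lv$level1, level2 = lv$level2,
               stringsAsFactors = FALSE)
  }))
  out$id <- paste0(out$comp1, "=", format(out$level1, trim = TRUE), ",",
                   out$comp2, "=", format(out$level2, trim = TRUE))
  out
}

#' Systematic single-perturbation screen
#'
#' Runs [run_condition()] for every component clamped to 0 and to 1 from the
#' given source attractor.
#'
#' @inheritParams run_condition
#' @param levels clamp levels per component (default 0 and 1).
#' @return list of `transition_outcome` objects (one per condition), with a
#'   `screen_summary` data.frame attached as attribute `"summary"`.
#' @export
screen_single <- function(net, attractor, attractors, n_reps = 100,
                          n_experiments = 1, config = engine_config(),
                          levels = c(0, 1)) {
  conds <- enumerate_single_conditions(net, levels)
  master <- config$seed %||% 1L
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cond <- perturbation_condition(
      stats::setNames(conds$level[i], conds$component[i]),
      source_state = attractor$label)
    cfg <- config
    cfg$seed <- derive_seed(master, i)
    out[[i]] <- run_condition(net, attractor, cond, attractors,
                              n_reps = n_reps, n_experiments = n_experiments,
                              config = cfg)
  }
  attr(out, "summary") <- summarize_screen(out)
  out
}

summarize_screen <- function(outcomes) {
  labels <- unique(unlist(lapply(outcomes, function(o) names(o$pct_to))))
  rows <- lapply(outcomes, function(o) {
    v <- stats::setNames(numeric(length(labels)), labels)
    v[names(o$pct_to)] <- o$pct_to
    cbind(data.frame(condition = condition_id(o$condition),
                     source = o$source %||% NA_character_,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  do.call(rbind, rows)
}

#' Systematic pairwise-perturbation screen
#'
#' Runs every unordered pair of components under the four clamp combinations
#' {00, 01, 10, 11}. Results can stream to a JSON-lines file (one condition
#' per line, with its derived seed); when `resume = TRUE` and the file exists,
#' conditions already present are not recomputed, which makes interrupted
#' screens restartable and shardable.
#'
#' @inheritParams screen_single
#' @param out_file optional JSON-lines output path (streamed, append mode).
#' @param resume skip conditions already present in `out_file`?
#' @param conditions optional subset of the condition table (as returned by
#'   [enumerate_pairwise_conditions()]) to run.
#' @return list of `transition_outcome` objects with attribute `"summary"`.
#' @export
screen_pairwise <- function(net, attractor, attractors, n_reps = 100,
                            n_experiments = 1, config = engine_config(),
                            levels = c(0, 1), out_file = NULL, resume = TRUE,
                            conditions = NULL) {
  conds <- conditions %||% enumerate_pairwise_conditions(net, levels)
  master <- config$seed %||% 1L
  done <- character(0)
  if (!is.null(out_file) && resume && file.exists(out_file)) {
    done <- vapply(readLines(out_file), function(l)
      jsonlite::fromJSON(l)$id %||% NA_character_, "", USE.NAMES = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(conds))) {
    if (conds$id[i] %in% done) next
    cond <- perturbation_condition(
      stats::setNames(c(conds$level1[i], conds$level2[i]),
                      c(conds$comp1[i], conds$comp2[i])),
      source_state = attractor$label)
    cfg <- config
    cfg$seed <- derive_seed(master, i)
    o <- run_condition(net, attractor, cond, attractors, n_reps = n_reps,
                       n_experiments = n_experiments, config = cfg)
    out[[length(out) + 1]] <- o
    if (!is.null(out_file)) {
      line <- jsonlite::toJSON(list(id = conds$id[i], seed = cfg$seed,
                                    source = attractor$label,
                                    pct_to = as.list(o$pct_to),
                                    sd_to = as.list(o$sd_to)),
                               auto_unbox = TRUE)
      cat(line, "\n", sep = "", file = out_file, append = TRUE)
    }
  }
  attr(out, "summary") <- summarize_screen(out)
  out
}

#' Markov transition summary over the single-perturbation ensemble
#'
#' Entry (s, t) is the mean, over the uniform ensemble of single-component
#' perturbation conditions run from source attractor s, of the fraction of
#' repetitions ending in destination t. Every row sums to 1 by construction.
#'
#' @param screens named list: one [screen_single()] result per source
#'   attractor label, covering every attractor.
#' @param attractors optional list of basal attractors; when given, a screen
#'   must be present for each attractor label.
#' @return matrix of class `markov_summary` (rows: sources, columns:
#'   destinations).
#' @export
markov_summary <- function(screens, attractors = NULL) {
  if (is.null(names(screens)) || any(!nzchar(names(screens)))) {
    stop("screens must be a named list keyed by source attractor label")
  }
  if (!is.null(attractors)) {
    missing <- setdiff(vapply(attractors, `[[`, "", "label"), names(screens))
    if (length(missing)) {
      stop("missing source state(s): ", paste(missing, collapse = ", "))
    }
  }
  labels <- unique(c(names(screens),
                     unlist(lapply(screens, function(sc)
                       unlist(lapply(sc, function(o) names(o$pct_to)))))))
  m <- matrix(0, length(screens), length(labels),
              dimnames = list(names(screens), labels))
  for (s in names(screens)) {
    probs <- stats::setNames(numeric(length(labels)), labels)
    for (o in screens[[s]]) probs[names(o$pct_to)] <- probs[names(o$pct_to)] + o$pct_to / 100
    m[s, ] <- probs / length(screens[[s]])
  }
  structure(m, class = c("markov_summary", "matrix", "array"))
}

#' @export
print.markov_summary <- function(x, ...) {
  cat("Markov transition summary (uniform single-perturbation ensemble):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Select candidate treatment conditions from a pairwise screen
#'
#' Keeps conditions with more than `min_healthy_pct` of transitions towards
#' the healthy state and less than `max_none_pct` towards the trivial
#' all-off ("None") state, drops conditions touching excluded components
#' (e.g. transcription factors, which are hard to target pharmacologically),
#' and bins the survivors by healthy percentage: `100-90`, `89-80`, `79-70`.
#'
#' @param outcomes list of `transition_outcome` objects.
#' @param min_healthy_pct floor on the healthy-destination percentage
#'   (default 70, exclusive).
#' @param max_none_pct cap on the None-destination percentage (default 5,
#'   exclusive).
#' @param exclude component ids whose conditions are dropped.
#' @param healthy_label,none_label destination labels to filter on.
#' @return data.frame with columns `condition`, `healthy_pct`, `none_pct`,
#'   `bin`, ordered by decreasing healthy percentage.
#' @export
select_candidates <- function(outcomes, min_healthy_pct = 70,
                              max_none_pct = 5, exclude = character(),
                              healthy_label = "Healthy", none_label = "None") {
  if (min_healthy_pct < 0 || min_healthy_pct > 100 ||
      max_none_pct < 0 || max_none_pct > 100) {
    stop("thresholds must lie in [0, 100]")
  }
  rows <- lapply(outcomes, function(o) {
    h <- o$pct_to[healthy_label]
    if (is.na(h)) stop("outcomes must include a '", healthy_label, "' percentage")
    n <- o$pct_to[none_label]
    if (is.na(n)) n <- 0
    data.frame(condition = condition_id(o$condition),
               healthy_pct = unname(h), none_pct = unname(n),
               excluded = any(names(o$condition$clamps) %in% exclude),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- tab$healthy_pct > min_healthy_pct & tab$none_pct < max_none_pct &
    !tab$excluded
  tab <- tab[keep, c("condition", "healthy_pct", "none_pct"), drop = FALSE]
  tab$bin <- cut(tab$healthy_pct, breaks = c(70, 80, 90, 100 + 1e-9),
                 labels = c("79-70", "89-80", "100-90"), right = FALSE)
  tab <- tab[order(-tab$healthy_pct), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Dose-grid perturbation experiment
#'
#' Clamps two components to every pair of levels on the given axes and runs
#' [run_condition()] in each cell; this covers both drug-dose screens (e.g.
#' PKA x FGFR1) and receptor-ratio sweeps (e.g. ALK1/ALK5 balance with
#' levels 0, 0.1, ..., 1).
#'
#' @inheritParams run_condition
#' @param comp_x,comp_y the two clamped components.
#' @param levels_x,levels_y clamp levels for each axis (subset of `[0, 1]`).
#' @return a list of class `dose_grid`: `comp_x`, `comp_y`, `levels_x`,
#'   `levels_y`, `cells` (list-matrix of `transition_outcome`), and
#'   `pct(label)` accessor via [dose_grid_pct()].
#' @export
dose_grid <- function(net, attractor, attractors, comp_x, comp_y,
                      levels_x = seq(0, 1, 0.1), levels_y = levels_x,
                      n_reps = 100, n_experiments = 1,
                      config = engine_config()) {
  if (length(levels_x) == 0 || length(levels_y) == 0) stop("empty level list")
  stopifnot(all(levels_x >= 0 & levels_x <= 1), all(levels_y >= 0 & levels_y <= 1))
  check_components(c(comp_x, comp_y), net$components$id)
  master <- config$seed %||% 1L
  cells <- vector("list", length(levels_x) * length(levels_y))
  dim(cells) <- c(length(levels_x), length(levels_y))
  k <- 0L
  for (i in seq_along(levels_x)) for (j in seq_along(levels_y)) {
    k <- k + 1L
    cond <- perturbation_condition(
      stats::setNames(c(levels_x[i], levels_y[j]), c(comp_x, comp_y)),
      source_state = attractor$label)
    cfg <- config
    cfg$seed <- derive_seed(master, k)
    cells[[i, j]] <- run_condition(net, attractor, cond, attractors,
                                   n_reps = n_reps,
                                   n_experiments = n_experiments, config = cfg)
  }
  structure(list(comp_x = comp_x, comp_y = comp_y,
                 levels_x = levels_x, levels_y = levels_y, cells = cells),
            class = "dose_grid")
}

#' Extract a destination-percentage matrix from a dose grid
#'
#' @param grid a [dose_grid()] result.
#' @param label destination attractor label.
#' @return numeric matrix (rows: `levels_x`, columns: `levels_y`).
#' @export
dose_grid_pct <- function(grid, label) {
  m <- matrix(0, length(grid$levels_x), length(grid$levels_y),
              dimnames = list(as.character(grid$levels_x),
                              as.character(grid$levels_y)))
  for (i in seq_along(grid$levels_x)) for (j in seq_along(grid$levels_y)) {
    p <- grid$cells[[i, j]]$pct_to[label]
    m[i, j] <- if (is.na(p)) 0 else p
  }
  m
}
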