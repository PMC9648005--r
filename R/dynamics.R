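#' Engine configuration
#'
#' @param saturation_default saturation constant used where a rule does not
#'   set its own. The saturation constant controls how fast net upstream
#'   activation saturates a variable at its maximum.
#' @param tolerance convergence tolerance: a state is stable when no
#'   sub-variable update moves it by more than this (default `1e-2`).
#' @param max_fast_passes cap on full asynchronous passes within one
#'   fast-layer relaxation.
#' @param max_total_steps cap on sub-variable update events per simulation
#'   ("time steps": one step = one sub-variable update).
#' @param seed optional integer seed; when set, the simulation is bit-for-bit
#'   reproducible.
#' @param stability_scope `"sub"` applies the tolerance per sub-variable
#'   (default); `"global"` applies it to the componentwise global activity.
#' @return a list of class `engine_config`.
#' @export
engine_config <- function(saturation_default = 1, tolerance = 1e-2,
                          max_fast_passes = 1000, max_total_steps = 50000,
                          seed = NULL, stability_scope = c("sub", "global")) {
  stopifnot(tolerance > 0, max_fast_passes > 0, max_total_steps > 0,
            saturation_default > 0)
  structure(list(saturation_default = saturation_default,
                 tolerance = tolerance,
                 max_fast_passes = max_fast_passes,
                 max_total_steps = max_total_steps,
                 seed = seed,
                 stability_scope = match.arg(stability_scope)),
            class = "engine_config")
}

#' System state of a two-layer network
#'
#' Holds the fast (protein activation) and slow (gene expression)
#' sub-variables, each in `[0, 1]` and indexed by component. Components absent
#' from a layer carry the neutral value 1 there, so the global activity --
#' the componentwise product `slow * fast` -- reduces to the present layer's
#' value. Clamps override the global activity seen by consumers and freeze
#' both sub-variables.
#'
#' @param net a `layered_network`.
#' @param fast,slow named numeric vectors (partial is fine; missing entries
#'   default to `default`, absent layers to 1).
#' @param clamp named numeric vector of clamped global activities.
#' @param default fill value for unspecified present-layer entries.
#' @return an object of class `system_state`.
#' @export
system_state <- function(net, fast = NULL, slow = NULL, clamp = NULL,
                         default = 0) {
  ids <- net$components$id
  f <- stats::setNames(rep(1, length(ids)), ids)
  s <- stats::setNames(rep(1, length(ids)), ids)
  f[net$components$id[net$components$has_fast]] <- default
  s[net$components$id[net$components$has_slow]] <- default
  if (!is.null(fast)) {
    check_components(names(fast), ids)
    f[names(fast)] <- fast
  }
  if (!is.null(slow)) {
    check_components(names(slow), ids)
    s[names(slow)] <- slow
  }
  cl <- numeric(0)
  if (!is.null(clamp) && length(clamp)) {
    check_components(names(clamp), ids)
    if (any(clamp < 0 | clamp > 1)) stop("clamp levels must lie in [0, 1]")
    cl <- clamp
  }
  if (any(f < 0 | f > 1 | s < 0 | s > 1)) stop("sub-variables must lie in [0, 1]")
  structure(list(fast = f, slow = s, clamp = cl), class = "system_state")
}

check_components <- function(who, ids) {
  bad <- setdiff(who, ids)
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "))
}

#' Global functional activity
#'
#' The value consumed by downstream rules: the product of a component's gene
#' expression level and protein activation potential, overridden by the clamp
#' level for clamped components. A protein cannot act unless it is both
#' expressed and activated.
#'
#' @param state a `system_state`.
#' @param component optional component id (or vector of ids); when omitted,
#'   the full named vector is returned.
#' @return numeric in `[0, 1]`.
#' @export
global_activity <- function(state, component = NULL) {
  ga <- state$fast * state$slow
  if (length(state$clamp)) ga[names(state$clamp)] <- state$clamp
  if (is.null(component)) return(ga)
  check_components(component, names(ga))
  ga[component]
}

#' Evaluate one update rule against a state
#'
#' Additive combiner: `clamp01((sum activators - sum inhibitors)/saturation)`.
#' Product combiner: `clamp01(prod(activators) * prod(1 - inhibitors))`.
#' Source contributions are the sources' global activities. An empty rule
#' (input component) returns the component's current level in the rule's
#' layer.
#'
#' @param rule an [update_rule()].
#' @param state a `system_state`.
#' @return the target's new activity level in `[0, 1]`.
#' @export
evaluate_rule <- function(rule, state) {
  if (nrow(rule$terms) == 0) {
    return(state[[rule$layer]][[rule$target]])
  }
  ga <- global_activity(state, rule$terms$source)
  act <- ga[rule$terms$sign > 0]
  inh <- ga[rule$terms$sign < 0]
  v <- if (rule$combiner == "additive") {
    (sum(act) - sum(inh)) / rule$saturation
  } else {
    prod(act) * prod(1 - inh)
  }
  if (!is.finite(v)) stop("non-finite rule output for ", rule$target)
  clamp01(v)
}

# --- compiled representation -------------------------------------------------
# The public API works on named vectors; the simulator compiles the network
# once into integer-indexed structures so the inner loop stays cheap.

compile_network <- function(net) {
  ids <- net$components$id
  idx <- stats::setNames(seq_along(ids), ids)
  mk <- function(layer) {
    out <- list()
    for (r in net$rules) {
      if (r$layer != layer || nrow(r$terms) == 0) next
      out[[length(out) + 1]] <- list(
        tgt = idx[[r$target]],
        src = unname(idx[r$terms$source]),
        pos = r$terms$sign > 0,
        combiner = r$combiner,
        sat = r$saturation)
    }
    out
  }
  list(ids = ids, n = length(ids), fast = mk("fast"), slow = mk("slow"))
}

eval_compiled <- function(r, ga) {
  x <- ga[r$src]
  v <- if (r$combiner == "additive") {
    (sum(x[r$pos]) - sum(x[!r$pos])) / r$sat
  } else {
    prod(x[r$pos]) * prod(1 - x[!r$pos])
  }
  if (is.na(v)) stop("non-finite rule output")
  min(1, max(0, v))
}

state_ga <- function(f, s, clamp_idx, clamp_val) {
  ga <- f * s
  if (length(clamp_idx)) ga[clamp_idx] <- clamp_val
  ga
}

#' Simulate to a stable state with priority-class asynchronous updates
#'
#' One simulation repeatedly (1) relaxes the fast layer: asynchronous passes
#' over a freshly reshuffled order of fast sub-variables until a full pass
#' changes none of them by more than the tolerance, then (2) updates one
#' uniformly chosen slow sub-variable. The loop ends when a full fast+slow
#' sweep changes nothing by more than the tolerance (`converged = TRUE`) or
#' when the step caps are hit (`converged = FALSE`, a possible cyclic regime
#' that is reported, never silently truncated). One "time step" is one
#' sub-variable update event.
#'
#' Clamped components are never updated; consumers see the clamp level as
#' their global activity, and both sub-variables stay frozen at their current
#' values.
#'
#' @param net a `layered_network`.
#' @param initial a `system_state` (or `NULL` for all present layers at 0).
#' @param clamps named numeric vector of clamp levels in `[0, 1]`.
#' @param config an [engine_config()].
#' @param record_history keep a per-step log of (component, layer, value)?
#' @return a list of class `simulation_trace` with `final` (a
#'   `system_state`), `converged`, `steps_used` and optionally `history`.
#' @export
simulate_network <- function(net, initial = NULL, clamps = NULL,
                             config = engine_config(),
                             record_history = FALSE) {
  cn <- compile_network(net)
  if (is.null(initial)) initial <- system_state(net)
  if (!is.null(config$seed)) set.seed(config$seed)

  f <- initial$fast[cn$ids]
  s <- initial$slow[cn$ids]
  clamp <- initial$clamp
  if (!is.null(clamps) && length(clamps)) {
    check_components(names(clamps), cn$ids)
    if (any(clamps < 0 | clamps > 1)) stop("clamp levels must lie in [0, 1]")
    clamp <- c(clamp[setdiff(names(clamp), names(clamps))], clamps)
  }
  clamp_idx <- match(names(clamp), cn$ids)
  clamp_val <- unname(clamp)

  fast_rules <- Filter(function(r) !(r$tgt %in% clamp_idx), cn$fast)
  slow_rules <- Filter(function(r) !(r$tgt %in% clamp_idx), cn$slow)
  tol <- config$tolerance
  steps <- 0L
  hist <- if (record_history) list() else NULL
  ga <- state_ga(f, s, clamp_idx, clamp_val)

  relax_fast <- function() {
    passes <- 0L
    repeat {
      if (length(fast_rules) == 0) return(TRUE)
      ord <- sample.int(length(fast_rules))
      maxd <- 0
      for (k in ord) {
        r <- fast_rules[[k]]
        v <- eval_compiled(r, ga)
        maxd <- max(maxd, abs(v - f[r$tgt]))
        f[r$tgt] <<- v
        ga[r$tgt] <<- v * s[r$tgt]
        steps <<- steps + 1L
        if (record_history) {
          hist[[length(hist) + 1L]] <<- list(component = cn$ids[r$tgt],
                                             layer = "fast", value = v)
        }
        if (steps >= config$max_total_steps) return(NA)
      }
      passes <- passes + 1L
      if (maxd <= tol) return(TRUE)
      if (passes >= config$max_fast_passes) return(FALSE)
    }
  }

  stable_now <- function() {
    check <- function(rules, layer_vec, other_vec) {
      for (r in rules) {
        v <- eval_compiled(r, ga)
        if (config$stability_scope == "sub") {
          if (abs(v - layer_vec[r$tgt]) > tol) return(FALSE)
        } else {
          if (abs(v * other_vec[r$tgt] - ga[r$tgt]) > tol) return(FALSE)
        }
      }
      TRUE
    }
    check(fast_rules, f, s) && check(slow_rules, s, f)
  }

  converged <- FALSE
  repeat {
    ok <- relax_fast()
    if (is.na(ok)) break            # step cap hit
    if (ok && stable_now()) { converged <- TRUE; break }
    if (length(slow_rules) == 0) {
      converged <- ok && stable_now()
      break
    }
    k <- sample.int(length(slow_rules), 1L)
    r <- slow_rules[[k]]
    v <- eval_compiled(r, ga)
    s[r$tgt] <- v
    ga[r$tgt] <- f[r$tgt] * v
    steps <- steps + 1L
    if (record_history) {
      hist[[length(hist) + 1L]] <- list(component = cn$ids[r$tgt],
                                        layer = "slow", value = v)
    }
    if (steps >= config$max_total_steps) break
  }

  final <- structure(list(fast = stats::setNames(f, cn$ids),
                          slow = stats::setNames(s, cn$ids),
                          clamp = clamp),
                     class = "system_state")
  structure(list(final = final, converged = converged, steps_used = steps,
                 history = if (record_history) do.call(rbind, lapply(hist, as.data.frame))),
            class = "simulation_trace")
}

#' Is a state stable?
#'
#' TRUE iff re-evaluating every non-input, unclamped rule changes no
#' sub-variable (or, with `stability_scope = "global"`, no global activity)
#' by more than the tolerance.
#'
#' @inheritParams simulate_network
#' @param state a `system_state`.
#' @return logical flag.
#' @export
is_stable <- function(net, state, config = engine_config()) {
  tol <- config$tolerance
  for (r in net$rules) {
    if (nrow(r$terms) == 0) next
    if (r$target %in% names(state$clamp)) next
    v <- evaluate_rule(r, state)
    cur <- state[[r$layer]][[r$target]]
    if (config$stability_scope == "sub") {
      if (abs(v - cur) > tol) return(FALSE)
    } else {
      other <- if (r$layer == "fast") state$slow[[r$target]] else state$fast[[r$target]]
      if (abs(v * other - cur * other) > tol) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.system_state <- function(x, ...) {
  ga <- global_activity(x)
  cat("<system_state>", length(ga), "components",
      if (length(x$clamp)) sprintf("(%d clamped)", length(x$clamp)) else "", "\n")
  print(round(ga, 3))
  invisible(x)
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("<simulation_trace> converged=%s steps=%d\n",
              x$converged, x$steps_used))
  invisible(x)
}
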