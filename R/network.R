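#' Two-layer regulatory network
#'
#' A `layered_network` couples a protein-signaling layer (fast,
#' post-translational influences) with a gene-regulatory layer (slow,
#' transcriptional influences). Every biological component may participate in
#' one or both layers; each participating (component, layer) pair carries
#' exactly one update rule. A rule with no terms marks the component as an
#' input in that layer: it holds its current value unless clamped.
#'
#' @param components data.frame with columns `id`, and optionally `role`
#'   (one of `growth_factor`, `receptor`, `kinase`, `transcription_factor`,
#'   `ecm_protein`, `other_signaling`, `gene_only`), `has_fast`, `has_slow`,
#'   `annotation`. Missing layer flags are inferred from the interactions and
#'   rules (a component participates in a layer if it is the target of a rule
#'   or any interaction in that layer; components untouched by either layer
#'   default to fast-layer membership).
#' @param interactions data.frame with columns `source`, `target`, `sign`
#'   (+1 activation / -1 inhibition), `layer` (`"fast"` or `"slow"`) and
#'   optionally `provenance` (`"curated"` or `"inferred"`).
#' @param rules optional list of update rules created by [update_rule()]. When
#'   `NULL`, one additive rule per (target, layer) is synthesized from the
#'   interaction rows with the default saturation constant.
#' @param metadata list with optional `name`, `version`, `provenance` entries.
#' @param saturation_default saturation constant used for synthesized rules.
#' @return an object of class `layered_network`.
#' @seealso [load_network()], [topology_stats()], [simulate_network()]
#' @export
layered_network <- function(components, interactions = NULL, rules = NULL,
                            metadata = list(), saturation_default = 1) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(components))
  components$id <- as.character(components$id)
  if (anyDuplicated(components$id)) {
    stop("duplicate component ids: ",
         paste(unique(components$id[duplicated(components$id)]), collapse = ", "))
  }
  if (is.null(components$role)) {
    components$role <- rep("other_signaling", nrow(components))
  }
  if (is.null(components$annotation)) {
    components$annotation <- rep("", nrow(components))
  }

  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0) {
    interactions <- data.frame(source = character(), target = character(),
                               sign = integer(), layer = character(),
                               provenance = character(),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    interactions$source <- as.character(interactions$source)
    interactions$target <- as.character(interactions$target)
    interactions$sign <- parse_sign(interactions$sign)
    if (!all(interactions$layer %in% c("fast", "slow"))) {
      stop("interaction layer must be 'fast' or 'slow'")
    }
    if (is.null(interactions$provenance)) interactions$provenance <- "curated"
    unknown <- setdiff(c(interactions$source, interactions$target), components$id)
    if (length(unknown)) {
      stop("interaction references unknown component(s): ",
           paste(unknown, collapse = ", "))
    }
  }

  if (is.null(rules)) {
    rules <- synthesize_rules(components$id, interactions, saturation_default)
  } else {
    names(rules) <- vapply(rules, function(r) rule_key(r$target, r$layer), "")
    if (anyDuplicated(names(rules))) {
      dup <- names(rules)[duplicated(names(rules))]
      stop("duplicate rule for (component, layer): ", paste(dup, collapse = ", "))
    }
    for (r in rules) {
      bad <- setdiff(c(r$target, r$terms$source), components$id)
      if (length(bad)) stop("rule references unknown component(s): ",
                            paste(bad, collapse = ", "))
    }
  }

  # Layer membership: rule targets and interaction endpoints in that layer.
  in_layer <- function(layer) {
    ids <- character()
    for (r in rules) if (r$layer == layer) ids <- c(ids, r$target)
    sub <- interactions[interactions$layer == layer, , drop = FALSE]
    unique(c(ids, sub$source, sub$target))
  }
  has_fast <- components$id %in% in_layer("fast")
  has_slow <- components$id %in% in_layer("slow")
  if (!is.null(components$has_fast)) has_fast <- has_fast | as.logical(components$has_fast)
  if (!is.null(components$has_slow)) has_slow <- has_slow | as.logical(components$has_slow)
  orphan <- !has_fast & !has_slow
  has_fast[orphan] <- TRUE  # default membership for isolated components
  components$has_fast <- has_fast
  components$has_slow <- has_slow

  # Every participating (component, layer) pair gets a rule; missing ones are
  # inputs (empty term list).
  for (i in seq_len(nrow(components))) {
    for (layer in c("fast", "slow")) {
      if (!components[[paste0("has_", layer)]][i]) next
      key <- rule_key(components$id[i], layer)
      if (is.null(rules[[key]])) {
        rules[[key]] <- update_rule(components$id[i], layer,
                                    saturation = saturation_default)
      }
    }
  }

  net <- structure(list(components = components,
                        interactions = interactions,
                        rules = rules,
                        metadata = metadata),
                   class = "layered_network")
  validate_network(net)
  net
}

parse_sign <- function(x) {
  if (is.character(x)) {
    out <- ifelse(x %in% c("+", "+1", "1", "activation"), 1L,
                  ifelse(x %in% c("-", "−", "-1", "inhibition"), -1L, NA_integer_))
  } else {
    out <- as.integer(x)
    out[!out %in% c(-1L, 1L)] <- NA_integer_
  }
  if (anyNA(out)) stop("interaction sign must be +1/-1 (or '+'/'-')")
  out
}

rule_key <- function(target, layer) paste(target, layer, sep = ".")

#' Create an update rule
#'
#' The additive combiner follows the model's transfer function:
#' `clamp01((sum of activator inputs - sum of inhibitor inputs) / saturation)`.
#' The product combiner, reserved for exceptional mechanisms where regulators
#' act as a conjunction, is
#' `clamp01(prod(activator inputs) * prod(1 - inhibitor inputs))`.
#' Inputs are the sources' global activities. A rule with no terms marks an
#' input component: it holds its current value in that layer.
#'
#' @param target component id the rule updates.
#' @param layer `"fast"` (protein activation) or `"slow"` (gene expression).
#' @param terms data.frame with columns `source`, `sign` (+1/-1); `NULL` or
#'   zero rows for an input component.
#' @param combiner `"additive"` (default) or `"product"`.
#' @param saturation positive saturation constant (additive combiner only).
#' @return a list of class `update_rule`.
#' @export
update_rule <- function(target, layer, terms = NULL, combiner = "additive",
                        saturation = 1) {
  stopifnot(layer %in% c("fast", "slow"),
            combiner %in% c("additive", "product"),
            saturation > 0)
  if (is.null(terms) || nrow(as.data.frame(terms)) == 0) {
    terms <- data.frame(source = character(), sign = integer(),
                        stringsAsFactors = FALSE)
  } else {
    terms <- as.data.frame(terms, stringsAsFactors = FALSE)
    terms$source <- as.character(terms$source)
    terms$sign <- parse_sign(terms$sign)
  }
  structure(list(target = as.character(target), layer = layer, terms = terms,
                 combiner = combiner, saturation = saturation),
            class = "update_rule")
}

synthesize_rules <- function(ids, interactions, saturation_default) {
  rules <- list()
  if (nrow(interactions)) {
    key <- paste(interactions$target, interactions$layer)
    for (k in unique(key)) {
      sub <- interactions[key == k, , drop = FALSE]
      r <- update_rule(sub$target[1], sub$layer[1],
                       terms = sub[, c("source", "sign")],
                       saturation = saturation_default)
      rules[[rule_key(r$target, r$layer)]] <- r
    }
  }
  rules
}

#' Validate a layered network
#'
#' Checks the structural invariants: unique component ids, signs in {-1, +1},
#' known endpoints, at least one layer per component, exactly one rule per
#' participating (component, layer) pair, and resolvable rule sources.
#'
#' @param net a `layered_network`.
#' @return `net`, invisibly; errors describe the first violated invariant.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "layered_network"))
  comp <- net$components
  if (any(!comp$has_fast & !comp$has_slow)) {
    stop("component must participate in at least one layer")
  }
  expected <- unlist(lapply(seq_len(nrow(comp)), function(i) {
    c(if (comp$has_fast[i]) rule_key(comp$id[i], "fast"),
      if (comp$has_slow[i]) rule_key(comp$id[i], "slow"))
  }))
  if (!setequal(expected, names(net$rules)) ||
      length(net$rules) != length(expected)) {
    stop("network must carry exactly one rule per participating (component, layer)")
  }
  for (r in net$rules) {
    if (!all(r$terms$source %in% comp$id)) stop("rule term references unknown component")
  }
  invisible(net)
}

#' @export
print.layered_network <- function(x, ...) {
  n_in <- sum(vapply(x$rules, function(r) nrow(r$terms) == 0, TRUE))
  cat("<layered_network>", x$metadata$name %||% "", "\n")
  cat("  components  :", nrow(x$components),
      sprintf("(fast %d, slow %d)", sum(x$components$has_fast),
              sum(x$components$has_slow)), "\n")
  cat("  interactions:", nrow(x$interactions), "\n")
  cat("  rules       :", length(x$rules),
      sprintf("(%d input rules)", n_in), "\n")
  invisible(x)
}

#' @export
format.update_rule <- function(x, ...) {
  if (nrow(x$terms) == 0) return(sprintf("%s[%s] <- (input)", x$target, x$layer))
  op <- ifelse(x$terms$sign > 0, "+", "-")
  sprintf("%s[%s] <- %s(%s)/%g", x$target, x$layer, x$combiner,
          paste0(op, x$terms$source, collapse = " "), x$saturation)
}

#' @export
print.update_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Identity of two networks up to row order: component set, interaction
# multiset, rule table.
#' Compare two layered networks
#'
#' Networks are considered equal when they have the same component table
#' (up to row order), the same multiset of interactions and the same rules
#' (terms compared as multisets, combiner and saturation exactly).
#'
#' @param a,b `layered_network` objects.
#' @return logical.
#' @export
networks_equal <- function(a, b) {
  norm_comp <- function(n) {
    d <- n$components[order(n$components$id),
                      c("id", "role", "has_fast", "has_slow", "annotation")]
    rownames(d) <- NULL
    d
  }
  norm_int <- function(n) {
    d <- n$interactions[, c("source", "target", "sign", "layer", "provenance")]
    d <- d[do.call(order, d), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  norm_rules <- function(n) {
    ks <- sort(names(n$rules))
    lapply(n$rules[ks], function(r) {
      t <- r$terms[order(r$terms$source, r$terms$sign), , drop = FALSE]
      rownames(t) <- NULL
      list(target = r$target, layer = r$layer, terms = t,
           combiner = r$combiner, saturation = r$saturation)
    })
  }
  isTRUE(all.equal(norm_comp(a), norm_comp(b))) &&
    isTRUE(all.equal(norm_int(a), norm_int(b))) &&
    isTRUE(all.equal(norm_rules(a), norm_rules(b)))
}
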