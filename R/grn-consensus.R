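#' Consensus of three edge-score matrices
#'
#' For each method the presence threshold is `mean(scores) - sd(scores)`,
#' computed over all finite scores of that method's matrix (self-edges and
#' DPI-pruned entries excluded); an edge is present for a method when its
#' score strictly exceeds the threshold (an `NA` score can never pass). Only
#' edges present in all three methods' results are kept. Each consensus edge
#' is signed by the Spearman correlation between its source and target
#' profiles in the supplied (merged, corrected) matrix: activation if
#' positive, inhibition if negative. Zero-variance pairs have no defined
#' sign and are dropped with a warning.
#'
#' @param scores list of three `edge_score_matrix` objects (identical TF and
#'   gene indexing).
#' @param m the [expression_matrix()] the scores were computed from.
#' @return data.frame of class `consensus_edges`: `source`, `target`, one
#'   score and one pass-flag column per method, `spearman`, `sign`.
#' @export
consensus_edges <- function(scores, m) {
  stopifnot(length(scores) == 3)
  dn <- dimnames(scores[[1]])
  for (s in scores[-1]) {
    if (!identical(dimnames(s), dn)) stop("score matrices must share TF/gene indexing")
  }
  methods <- vapply(scores, function(s) attr(s, "method") %||% "method", "")
  if (anyDuplicated(methods)) methods <- paste0(methods, "_", seq_along(methods))

  pass <- lapply(scores, function(s) {
    fin <- s[is.finite(s)]
    thr <- mean(fin) - (if (length(fin) > 1) stats::sd(fin) else 0)
    p <- s > thr
    p[!is.finite(s)] <- FALSE
    p
  })
  for (tf in intersect(dn[[1]], dn[[2]])) {
    for (k in 1:3) pass[[k]][tf, tf] <- FALSE  # self-edges never consensus
  }
  all_pass <- pass[[1]] & pass[[2]] & pass[[3]]
  idx <- which(all_pass, arr.ind = TRUE)
  out <- data.frame(source = dn[[1]][idx[, 1]], target = dn[[2]][idx[, 2]],
                    stringsAsFactors = FALSE)
  for (k in 1:3) {
    out[[paste0("score_", methods[k])]] <- scores[[k]][idx]
    out[[paste0("pass_", methods[k])]] <- rep(TRUE, nrow(out))
  }
  if (nrow(out)) {
    out$spearman <- vapply(seq_len(nrow(out)), function(i) {
      a <- m$values[out$source[i], ]
      b <- m$values[out$target[i], ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b, method = "spearman")
    }, 0)
    if (anyNA(out$spearman)) {
      warning("dropping ", sum(is.na(out$spearman)),
              " edge(s) with undefined Spearman sign (zero variance)")
      out <- out[!is.na(out$spearman), , drop = FALSE]
    }
    out$sign <- ifelse(out$spearman >= 0, 1L, -1L)
  } else {
    out$spearman <- numeric(0)
    out$sign <- integer(0)
  }
  rownames(out) <- NULL
  class(out) <- c("consensus_edges", "data.frame")
  out
}

#' Integrate inferred edges into a network's gene-regulatory layer
#'
#' Appends each consensus edge as a slow-layer interaction with provenance
#' `"inferred"` and adds it as a term to the target's slow update rule
#' (creating the rule -- and slow-layer membership -- when the target had
#' none). Edges duplicating an existing term of the target's slow rule are
#' skipped and reported.
#'
#' @param net a `layered_network`.
#' @param edges a [consensus_edges()] data.frame (columns `source`, `target`,
#'   `sign`).
#' @param mapping optional named character vector gene id -> component id
#'   (identity for ids already matching components).
#' @param saturation saturation constant for newly created slow rules.
#' @return the augmented `layered_network`, with an `"integration_report"`
#'   attribute (data.frame: `source`, `target`, `status` added/duplicate).
#' @export
integrate_edges <- function(net, edges, mapping = NULL, saturation = 1) {
  map_id <- function(id) {
    if (!is.null(mapping) && id %in% names(mapping)) mapping[[id]] else id
  }
  report <- list()
  for (i in seq_len(nrow(edges))) {
    src <- map_id(edges$source[i])
    tgt <- map_id(edges$target[i])
    bad <- setdiff(c(src, tgt), net$components$id)
    if (length(bad)) stop("unmappable gene id(s): ", paste(bad, collapse = ", "))
    key <- rule_key(tgt, "slow")
    r <- net$rules[[key]]
    dup <- !is.null(r) &&
      any(r$terms$source == src & r$terms$sign == edges$sign[i])
    if (dup) {
      report[[length(report) + 1]] <- data.frame(source = src, target = tgt,
                                                 status = "duplicate")
      next
    }
    if (is.null(r)) r <- update_rule(tgt, "slow", saturation = saturation)
    r$terms <- rbind(r$terms, data.frame(source = src, sign = edges$sign[i],
                                         stringsAsFactors = FALSE))
    net$rules[[key]] <- r
    net$interactions <- rbind(net$interactions,
                              data.frame(source = src, target = tgt,
                                         sign = as.integer(edges$sign[i]),
                                         layer = "slow",
                                         provenance = "inferred",
                                         stringsAsFactors = FALSE))
    net$components$has_slow[net$components$id == tgt] <- TRUE
    report[[length(report) + 1]] <- data.frame(source = src, target = tgt,
                                               status = "added")
  }
  # slow-layer membership may have grown: regenerate via the constructor so
  # sources gain any missing input rules and invariants re-check
  net2 <- layered_network(net$components, net$interactions, net$rules,
                          metadata = net$metadata)
  attr(net2, "integration_report") <-
    if (length(report)) do.call(rbind, report)
    else data.frame(source = character(), target = character(),
                    status = character(), stringsAsFactors = FALSE)
  net2
}
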