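# Shared builders and independent oracles. Everything here is constructed in
# code at test time; no binary fixtures.

# Toy 3-row edge table: A->B(+,fast), B->C(-,fast), C->A(+,slow).
write_toy_table <- function(path) {
  writeLines(c("source\ttarget\tsign\tlayer\tprovenance",
               "A\tB\t+\tfast\tcurated",
               "B\tC\t-\tfast\tcurated",
               "C\tA\t+\tslow\tcurated"), path)
  path
}

# Redundant self-sustaining pair: each component activated by itself and its
# partner (saturation 1). The all-ones state survives any single clamp.
make_redundant_pair <- function() {
  comp <- data.frame(id = c("M1", "M2"), stringsAsFactors = FALSE)
  ints <- data.frame(source = c("M1", "M2", "M1", "M2"),
                     target = c("M1", "M1", "M2", "M2"),
                     sign = 1L, layer = "fast", provenance = "curated",
                     stringsAsFactors = FALSE)
  layered_network(comp, ints, metadata = list(name = "redundant_pair"))
}

# Canonical toggle: mutual inhibition + self-activation at saturation 1
# (fixed point continuum on the axes; used only for point checks).
make_sat1_toggle <- function() make_fixture("toggle_switch", saturation = 1)

# Independent BFS over the interaction list (ignores igraph entirely).
bfs_distances <- function(net, directed = FALSE) {
  ids <- net$components$id
  n <- length(ids)
  adj <- lapply(ids, function(i) character(0))
  names(adj) <- ids
  for (k in seq_len(nrow(net$interactions))) {
    s <- net$interactions$source[k]; t <- net$interactions$target[k]
    adj[[s]] <- union(adj[[s]], t)
    if (!directed) adj[[t]] <- union(adj[[t]], s)
  }
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (s in ids) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (!is.finite(d[s, v])) {
        d[s, v] <- d[s, u] + 1
        queue <- c(queue, v)
      }
    }
  }
  d
}

oracle_mean_shortest_path <- function(net, directed = FALSE) {
  d <- bfs_distances(net, directed)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_mean_unique_neighbors <- function(net) {
  ids <- net$components$id
  nb <- lapply(ids, function(i) character(0))
  names(nb) <- ids
  for (k in seq_len(nrow(net$interactions))) {
    s <- net$interactions$source[k]; t <- net$interactions$target[k]
    if (s == t) next
    nb[[s]] <- union(nb[[s]], t)
    nb[[t]] <- union(nb[[t]], s)
  }
  mean(lengths(nb))
}

# Global-activity profile of a state as a plain named vector.
ga <- function(state) global_activity(state)

# The two polarized toggle attractors, as monte_carlo-style attractor lists.
toggle_attractors <- function(net = make_fixture("toggle_switch")) {
  mk <- function(a, b, label) {
    list(label = label,
         global = c(A = a, B = b),
         fast = c(A = a, B = b),
         slow = c(A = 1, B = 1))
  }
  list(mk(1, 0, "Apole"), mk(0, 1, "Bpole"), mk(0, 0, "Off"))
}

# Area under the precision-recall curve over TF x gene candidates, with
# proper handling of tied scores (threshold-grouped); NA scores rank last.
aupr_ratio <- function(sc, truth_keys) {
  df <- expand.grid(source = rownames(sc), target = colnames(sc),
                    stringsAsFactors = FALSE)
  df <- df[df$source != df$target, ]
  df$score <- sc[cbind(df$source, df$target)]
  df$score[is.na(df$score)] <- 0
  df$true <- paste(df$source, df$target) %in% truth_keys
  ths <- sort(unique(df$score), decreasing = TRUE)
  P <- sum(df$true); a <- 0; prev_rec <- 0
  for (t in ths) {
    sel <- df$score >= t
    prec <- mean(df$true[sel])
    rec <- sum(df$true[sel]) / P
    a <- a + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  a / mean(df$true)   # enrichment over the random-ranking baseline
}

expect_state_near <- function(state, expected, tol = 1e-6) {
  expect_equal(unname(ga(state)[names(expected)]), unname(expected),
               tolerance = tol)
}
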