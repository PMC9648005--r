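# Scored on one shared synthetic dataset to keep runtimes low.
sim <- simulate_expression(seed = 42)
m <- correct_batch(quantile_normalize(sim$matrix))
tfs <- rownames(m$values)[1:5]

fake_scores <- function(vals, method) {
  structure(vals, method = method,
            class = c("edge_score_matrix", "matrix", "array"))
}

test_that("score matrices have the TF x gene shape with undefined self-scores", {
  for (meth in c("mi_dpi", "tree_importance", "stability_regression")) {
    sc <- score_edges(m, tfs, meth, seed = 1)
    expect_equal(dim(sc), c(length(tfs), nrow(m$values)))
    expect_equal(rownames(sc), tfs)
    for (tf in tfs) expect_true(is.na(sc[tf, tf]))
    expect_true(all(sc[is.finite(sc)] >= 0))
    # deterministic given seed
    sc2 <- score_edges(m, tfs, meth, seed = 1)
    expect_equal(unclass(sc), unclass(sc2))
  }
  expect_error(score_edges(m, c("TF1", "NOPE"), "mi_dpi"), "unknown TF")
  small <- expression_matrix(m$values[, 1:5])
  expect_error(score_edges(small, tfs, "mi_dpi"), ">= 10 samples")
})

test_that("every scorer enriches planted edges over the random baseline", {
  # enrichment bound frozen from the ground-truth oracle across seeds: each
  # method family clears 1.5x the random-ranking AUPR baseline on this
  # generator world (the ceiling is structural: reverse TF-TF edges and
  # collinear co-parents cannot be oriented from observational data)
  truth <- paste(sim$edges$source, sim$edges$target)
  for (s in c(2, 5)) {
    simx <- simulate_expression(seed = s)
    mx <- correct_batch(quantile_normalize(simx$matrix))
    truthx <- paste(simx$edges$source, simx$edges$target)
    for (meth in c("mi_dpi", "tree_importance", "stability_regression")) {
      sc <- score_edges(mx, tfs, meth, seed = s)
      expect_gt(aupr_ratio(sc, truthx), 1.5,
                label = paste(meth, "AUPR enrichment, seed", s))
    }
  }
})

test_that("a pure-noise gene stays below the MI threshold across seeds", {
  # the DPI step prunes the weakest edge of every triangle, so a gene
  # independent of all TFs ends with no reported (finite) score above the
  # m-sigma operating point
  hits <- 0
  for (s in 1:10) {
    sim2 <- simulate_expression(seed = 100 + s, n_samples = 120)
    m2 <- correct_batch(quantile_normalize(sim2$matrix))
    set.seed(s)
    noise <- matrix(rnorm(ncol(m2$values)), 1,
                    dimnames = list("NOISE", colnames(m2$values)))
    m2$values <- rbind(m2$values, noise)
    sc <- score_edges(m2, paste0("TF", 1:5), "mi_dpi", seed = s)
    thr <- mean(sc[is.finite(sc)]) - sd(sc[is.finite(sc)])
    col <- sc[, "NOISE"]
    top <- if (all(is.na(col))) -Inf else max(col, na.rm = TRUE)
    if (top <= thr) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("constant genes score zero with a warning", {
  m2 <- m
  m2$values["G5", ] <- 3
  expect_warning(sc <- score_edges(m2, tfs, "tree_importance", seed = 1),
                 "constant gene")
  expect_true(all(sc[, "G5"] == 0, na.rm = TRUE))
})

test_that("consensus applies the m-sigma rule, triple intersection and Spearman sign", {
  genes <- c("TF1", "TF2", "g1", "g2")
  base <- matrix(NA_real_, 2, 4, dimnames = list(c("TF1", "TF2"), genes))
  # methods report only their surviving edges; absent (NA) entries can never
  # pass, and the m-sigma threshold is computed over the reported scores
  s1 <- base; s1["TF1", "g1"] <- 5; s1["TF2", "g2"] <- 4
  s2 <- base; s2["TF1", "g1"] <- 4; s2["TF2", "g2"] <- 5
  s3 <- base; s3["TF1", "g1"] <- 6; s3["TF1", "g2"] <- 0.1
  # s3 thresholds: mean(6, 0.1) - sd = -1.1, so both reported edges pass,
  # but TF2->g2 is absent from s3 -> not a consensus edge
  set.seed(8)
  x <- rbind(TF1 = rnorm(20), TF2 = rnorm(20))
  x <- rbind(x, g1 = -2 * x["TF1", ] + rnorm(20, sd = 0.01),
             g2 = x["TF2", ] + rnorm(20, sd = 0.01))
  me <- expression_matrix(x)
  sc <- list(fake_scores(s1, "a"), fake_scores(s2, "b"), fake_scores(s3, "c"))
  ce <- consensus_edges(sc, me)
  expect_equal(nrow(ce), 1)                    # only the triple-pass edge
  expect_equal(ce$source, "TF1")
  expect_equal(ce$target, "g1")
  expect_equal(ce$sign, -1L)                   # anti-correlated pair
  expect_lt(ce$spearman, -0.9)

  # a score at or below the m-sigma threshold fails its method: push the
  # TF1->g1 score in s3 below mean - sd of {., 0.1}
  s3b <- s3; s3b["TF1", "g1"] <- 0.1   # mean 0.1, sd 0 -> threshold 0.1
  ce2 <- consensus_edges(list(fake_scores(s1, "a"), fake_scores(s2, "b"),
                              fake_scores(s3b, "c")), me)
  expect_equal(nrow(ce2), 0)

  # an NA (pruned) score in any single method kills the edge
  s1na <- s1; s1na["TF1", "g1"] <- NA
  ce3 <- consensus_edges(list(fake_scores(s1na, "a"), fake_scores(s2, "b"),
                              fake_scores(s3, "c")), me)
  expect_false(any(ce3$source == "TF1" & ce3$target == "g1"))

  # mismatched indexing is rejected
  bad <- fake_scores(s1[, c(2, 1, 3, 4)], "a")
  expect_error(consensus_edges(list(bad, fake_scores(s2, "b"),
                                    fake_scores(s3, "c")), me), "indexing")
})

test_that("consensus is invariant under affine rescaling of any method's scores", {
  sc <- lapply(c("mi_dpi", "tree_importance", "stability_regression"),
               function(k) score_edges(m, tfs, k, seed = 3))
  ce <- consensus_edges(sc, m)
  key <- function(e) sort(paste(e$source, e$target))
  sc2 <- sc
  sc2[[2]] <- fake_scores(unclass(sc[[2]]) * 7 + 3, attr(sc[[2]], "method"))
  expect_equal(key(consensus_edges(sc2, m)), key(ce))
  # raising the top-scoring edge never removes it
  sc3 <- sc
  top <- which(unclass(sc3[[1]]) == max(sc3[[1]][is.finite(sc3[[1]])]),
               arr.ind = TRUE)[1, ]
  if (paste(rownames(sc3[[1]])[top[1]], colnames(sc3[[1]])[top[2]]) %in%
      paste(ce$source, ce$target)) {
    sc3[[1]][top[1], top[2]] <- sc3[[1]][top[1], top[2]] * 2
    expect_true(paste(rownames(sc3[[1]])[top[1]], colnames(sc3[[1]])[top[2]]) %in%
                  paste(consensus_edges(sc3, m)$source,
                        consensus_edges(sc3, m)$target))
  }
})

test_that("zero-variance pairs are dropped from the sign step with a warning", {
  genes <- c("TF1", "TF2", "g1")
  s <- matrix(NA_real_, 2, 3, dimnames = list(c("TF1", "TF2"), genes))
  s["TF1", "g1"] <- 5; s["TF2", "g1"] <- 4   # both pass (threshold ~3.8)
  x <- rbind(TF1 = rnorm(15), TF2 = rnorm(15), g1 = rep(1, 15))
  me <- expression_matrix(x)
  sc <- list(fake_scores(s, "a"), fake_scores(s, "b"), fake_scores(s, "c"))
  expect_warning(ce <- consensus_edges(sc, me), "undefined Spearman")
  expect_false("g1" %in% ce$target)
})

test_that("integrate_edges appends slow-layer terms, skips duplicates", {
  net <- make_fixture("random_layered", 5, seed = 2)
  n_int0 <- nrow(net$interactions)
  edges <- data.frame(source = c("G1", "G2"), target = c("G3", "G3"),
                      sign = c(1L, -1L))
  net2 <- integrate_edges(net, edges)
  expect_equal(nrow(net2$interactions), n_int0 + 2)
  expect_true(all(c("G1", "G2") %in% net2$rules[["G3.slow"]]$terms$source))
  inferred <- net2$interactions[net2$interactions$provenance == "inferred", ]
  expect_equal(nrow(inferred), 2)
  expect_true(all(inferred$layer == "slow"))
  rep2 <- attr(net2, "integration_report")
  expect_equal(rep2$status, c("added", "added"))

  # adding the same edge again: count unchanged, duplicate reported
  net3 <- integrate_edges(net2, edges[1, ])
  expect_equal(nrow(net3$interactions), nrow(net2$interactions))
  expect_equal(attr(net3, "integration_report")$status, "duplicate")

  # empty edge list leaves the network unchanged
  net4 <- integrate_edges(net, edges[0, ])
  expect_true(networks_equal(net, net4))

  # unmappable ids error; explicit mapping is honored
  expect_error(integrate_edges(net, data.frame(source = "Sox9", target = "G1",
                                               sign = 1L)), "unmappable")
  net5 <- integrate_edges(net, data.frame(source = "Sox9", target = "G1",
                                          sign = 1L),
                          mapping = c(Sox9 = "G5"))
  expect_true("G5" %in% net5$rules[["G1.slow"]]$terms$source)
})
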