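toggle <- make_fixture("toggle_switch")
atts <- toggle_attractors()
apole <- atts[[1]]; bpole <- atts[[2]]
cfg <- engine_config(seed = 1)

fake_outcome <- function(clamps, healthy, none) {
  pct <- c(Healthy = healthy, None = none,
           Hypertrophic = 100 - healthy - none)
  structure(list(condition = perturbation_condition(clamps),
                 source = "Hypertrophic", n_reps = 100, n_experiments = 1,
                 pct_to = pct, sd_to = pct * 0),
            class = "transition_outcome")
}

test_that("run_condition reports transition percentages that sum to 100", {
  cond <- perturbation_condition(c(B = 1), duration = 200)
  out <- run_condition(toggle, apole, cond, atts, n_reps = 25,
                       n_experiments = 3, config = cfg)
  expect_equal(sum(out$pct_to), 100)
  expect_equal(unname(out$pct_to["Bpole"]), 100)   # forced flip of the toggle
  expect_true(all(out$sd_to <= 5))
  expect_error(run_condition(toggle, apole, cond, atts, n_reps = 0), "n_reps")
})

test_that("null perturbations (clamp at attractor value) never move the system", {
  fixtures <- list(
    list(net = toggle, att = apole, all = atts),
    list(net = toggle, att = bpole, all = atts),
    list(net = make_redundant_pair(),
         att = list(label = "On", global = c(M1 = 1, M2 = 1),
                    fast = c(M1 = 1, M2 = 1), slow = c(M1 = 1, M2 = 1)),
         all = list(list(label = "On", global = c(M1 = 1, M2 = 1),
                         fast = c(M1 = 1, M2 = 1), slow = c(M1 = 1, M2 = 1)),
                    list(label = "Off", global = c(M1 = 0, M2 = 0),
                         fast = c(M1 = 0, M2 = 0), slow = c(M1 = 0, M2 = 0)))))
  for (fx in fixtures) {
    for (comp in fx$net$components$id) {
      cond <- perturbation_condition(
        stats::setNames(fx$att$global[comp], comp), duration = 100)
      out <- run_condition(fx$net, fx$att, cond, fx$all, n_reps = 10,
                           n_experiments = 1, config = cfg)
      expect_equal(unname(out$pct_to[fx$att$label]), 100,
                   info = paste(fx$net$metadata$name, comp))
    }
  }
})

test_that("single screens enumerate 2N conditions and pairwise 2N(N-1)", {
  for (n in c(2, 3, 5, 7)) {
    net <- make_fixture("chain", n)
    expect_equal(nrow(enumerate_single_conditions(net)), 2 * n)
    expect_equal(nrow(enumerate_pairwise_conditions(net)), 2 * n * (n - 1))
  }
  net60 <- make_fixture("random_layered", 60, seed = 1)
  expect_equal(nrow(enumerate_pairwise_conditions(net60)), 7080)
})

test_that("the toggle's single-perturbation screen has the hand-derived outcomes", {
  sc <- screen_single(toggle, apole, atts, n_reps = 5, n_experiments = 1,
                      config = cfg)
  expect_length(sc, 4)
  got <- attr(sc, "summary")
  # A=0 kills the active pole -> Off; A=1 and B=0 are no-ops; B=1 flips
  expect_equal(got$Off[got$condition == "A=0"], 100)
  expect_equal(got$Apole[got$condition == "A=1"], 100)
  expect_equal(got$Apole[got$condition == "B=0"], 100)
  expect_equal(got$Bpole[got$condition == "B=1"], 100)
})

test_that("Markov summary rows sum to one and match the enumerated ensemble", {
  scA <- screen_single(toggle, apole, atts, n_reps = 5, n_experiments = 1,
                       config = cfg)
  scB <- screen_single(toggle, bpole, atts, n_reps = 5, n_experiments = 1,
                       config = engine_config(seed = 2))
  mk <- markov_summary(list(Apole = scA, Bpole = scB))
  expect_equal(unname(rowSums(mk)), c(1, 1))
  # hand-derived: each pole keeps itself under 2 of 4 conditions, flips under
  # one, collapses under one
  expect_equal(mk["Apole", "Apole"], 0.5)
  expect_equal(mk["Apole", "Bpole"], 0.25)
  expect_equal(mk["Apole", "Off"], 0.25)
  expect_equal(mk["Bpole", "Bpole"], 0.5)
  expect_error(markov_summary(list(Apole = scA), atts), "missing source")
  expect_error(markov_summary(unname(list(scA))), "named list")
})

test_that("an attractor no single clamp can escape has self-probability 1", {
  net <- make_redundant_pair()
  on <- list(label = "On", global = c(M1 = 1, M2 = 1),
             fast = c(M1 = 1, M2 = 1), slow = c(M1 = 1, M2 = 1))
  off <- list(label = "Off", global = c(M1 = 0, M2 = 0),
              fast = c(M1 = 0, M2 = 0), slow = c(M1 = 0, M2 = 0))
  sc <- screen_single(net, on, list(on, off), n_reps = 5, n_experiments = 1,
                      config = cfg)
  mk <- markov_summary(list(On = sc))
  expect_equal(mk["On", "On"], 1)
})

test_that("pairwise screens stream to JSON-lines and resume where they left off", {
  conds <- enumerate_pairwise_conditions(toggle)
  expect_equal(nrow(conds), 4)   # C(2,1) pairs... one pair, four sign combos
  out_file <- withr::local_tempfile(fileext = ".jsonl")
  first <- screen_pairwise(toggle, apole, atts, n_reps = 3,
                           config = cfg, out_file = out_file,
                           conditions = conds[1:2, ])
  expect_length(first, 2)
  expect_length(readLines(out_file), 2)
  rest <- screen_pairwise(toggle, apole, atts, n_reps = 3,
                          config = cfg, out_file = out_file)
  expect_length(rest, 2)         # the first two were skipped
  lines <- lapply(readLines(out_file), jsonlite::fromJSON)
  expect_setequal(vapply(lines, `[[`, "", "id"), conds$id)
  expect_true(all(vapply(lines, function(l) sum(unlist(l$pct_to)), 0) == 100))
})

test_that("select_candidates applies both thresholds, bins and exclusions", {
  outcomes <- list(
    fake_outcome(c(SMAD3 = 1, NFKB = 0), 100, 0),  # top bin
    fake_outcome(c(ALK5 = 1, ALK1 = 0), 92, 3),    # top bin
    fake_outcome(c(PKA = 1, WNT = 0), 85, 2),      # middle bin
    fake_outcome(c(IGF = 1, DC = 1), 71, 0),       # bottom bin
    fake_outcome(c(X1 = 1, X2 = 0), 71, 6),        # None too frequent
    fake_outcome(c(X3 = 1, X4 = 0), 69, 0),        # below the floor
    fake_outcome(c(RUNX2 = 0, SMAD3 = 1), 100, 0)) # excluded (TF)
  sel <- select_candidates(outcomes, exclude = "RUNX2")
  expect_equal(nrow(sel), 4)
  expect_equal(as.character(sel$bin),
               c("100-90", "100-90", "89-80", "79-70"))
  expect_false(any(grepl("RUNX2", sel$condition)))
  expect_error(select_candidates(outcomes, min_healthy_pct = 101), "\\[0, 100\\]")
  # boundary: exactly 70% healthy or exactly 5% None are rejected
  expect_equal(nrow(select_candidates(list(fake_outcome(c(A = 1, B = 1), 70, 0)))), 0)
  expect_equal(nrow(select_candidates(list(fake_outcome(c(A = 1, B = 1), 90, 5)))), 0)
})

test_that("dose grids cover every level pair and keep the null cell silent", {
  levels <- c(0, 0.5, 1)
  dg <- dose_grid(toggle, apole, atts, "A", "B", levels_x = levels,
                  levels_y = levels, n_reps = 3, config = cfg)
  expect_equal(dim(dg$cells), c(3, 3))
  stay <- dose_grid_pct(dg, "Apole")
  # clamping both components at their attractor values changes nothing
  expect_equal(stay["1", "0"], 100)
  # fully inverted clamp flips the toggle
  expect_equal(dose_grid_pct(dg, "Bpole")["0", "1"], 100)
  expect_error(dose_grid(toggle, apole, atts, "A", "B", levels_x = numeric(0)),
               "empty level")
  # 0..1 by 0.1 axes enumerate 121 cells
  dg2 <- dose_grid(toggle, apole, atts, "A", "B", n_reps = 1, config = cfg)
  expect_equal(length(dg2$cells), 121)
})

test_that("stochastic fixtures keep replicate dispersion within a few points", {
  net <- make_fixture("random_layered", 4, seed = 6)
  mc <- monte_carlo(net, n_init = 200, config = engine_config(seed = 5))
  labels <- paste0("S", seq_along(mc$attractors))
  for (i in seq_along(mc$attractors)) mc$attractors[[i]]$label <- labels[i]
  src <- mc$attractors[[1]]
  cond <- perturbation_condition(
    stats::setNames(1 - round(src$global[1]), names(src$global)[1]),
    duration = 200)
  out <- run_condition(net, src, cond, mc$attractors, n_reps = 100,
                       n_experiments = 3, config = engine_config(seed = 8))
  expect_equal(sum(out$pct_to), 100)
  expect_true(all(out$sd_to <= 5))
})
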