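test_that("the seed feature maximizes the configured criterion", {
  set.seed(201)
  y <- rep(c(-1, 1), each = 20)
  vals <- matrix(rnorm(40 * 6), 40, 6)
  vals[, 4] <- y                      # exact copy of the label
  em <- toy_expression(vals, y)
  expect_equal(select_seed(em, "mutual_information"), "f4")
  expect_equal(select_seed(em, "marginal_power"), "f4")
  # all-identical features: lexicographically first id wins
  emt <- toy_expression(matrix(rep(rnorm(40), 4), 40, 4), y)
  expect_equal(select_seed(emt, "mutual_information"), "f1")
  # definitional equivalence with ranking against the empty set
  f0 <- fit_svm(em, character(0))
  expect_equal(select_seed(em, "marginal_power"),
               rank_candidates(em, f0, character(0), feature_ids(em), t = 1)$feature)
})

test_that("with a singleton candidate set the loop is pure forward selection", {
  set.seed(205)
  st <- generate_study(synthetic_spec(n_samples = 40, n_features = 15,
                                      n_blocks = 2, block_size = 3,
                                      unresolved_fraction = 0, seed = 3))
  sel <- bpfs_select(st$data, st$graph, st$mapping, influence_model(),
                     target_count = 6, t = 1)
  # reproduce by hand: seed + repeated top-1 marginal power
  selected <- select_seed(st$data)
  while (length(selected) < 6) {
    fit <- fit_svm(st$data, selected)
    top <- rank_candidates(st$data, fit, selected,
                           setdiff(feature_ids(st$data), selected), t = 1)
    selected <- c(selected, top$feature)
  }
  expect_equal(sel$selected, selected)
})

test_that("an edgeless graph with all features resolved reduces to score-only selection", {
  set.seed(207)
  st <- generate_study(synthetic_spec(n_samples = 50, n_features = 20,
                                      n_blocks = 3, block_size = 3,
                                      unresolved_fraction = 0, seed = 8))
  blind_graph <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unname(st$mapping))
  sel_blind <- bpfs_select(st$data, blind_graph, st$mapping, influence_model(),
                           target_count = 7, t = 5)
  sel_t1 <- bpfs_select(st$data, blind_graph, st$mapping, influence_model(),
                        target_count = 7, t = 1)
  # every candidate has zero influence, so the best-scored one always wins
  expect_equal(sel_blind$selected, sel_t1$selected)
  expect_true(all(sel_blind$log$tif == 0))
})

test_that("pathway influence overrides score rank within the candidate set", {
  # constructed inversion: two strong candidates sit adjacent to the seed
  # gene on the graph, a slightly weaker third is disconnected
  set.seed(210)
  n <- 60
  y <- rep(c(-1, 1), each = n / 2)
  lat <- rnorm(n)
  seedv <- y * 1.2 + 0.3 * lat + rnorm(n, sd = 0.4)
  strong1 <- y * 1.1 + 0.8 * seedv + rnorm(n, sd = 0.3)
  strong2 <- y * 1.0 + 0.8 * seedv + rnorm(n, sd = 0.3)
  weak <- y * 0.8 + rnorm(n, sd = 0.6)
  noise <- matrix(rnorm(n * 2), n)
  em <- toy_expression(cbind(seedv, strong1, strong2, weak, noise), y)
  g <- consolidate(data.frame(a = c("g_f1", "g_f1"), b = c("g_f2", "g_f3")),
                   extra_vertices = c("g_f4", "g_f5", "g_f6"))
  map <- setNames(paste0("g_", feature_ids(em)), feature_ids(em))
  sel <- bpfs_select(em, g, map, influence_model(), target_count = 2, t = 3)
  it2 <- sel$log[sel$log$iteration == 2, ]
  expect_equal(sel$selected[1], "f1")
  # the top-scored candidates f2/f3 are graph neighbours of f1 (TIF 1);
  # f4 is disconnected (TIF 0) and must win despite its worse score rank
  expect_true(all(c("f2", "f3", "f4") %in% it2$feature))
  expect_equal(it2$feature[which(it2$chosen)], "f4")
  expect_gt(max(it2$tif), 0)
  # blind counterpart picks the best-scored neighbour instead
  blind <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unname(map))
  sel_b <- bpfs_select(em, blind, map, influence_model(), target_count = 2, t = 3)
  expect_true(sel_b$selected[2] %in% c("f2", "f3"))
  expect_false(identical(sel$selected, sel_b$selected))
})

test_that("all-unresolved features make influence constant, so score order decides", {
  set.seed(215)
  st <- generate_study(synthetic_spec(n_samples = 40, n_features = 12,
                                      n_blocks = 2, block_size = 3,
                                      unresolved_fraction = 1, seed = 4))
  sel <- bpfs_select(st$data, st$graph, st$mapping,
                     influence_model(p = 0.0088), target_count = 5, t = 4)
  for (it in 2:5) {
    rows <- sel$log[sel$log$iteration == it, ]
    expect_equal(rows$tif, rep(0.0088 * (it - 1), nrow(rows)))
    expect_equal(rows$feature[which(rows$chosen)], rows$feature[1])
  }
})

test_that("selection output is well-formed, deterministic, and fully logged", {
  st <- generate_study(synthetic_spec(n_samples = 50, n_features = 25, seed = 6))
  sel1 <- bpfs_select(st$data, st$graph, st$mapping, influence_model(),
                      target_count = 10, t = 4)
  sel2 <- bpfs_select(st$data, st$graph, st$mapping, influence_model(),
                      target_count = 10, t = 4)
  expect_identical(sel1$selected, sel2$selected)
  expect_identical(sel1$log, sel2$log)
  expect_length(sel1$selected, 10)
  expect_false(anyDuplicated(sel1$selected) > 0)
  per_it <- table(sel1$log$iteration)
  expect_true(all(per_it[-1] <= 4))
  expect_equal(sum(sel1$log$chosen), 10)
  expect_error(bpfs_select(st$data, st$graph, st$mapping, influence_model(),
                           target_count = 26, t = 4), "exceeds")
  # serialization
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".jsonl")
  write_selection(sel1, p1)
  tab <- read.table(p1, header = TRUE, sep = "\t")
  expect_equal(tab$feature, sel1$selected)
  write_candidate_log(sel1, p2)
  lines <- readLines(p2)
  expect_length(lines, 10)
  expect_equal(jsonlite::fromJSON(lines[2])$iteration, 2)
})

test_that("pathway-aware selection never covers fewer blocks when score ties are graph-resolved", {
  # candidates tied in score but differing in graph redundancy: the aware
  # run must spread across modules at least as well as the blind run
  covered <- function(sel, blocks) length(unique(na.omit(blocks[sel])))
  set.seed(440)
  n <- 80
  y <- rep(c(-1, 1), each = n / 2)
  # three blocks of two IDENTICAL columns each: scores tie exactly, so the
  # blind tie-break (feature id) stays inside a block while influence
  # pushes the aware run to a fresh block
  base <- vapply(1:3, function(b) y * 1.5 + rnorm(n), numeric(n))
  vals <- base[, c(1, 1, 2, 2, 3, 3)] + 0
  em <- toy_expression(vals, y)
  blocks <- setNames(rep(1:3, each = 2), feature_ids(em))
  edges <- data.frame(a = paste0("g_", c("f1", "f3", "f5")),
                      b = paste0("g_", c("f2", "f4", "f6")))
  g <- consolidate(edges)
  map <- setNames(paste0("g_", feature_ids(em)), feature_ids(em))
  aware <- bpfs_select(em, g, map, influence_model(), target_count = 3, t = 6)
  blind_g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unname(map))
  blind <- bpfs_select(em, blind_g, map, influence_model(),
                       target_count = 3, t = 6)
  expect_equal(covered(aware$selected, blocks), 3)
  expect_gte(covered(aware$selected, blocks), covered(blind$selected, blocks))
})
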