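test_that("every generator is deterministic at a fixed seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(make_alkane_ladder(cfg), make_alkane_ladder(cfg))
  expect_identical(make_component_table(cfg), make_component_table(cfg))
  expect_identical(make_bipartite_edges(cfg), make_bipartite_edges(cfg))
  expect_identical(make_pathways(cfg), make_pathways(cfg))
  expect_identical(make_de_table(cfg), make_de_table(cfg))
  expect_identical(make_docking_scores(cfg), make_docking_scores(cfg))
  # different seeds give different draws
  expect_false(identical(make_component_table(cfg),
                         make_component_table(sim_config(seed = 100))))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(7)
  a <- runif(1)
  set.seed(7)
  invisible(make_component_table(sim_config(seed = 1)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("generated ladders span C8-C40 and stay strictly increasing", {
  for (seed in c(1, 7, 2026)) {
    lad <- make_alkane_ladder(sim_config(seed = seed))
    expect_equal(nrow(lad), 33L)
    expect_equal(lad$carbon_number, 8:40)
    expect_true(all(diff(lad$retention_time_min) > 0))
    # consistency with the retention-index module at the ladder's own points
    expect_equal(kovats_ri(lad$retention_time_min, lad),
                 100 * lad$carbon_number)
  }
})

test_that("generated component tables respect content and log P bounds", {
  cfg <- sim_config(seed = 5)
  tab <- make_component_table(cfg)
  expect_equal(nrow(tab), cfg$n_components)
  expect_false(anyDuplicated(tab$name) > 0)
  expect_true(all(tab$content_pct >= 0))
  expect_lte(sum(tab$content_pct), 100)
  expect_true(all(tab$log_p >= -2 & tab$log_p <= 8))
})

test_that("generated log P values center on the configured mean", {
  cfg <- sim_config(seed = 6, n_components = 10000L)
  tab <- make_component_table(cfg)
  se <- cfg$logp_sd / sqrt(cfg$n_components)
  # truncation at [-2, 8] is >3 sd out for the defaults, so the bias is
  # far below the Monte-Carlo tolerance
  expect_lt(abs(mean(tab$log_p) - cfg$logp_mean), 3 * se + 0.01)
})

test_that("edge probability 0 and 1 give empty and complete bipartite sets", {
  cfg0 <- sim_config(seed = 8, edge_probability = 0)
  expect_equal(nrow(make_bipartite_edges(cfg0)), 0L)
  cfg1 <- sim_config(seed = 8, edge_probability = 1)
  edges <- make_bipartite_edges(cfg1)
  expect_equal(nrow(edges), cfg1$n_components * cfg1$n_targets)
  expect_equal(anyDuplicated(edges), 0L)
})

test_that("empirical edge density is within binomial tolerance", {
  cfg <- sim_config(seed = 9, n_components = 40L, n_targets = 50L,
                    edge_probability = 0.3)
  n_pairs <- cfg$n_components * cfg$n_targets
  hits <- sum(vapply(1:10, function(i) {
    nrow(make_bipartite_edges(sim_config(seed = 9 + i, n_components = 40L,
                                         n_targets = 50L,
                                         edge_probability = 0.3)))
  }, numeric(1)))
  n_total <- 10 * n_pairs
  se <- sqrt(0.3 * 0.7 / n_total)
  expect_lt(abs(hits / n_total - 0.3), 4 * se)
})

test_that("generated pathways are non-empty subsets of the target universe", {
  cfg <- sim_config(seed = 10)
  pw <- make_pathways(cfg)
  expect_equal(nrow(pw), cfg$n_pathways)
  members <- strsplit(pw$target_symbols, ";", fixed = TRUE)
  expect_true(all(lengths(members) >= 1L))
  tgts <- sprintf("TGT%02d", seq_len(cfg$n_targets))
  expect_true(all(unlist(members) %in% tgts))
})

test_that("frac_de = 0 yields no significant genes at zero noise", {
  cfg <- sim_config(seed = 12, frac_de = 0, noise_sd = 0, n_genes = 500L)
  de <- make_de_table(cfg)
  res <- classify_degs(de$stats)
  expect_equal(unname(res$counts[c("up", "down")]), c(0L, 0L))
})

test_that("noisy recovery rate matches the normal exceedance probability", {
  # planted logFC = effect +- N(0, 0.5); recovery as 'up' for a positive
  # plant requires logFC > 1.2, i.e. P = pnorm((2.0 - 1.2) / 0.5)
  p_recover <- pnorm((2.0 - 1.2) / 0.5)
  recovered <- total <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(seed = seed, n_genes = 50L, frac_de = 0.4,
                      effect_size = 2.0, noise_sd = 0.5)
    de <- make_de_table(cfg)
    res <- classify_degs(de$stats)
    got <- setNames(as.character(res$table$regulation),
                    res$table$gene_symbol)
    want <- setNames(de$truth$label, toupper(de$truth$gene_symbol))
    planted <- names(want)[want != "not_significant"]
    recovered <- recovered + sum(got[planted] == want[planted])
    total <- total + length(planted)
  }
  se <- sqrt(p_recover * (1 - p_recover) / total)
  expect_lt(abs(recovered / total - p_recover), 4 * se)
})

test_that("docking generator produces positive ratios that pass assembly", {
  cfg <- sim_config(seed = 13)
  dock <- make_docking_scores(cfg)
  expect_true(all(dock$controls$positive_control_score > 0))
  ratio <- dock$dockings$raw_score /
    dock$controls$positive_control_score[
      match(dock$dockings$target_symbol, dock$controls$target_symbol)]
  expect_true(all(ratio > 0))
  # generated tables satisfy the docking module's referential contract
  z <- component_scores(make_component_table(cfg))
  sm <- score_matrix(dock$dockings, dock$controls, z)
  expect_equal(dim(sm$matrix), c(cfg$n_components, cfg$n_targets))
  expect_false(anyNA(sm$matrix))
})

test_that("generated inputs pass every consuming validator", {
  cfg <- sim_config(seed = 14)
  expect_s3_class(validate_alkane_ladder(make_alkane_ladder(cfg)),
                  "alkane_ladder")
  comps <- validate_component_table(make_component_table(cfg))
  st <- score_all(comps, make_bipartite_edges(cfg), make_pathways(cfg))
  expect_s3_class(st, "score_table")
  expect_equal(nrow(st$n), cfg$n_pathways)
})

test_that("sim_config validates counts, probabilities and dispersions", {
  expect_error(sim_config(n_components = 0), "positive count")
  expect_error(sim_config(edge_probability = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(frac_de = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(sim_config(logp_sd = 0), "positive")
})
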