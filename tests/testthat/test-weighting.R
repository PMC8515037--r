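test_that("absorption_fraction matches its closed form and symmetry", {
  expect_equal(absorption_fraction(0), 0.5)
  expect_equal(absorption_fraction(1), 10 / 11)
  expect_equal(absorption_fraction(-1), 1 / 11)
  grid <- seq(-8, 8, length.out = 1000)
  expect_equal(absorption_fraction(grid) + absorption_fraction(-grid),
               rep(1, length(grid)))
  # strictly increasing, bounded in (0, 1)
  vals <- absorption_fraction(grid)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  expect_error(absorption_fraction(Inf), "finite")
  expect_error(absorption_fraction(NA_real_), "finite")
})

test_that("component Z score is absorption fraction times content", {
  comps <- validate_component_table(data.frame(
    name = c("a", "b", "c"), cas = "",
    content_pct = c(10, 0, 18.527),
    retention_index = c(900, 1000, 1467.285),
    log_p = c(0, 3, 6), stringsAsFactors = FALSE))
  z <- component_scores(comps)
  expect_equal(z$z_score[z$component_name == "a"], 5)
  expect_equal(z$z_score[z$component_name == "b"], 0)
  # independent evaluation of the closed form at log P = 6
  expect_equal(z$z_score[z$component_name == "c"],
               18.527 * (1e6 / (1e6 + 1)))
  expect_true(all(z$z_score <= comps$content_pct[match(z$component_name,
                                                       comps$name)]))
})

test_that("missing log P errors by name, or skips under the explicit flag", {
  comps <- validate_component_table(data.frame(
    name = c("good", "bad"), cas = "", content_pct = c(1, 2),
    retention_index = c(900, 950), log_p = c(2, NA),
    stringsAsFactors = FALSE))
  expect_error(component_scores(comps), "bad")
  expect_warning(z <- component_scores(comps, on_missing_logp = "skip"),
                 "bad")
  expect_equal(z$component_name, "good")
})

test_that("duplicate component names are rejected as ambiguous", {
  comps <- data.frame(name = c("x", "x"), cas = "", content_pct = c(1, 2),
                      retention_index = c(900, 950), log_p = c(1, 1),
                      stringsAsFactors = FALSE)
  expect_error(component_scores(validate_component_table(comps)),
               "duplicate component")
})

test_that("target scores deduplicate edges and sum incident Z", {
  comps <- validate_component_table(data.frame(
    name = c("a", "b"), cas = "", content_pct = c(2, 4),
    retention_index = c(900, 950), log_p = c(0, 0),
    stringsAsFactors = FALSE))
  z <- component_scores(comps)  # z: a = 1, b = 2
  edges <- data.frame(component_name = c("a", "b", "b", "a"),
                      target_symbol = c("T1", "T1", "T1", "t2"))
  t <- target_scores(z, edges)
  expect_equal(t$t_score[t$target_symbol == "T1"], 3)  # duplicate b edge collapsed
  expect_equal(t$t_score[t$target_symbol == "T2"], 1)  # symbol uppercased
  expect_error(target_scores(z, data.frame(component_name = "ghost",
                                           target_symbol = "T1")),
               "unknown component")
})

test_that("pathway scores sum member T, absentees contribute zero", {
  t <- data.frame(target_symbol = c("T1", "T2"), t_score = c(1.5, 2.5))
  pw <- data.frame(pathway_id = c("p1", "p2"),
                   target_symbols = c("T1;T2;NOT_SCORED", "NOT_SCORED"))
  n <- pathway_scores(t, pw)
  expect_equal(n$n_score[n$pathway_id == "p1"], 4)
  expect_equal(n$n_score[n$pathway_id == "p2"], 0)
  expect_error(pathway_scores(t, pw[0, , drop = FALSE]), "empty")
  expect_error(pathway_scores(t, data.frame(pathway_id = "p", target_symbols = "")),
               "non-empty")
})

test_that("Z/T/N cascade agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:200) {
    comps <- random_component_table(sample(1:10, 1L))
    edges <- random_edges(comps, sample(1:10, 1L))
    pathways <- random_pathway_list(sample(1:5, 1L), 10L)
    want <- oracle_cascade(comps, edges, pathways)
    st <- score_all(comps, edges, pathway_list_to_table(pathways))
    expect_equal(st$z$z_score,
                 unname(want$z[st$z$component_name]), tolerance = 1e-12)
    expect_equal(st$t$t_score,
                 unname(want$t[st$t$target_symbol]), tolerance = 1e-12)
    expect_equal(st$n$n_score,
                 unname(want$n[st$n$pathway_id]), tolerance = 1e-12)
  }
})

test_that("scaling all contents by c scales Z, T and N by exactly c", {
  set.seed(102)
  comps <- random_component_table(8)
  edges <- random_edges(comps, 6)
  pathways <- pathway_list_to_table(random_pathway_list(4, 6))
  base <- score_all(comps, edges, pathways)
  for (c_scale in c(0.25, 3, 17.5)) {
    scaled <- comps
    scaled$content_pct <- scaled$content_pct * c_scale
    st <- score_all(scaled, edges, pathways)
    expect_equal(st$z$z_score, base$z$z_score * c_scale, tolerance = 1e-12)
    expect_equal(st$t$t_score, base$t$t_score * c_scale, tolerance = 1e-12)
    expect_equal(st$n$n_score, base$n$n_score * c_scale, tolerance = 1e-12)
  }
})

test_that("N is conserved when pathways partition the target set", {
  set.seed(103)
  comps <- random_component_table(6)
  edges <- random_edges(comps, 9, p = 0.6)
  tgts <- unique(toupper(edges$target_symbol))
  split_idx <- sample(rep(1:3, length.out = length(tgts)))
  partition <- split(tgts, split_idx)
  names(partition) <- paste0("part", seq_along(partition))
  st <- score_all(comps, edges, pathway_list_to_table(partition))
  expect_equal(sum(st$n$n_score), sum(st$t$t_score), tolerance = 1e-12)
})

test_that("normalization rescales scores without touching rankings", {
  set.seed(104)
  comps <- random_component_table(7)
  edges <- random_edges(comps, 5)
  plain <- score_all(comps, edges)
  norm <- score_all(comps, edges, normalize = TRUE)
  expect_equal(norm$z$component_name, plain$z$component_name)
  expect_equal(norm$t$target_symbol, plain$t$target_symbol)
  expect_equal(norm$z$z_score * sum(comps$content_pct), plain$z$z_score,
               tolerance = 1e-12)
})

test_that("score_all handles degenerate chains and empty edge lists", {
  comps <- validate_component_table(data.frame(
    name = "only", cas = "", content_pct = 10, retention_index = 1000,
    log_p = 1, stringsAsFactors = FALSE))
  # single component -> single target -> single pathway: N = T = Z
  st <- score_all(comps,
                  data.frame(component_name = "only", target_symbol = "T1"),
                  data.frame(pathway_id = "p", target_symbols = "T1"))
  expect_equal(st$z$z_score, 10 * 10 / 11)
  expect_equal(st$t$t_score, st$z$z_score)
  expect_equal(st$n$n_score, st$z$z_score)
  # empty edges: no targets, all pathway scores zero
  st0 <- score_all(comps, data.frame(component_name = character(0),
                                     target_symbol = character(0)),
                   data.frame(pathway_id = "p", target_symbols = "T1"))
  expect_equal(nrow(st0$t), 0L)
  expect_equal(st0$n$n_score, 0)
})

test_that("score tables print and summarize without error", {
  set.seed(105)
  comps <- random_component_table(5)
  st <- score_all(comps, random_edges(comps, 4))
  expect_output(print(st), "weight coefficient")
  expect_output(print(summary(st)), "components")
})
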