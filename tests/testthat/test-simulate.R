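test_that("label simulation hits the requested class ratio exactly and deterministically", {
  cfg <- sim_config(n_genes = 1137, minority_fraction = 115 / 1137, seed = 3)
  labs <- simulate_labels(cfg)
  expect_equal(sum(labs$label == "DR"), 115)
  expect_equal(sum(labs$label == "NotDR"), 1022)

  cfg2 <- sim_config(n_genes = 20, minority_fraction = 0.5, seed = 99)
  expect_equal(sum(simulate_labels(cfg2)$label == "DR"), 10)

  expect_identical(simulate_labels(cfg), simulate_labels(cfg))
  # different seed, different assignment (same counts)
  cfg_b <- sim_config(n_genes = 1137, minority_fraction = 115 / 1137, seed = 4)
  expect_false(identical(simulate_labels(cfg)$label, simulate_labels(cfg_b)$label))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_genes = 10, minority_fraction = 0.05),
               class = "drinfer_config_error")
  expect_error(sim_config(n_binary_features = 3, n_enriched_features = 5),
               class = "drinfer_config_error")
  expect_error(sim_config(minority_fraction = 1.2), class = "drinfer_config_error")
})

test_that("binary matrix: planted enrichment matches its binomial law, null knobs behave", {
  # binomial oracle on the generator's own draws: minority positive rate for
  # planted features should sit within 3 SE of base * odds = 0.20
  cfg <- sim_config(n_genes = 2000, minority_fraction = 0.1,
                    n_binary_features = 10, n_enriched_features = 4,
                    base_positive_rate = 0.04, enrichment_odds = 5, seed = 11)
  labs <- simulate_labels(cfg)
  bm <- simulate_binary_matrix(labs, cfg)
  m <- as.matrix(bm$matrix[bm$planted])
  minority <- labs$label == "DR"
  n_draws <- sum(minority) * length(bm$planted)
  rate <- mean(m[minority, ])
  se <- sqrt(0.2 * 0.8 / n_draws)
  expect_lt(abs(rate - 0.2), 3 * se)
  # non-planted columns stay at base rate in the minority too
  m0 <- as.matrix(bm$matrix[setdiff(names(bm$matrix), c("gene_id", bm$planted))])
  rate0 <- mean(m0[minority, ])
  se0 <- sqrt(0.04 * 0.96 / length(m0[minority, ]))
  expect_lt(abs(rate0 - 0.04), 3 * se0)

  # base rate 0: non-planted columns identically zero
  cfg0 <- sim_config(n_genes = 100, n_binary_features = 6, n_enriched_features = 2,
                     base_positive_rate = 0, enrichment_odds = 50, seed = 5)
  bm0 <- simulate_binary_matrix(simulate_labels(cfg0), cfg0)
  nonplanted <- setdiff(names(bm0$matrix), c("gene_id", bm0$planted))
  expect_true(all(as.matrix(bm0$matrix[nonplanted]) == 0))

  # odds = 1: planted columns share the base generating rate
  cfg1 <- sim_config(n_genes = 2000, n_binary_features = 10, n_enriched_features = 5,
                     base_positive_rate = 0.1, enrichment_odds = 1, seed = 6)
  labs1 <- simulate_labels(cfg1)
  bm1 <- simulate_binary_matrix(labs1, cfg1)
  mp <- as.matrix(bm1$matrix[bm1$planted])
  rate1 <- mean(mp[labs1$label == "DR", ])
  se1 <- sqrt(0.1 * 0.9 / (sum(labs1$label == "DR") * 5))
  expect_lt(abs(rate1 - 0.1), 3 * se1)
})

test_that("annotation DAG is rooted, acyclic, and unpropagated", {
  cfg <- sim_config(n_genes = 30, dag_depth = 3, dag_branching = 3, seed = 8)
  labs <- simulate_labels(cfg)
  dag <- simulate_dag_annotations(labs, cfg)
  g <- igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                     vertices = data.frame(name = dag$terms))
  expect_true(igraph::is_dag(g))
  # reachability oracle: every node has a directed path to the root
  d <- igraph::distances(g, to = dag$root, mode = "out")
  expect_true(all(is.finite(d)))
  # single root: only the root has no parent
  expect_identical(setdiff(dag$edges$parent, dag$edges$child), dag$root)
  # direct annotations are not closed: at least one annotated term has an
  # unannotated ancestor for some gene (propagation is the builders' job)
  closed <- propagate_annotations(dag)
  expect_gt(nrow(closed$annotations), nrow(dag$annotations))
})

test_that("depth-1 DAG is a star around the root", {
  cfg <- sim_config(n_genes = 20, dag_depth = 1, dag_branching = 4, seed = 2)
  dag <- simulate_dag_annotations(simulate_labels(cfg), cfg)
  expect_true(all(dag$edges$parent == dag$root))
})

test_that("simulated graphs: density zero is edgeless, PPI is simple, seeds reproduce", {
  cfg0 <- sim_config(n_genes = 20, graph_n_nodes = 10, graph_edge_density = 0, seed = 3)
  expect_equal(igraph::ecount(simulate_pathway_graph(cfg0)), 0)

  cfg <- sim_config(n_genes = 40, graph_n_nodes = 15, graph_edge_density = 0.2, seed = 3)
  g1 <- simulate_pathway_graph(cfg)
  g2 <- simulate_pathway_graph(cfg)
  expect_identical(igraph::as_data_frame(g1), igraph::as_data_frame(g2))
  # acyclic mode guarantees a zero-in-degree source
  expect_gte(sum(igraph::degree(g1, mode = "in") == 0), 1)
  expect_true(igraph::is_dag(g1))

  labs <- simulate_labels(cfg)
  net <- simulate_ppi_network(labs, cfg)
  expect_false(igraph::any_loop(net))
  expect_false(igraph::any_multiple(net))
  net2 <- simulate_ppi_network(labs, cfg)
  expect_identical(igraph::as_data_frame(net), igraph::as_data_frame(net2))
})

test_that("continuous matrix: null planted columns keep nominal type-I error", {
  # Monte-Carlo: with effect_size = 0 the two-sample t statistic on planted
  # columns follows its null law, so rejections at alpha = 0.05 stay nominal
  reps <- 300
  pvals <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_genes = 40, minority_fraction = 0.5,
                      n_continuous_features = 1, n_planted_continuous = 1,
                      continuous_effect_size = 0, seed = 10000 + r)
    labs <- simulate_labels(cfg)
    cm <- simulate_continuous_matrix(labs, cfg)
    v <- cm$matrix[[cm$planted]]
    stats::t.test(v[labs$label == "DR"], v[labs$label == "NotDR"])$p.value
  }, double(1))
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("continuous matrix: huge effect puts planted features first in F ranking", {
  cfg <- sim_config(n_genes = 400, n_continuous_features = 30,
                    n_planted_continuous = 3, continuous_effect_size = 10, seed = 21)
  labs <- simulate_labels(cfg)
  cm <- simulate_continuous_matrix(labs, cfg)
  plan <- fit_univariate_k(cm$matrix, labs, k = 3)
  expect_setequal(retained_features(plan), cm$planted)
  expect_identical(cm$matrix, simulate_continuous_matrix(labs, cfg)$matrix)
})
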