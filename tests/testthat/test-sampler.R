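test_that("partition_seeds shuffles into fixed-size batches", {
  ids <- sprintf("d%04d", 1:1801)
  b <- partition_seeds(ids, 164L, rng_seed = 1)
  expect_length(b, 11L)
  expect_equal(unname(lengths(b)), c(rep(164L, 10), 161L))
  expect_setequal(unlist(b), ids)
  expect_identical(b, partition_seeds(ids, 164L, rng_seed = 1))
  expect_false(identical(b, partition_seeds(ids, 164L, rng_seed = 2)))
  expect_length(partition_seeds(ids[1:10], 10L, rng_seed = 1), 1L)
})

test_that("unbinding budgets recover the exact L-hop neighbourhood", {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 20, n_disease = 15,
                                          n_protein = 30, n_pathway = 5,
                                          rng_seed = 8))
  g <- add_reverse_relations(sim$graph)
  seeds <- g$nodes$drug[1:4]
  for (L in 1:3) {
    sb <- sample_subgraph(g, seeds, sampler_config(depth = L, budget = 10000L,
                                                   batch_size = 4L),
                          rng_seed = 1)
    # BFS oracle over the undirected neighbour structure
    reach <- stats::setNames(lapply(names(g$nodes), function(x) character()),
                             names(g$nodes))
    reach$drug <- seeds
    frontier <- list(drug = seeds)
    for (step in seq_len(L)) {
      nxt <- stats::setNames(lapply(names(g$nodes), function(x) character()),
                             names(g$nodes))
      for (r in g$relations) {
        hit <- r$src %in% frontier[[r$src_type]]
        nxt[[r$dst_type]] <- c(nxt[[r$dst_type]], r$dst[hit])
        hit2 <- r$dst %in% frontier[[r$dst_type]]
        nxt[[r$src_type]] <- c(nxt[[r$src_type]], r$src[hit2])
      }
      frontier <- lapply(names(nxt), function(ty)
        setdiff(unique(nxt[[ty]]), reach[[ty]]))
      names(frontier) <- names(nxt)
      for (ty in names(nxt)) reach[[ty]] <- union(reach[[ty]], frontier[[ty]])
    }
    for (ty in names(reach))
      expect_setequal(sb$subgraph$nodes[[ty]], reach[[ty]])
  }
})

test_that("per-iteration per-type additions respect the budget", {
  sim <- generate_synthetic_kg(synth_spec(rng_seed = 13))
  g <- add_reverse_relations(sim$graph)
  cfg <- sampler_config(depth = 3L, budget = 40L, batch_size = 25L)
  sb <- sample_subgraph(g, g$nodes$drug[1:25], cfg, rng_seed = 3)
  for (it in sb$new_per_iter) expect_true(all(it <= 40L))
  # seeds always included
  expect_true(all(g$nodes$drug[1:25] %in% sb$subgraph$nodes$drug))
})

test_that("sampling is deterministic and yields valid induced subgraphs", {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 40, n_disease = 30,
                                          n_protein = 60, rng_seed = 19))
  g <- add_reverse_relations(sim$graph)
  cfg <- sampler_config(depth = 2L, budget = 25L, batch_size = 10L)
  s1 <- sample_subgraph(g, g$nodes$drug[1:10], cfg, rng_seed = 7)
  s2 <- sample_subgraph(g, g$nodes$drug[1:10], cfg, rng_seed = 7)
  expect_identical(s1$subgraph$nodes, s2$subgraph$nodes)
  expect_identical(s1$subgraph$relations, s2$subgraph$relations)
  # induced-subgraph property: every edge of the parent with both endpoints
  # sampled is present, and nothing else
  ref <- induce_subgraph(g, s1$subgraph$nodes)
  expect_identical(s1$subgraph$relations, ref$relations)
  expect_error(sample_subgraph(g, character(), cfg), class = "hgt_config_error")
  expect_error(sample_subgraph(g, "ghost", cfg), class = "hgt_lookup_error")
})

test_that("raising budgets never shrinks the sampled subgraph below, and the
           full-budget subgraph dominates", {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 40, n_disease = 30,
                                          n_protein = 60, rng_seed = 23))
  g <- add_reverse_relations(sim$graph)
  seeds <- g$nodes$drug[1:8]
  n_small <- n_nodes(sample_subgraph(g, seeds,
                                     sampler_config(depth = 2, budget = 10,
                                                    batch_size = 8),
                                     rng_seed = 5)$subgraph)
  n_big <- n_nodes(sample_subgraph(g, seeds,
                                   sampler_config(depth = 2, budget = 10000,
                                                  batch_size = 8),
                                   rng_seed = 5)$subgraph)
  expect_lte(n_small, n_big)
})

test_that("coverage_report counts usable positives exactly", {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 20, n_disease = 15,
                                          n_protein = 25, rng_seed = 29))
  g <- sim$graph
  split <- split_indications(g, "indication", 0.8, rng_seed = 2)
  gm <- add_reverse_relations(apply_split(g, split))
  full <- sample_subgraph(gm, g$nodes$drug,
                          sampler_config(depth = 3, budget = 10000,
                                         batch_size = 20), rng_seed = 1)
  rep_full <- coverage_report(list(full), split)
  # full subgraph sees every masked pair whose endpoints are still connected
  by_hand <- sum(split$masked$drug %in% full$subgraph$nodes$drug &
                   split$masked$disease %in% full$subgraph$nodes$disease)
  expect_equal(rep_full$usable_positives, by_hand)
  # a batch without diseases has zero usable positives
  no_dis <- full
  no_dis$subgraph <- induce_subgraph(gm, list(drug = gm$nodes$drug,
                                              protein = gm$nodes$protein))
  expect_equal(coverage_report(list(no_dis), split)$usable_positives, 0L)
  expect_error(coverage_report(list(), split), class = "hgt_config_error")
})

test_that("masked and validation pairs never appear in sampled subgraphs", {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 30, n_disease = 20,
                                          n_protein = 40, rng_seed = 37))
  g <- sim$graph
  pairs <- indication_pairs(g, "indication")
  val <- pairs[seq_len(10), ]
  split <- split_indications(g, "indication", 0.8, rng_seed = 3,
                             validation = val)
  gm <- add_reverse_relations(apply_split(g, split))
  hidden <- c(pair_key(split$masked$drug, split$masked$disease),
              pair_key(val$drug, val$disease))
  for (seed in 1:5) {
    sb <- sample_subgraph(gm, g$nodes$drug,
                          sampler_config(depth = 3, budget = 50,
                                         batch_size = 30), rng_seed = seed)
    for (key in relation_keys(sb$subgraph)) {
      r <- sb$subgraph$relations[[key]]
      expect_length(intersect(c(pair_key(r$src, r$dst), pair_key(r$dst, r$src)),
                              hidden), 0)
    }
  }
})
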