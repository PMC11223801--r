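# Small graph builders used across tests.

# drugs {d1,d2,d3}, diseases {s1,s2}, protein p1; indication (d1,s1); (d2,p1)
toy_graph <- function() {
  hetero_graph(
    nodes = list(drug = c("d1", "d2", "d3"), disease = c("s1", "s2"),
                 protein = c("p1")),
    relations = list(
      indication = list(relation = "indication", src_type = "drug",
                        dst_type = "disease", src = "d1", dst = "s1"),
      drug_protein = list(relation = "drug_protein", src_type = "drug",
                          dst_type = "protein", src = "d2", dst = "p1")))
}

# seeded random heterograph: 3-5 node types, >= 4 relation types
random_heterograph <- function(seed, max_nodes = 50L, n_types = 3L,
                               n_relations = 4L, p_edge = 0.25) {
  with_seed(seed, {
    n_types <- max(3L, n_types)
    types <- paste0("T", seq_len(n_types))
    per_type <- pmax(2L, as.integer(stats::rmultinom(1, max_nodes - 2L * n_types,
                                                     rep(1, n_types))) + 2L)
    nodes <- lapply(seq_len(n_types), function(i)
      sprintf("%s_n%02d", types[i], seq_len(per_type[i])))
    names(nodes) <- types
    relations <- list()
    for (r in seq_len(max(4L, n_relations))) {
      st <- sample(types, 1); dt <- sample(types, 1)
      grid <- expand.grid(src = nodes[[st]], dst = nodes[[dt]],
                          stringsAsFactors = FALSE)
      if (st == dt) grid <- grid[grid$src != grid$dst, ]
      keep <- stats::runif(nrow(grid)) < p_edge
      relations[[paste0("R", r)]] <- list(relation = paste0("R", r),
                                          src_type = st, dst_type = dt,
                                          src = grid$src[keep], dst = grid$dst[keep])
    }
    hetero_graph(nodes, relations)
  })
}

random_states <- function(g, d, seed) {
  with_seed(seed, {
    H <- lapply(g$nodes, function(ids)
      matrix(stats::rnorm(length(ids) * d), length(ids), d))
    H
  })
}

# benchmark-conditions simulation + embedded graph, small-budget variants
bench_spec <- function(...) synth_spec(rng_seed = 101L, ...)

embedded_graph <- function(sim) attach_embeddings(sim$graph, sim$embeddings)
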