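# helper: layer params with deterministic identity-style weights
identity_layer <- function(types, relations, d_model, h) {
  cfg <- encoder_config(d_model = d_model, n_heads = h, n_layers = 1L,
                        activation = "relu")
  lp <- hgt_layer_params(types, relations, cfg, rng_seed = 1)
  dh <- lp$d_head
  for (ty in types) {
    for (nm in c("k", "q", "m", "a"))
      lp$par[[nm]][[ty]] <- list(W = diag(d_model), b = rep(0, d_model))
  }
  for (key in relations$key) {
    lp$par$att[[key]] <- array(diag(dh), c(dh, dh, h))
    lp$par$msg[[key]] <- array(diag(dh), c(dh, dh, h))
    lp$par$mu[[key]] <- 1
  }
  lp
}

two_neighbor_graph <- function() {
  hetero_graph(
    nodes = list(src = c("a", "b"), tgt = "t"),
    relations = list(rel = list(relation = "rel", src_type = "src",
                                dst_type = "tgt", src = c("a", "b"),
                                dst = c("t", "t"))))
}

test_that("attention of a singleton neighbourhood is exactly one", {
  g <- hetero_graph(
    nodes = list(src = "a", tgt = "t"),
    relations = list(rel = list(relation = "rel", src_type = "src",
                                dst_type = "tgt", src = "a", dst = "t")))
  lp <- hgt_layer_params(node_types(g), meta_relations(g),
                         encoder_config(d_model = 8, n_heads = 4, n_layers = 1),
                         rng_seed = 3)
  H <- random_states(g, 8, 5)
  at <- hgt_attention(g, H, lp)
  expect_equal(unname(at$tgt$weights), matrix(1, 1, 4))
})

test_that("two-neighbour attention reproduces the hand-computed softmax", {
  g <- two_neighbor_graph()
  lp <- identity_layer(node_types(g), meta_relations(g), d_model = 2, h = 1)
  H <- list(src = rbind(c(1, 0), c(0, 1)), tgt = rbind(c(1, 0)))
  at <- hgt_attention(g, H, lp)
  # scores: (K . Q)/sqrt(2) = 1/sqrt(2) for a, 0 for b
  expected <- exp(c(1 / sqrt(2), 0)); expected <- expected / sum(expected)
  expect_equal(unname(at$tgt$weights[, 1]), expected, tolerance = 1e-12)
  expect_equal(round(expected, 3), c(0.670, 0.330))
})

test_that("per-head attention over in-neighbours sums to one on random graphs", {
  for (seed in 1:10) {
    g <- random_heterograph(seed, max_nodes = 40)
    cfg <- encoder_config(d_model = 8, n_heads = 4, n_layers = 1)
    lp <- hgt_layer_params(node_types(g), meta_relations(g), cfg,
                           rng_seed = seed + 100)
    H <- random_states(g, 8, seed + 200)
    at <- hgt_attention(g, H, lp)
    for (tt in names(at)) {
      sums <- rowsum(at[[tt]]$weights,
                     match(at[[tt]]$edges$dst, unique(at[[tt]]$edges$dst)))
      expect_lt(max(abs(sums - 1)), 1e-6)
    }
  }
})

test_that("identity messages pass the source state through", {
  g <- two_neighbor_graph()
  lp <- identity_layer(node_types(g), meta_relations(g), d_model = 2, h = 1)
  H <- list(src = rbind(c(0.3, -0.7), c(2, 1)), tgt = rbind(c(0, 0)))
  ms <- hgt_messages(g, H, lp)
  expect_equal(unname(ms$tgt$messages), unname(H$src))
  H0 <- list(src = matrix(0, 2, 2), tgt = rbind(c(1, 1)))
  expect_equal(unname(hgt_messages(g, H0, lp)$tgt$messages), matrix(0, 2, 2))
})

test_that("messages match a dense matrix-product oracle", {
  g <- random_heterograph(31, max_nodes = 10, n_relations = 4)
  cfg <- encoder_config(d_model = 6, n_heads = 2, n_layers = 1)
  lp <- hgt_layer_params(node_types(g), meta_relations(g), cfg, rng_seed = 32)
  H <- random_states(g, 6, 33)
  ms <- hgt_messages(g, H, lp)
  dh <- lp$d_head
  for (tt in names(ms)) {
    ed <- ms[[tt]]$edges
    for (e in seq_len(nrow(ed))) {
      s_idx <- match(ed$src[e], g$nodes[[ed$src_type[e]]])
      mlin <- lp$par$m[[ed$src_type[e]]]
      M <- as.numeric(H[[ed$src_type[e]]][s_idx, ] %*% mlin$W + mlin$b)
      expected <- c(M[1:dh] %*% lp$par$msg[[ed$relation[e]]][, , 1],
                    M[dh + 1:dh] %*% lp$par$msg[[ed$relation[e]]][, , 2])
      expect_equal(unname(ms[[tt]]$messages[e, ]), expected, tolerance = 1e-10)
    }
  }
})

test_that("aggregation endpoints behave: one-hot attention and isolated nodes", {
  # single in-neighbour -> aggregate before A-linear equals that message;
  # with identity A and relu the update is relu(msg) + prev
  g <- hetero_graph(
    nodes = list(src = "a", tgt = c("t", "iso")),
    relations = list(rel = list(relation = "rel", src_type = "src",
                                dst_type = "tgt", src = "a", dst = "t")))
  lp <- identity_layer(node_types(g), meta_relations(g), d_model = 2, h = 1)
  H <- list(src = rbind(c(0.4, -0.2)), tgt = rbind(c(1, 1), c(2, -3)))
  at <- hgt_attention(g, H, lp)
  ms <- hgt_messages(g, H, lp)
  out <- hgt_aggregate(at, ms, H, lp, g)
  expect_equal(out$tgt[1, ], pmax(c(0.4, -0.2), 0) + c(1, 1))
  # isolated node with zero-bias A-linear and relu(0) = 0: pure residual
  expect_equal(out$tgt[2, ], c(2, -3))
})

test_that("the vectorised layer equals the dense per-node oracle", {
  for (seed in 1:6) {
    g <- random_heterograph(seed + 40, max_nodes = 10, n_relations = 5,
                            p_edge = 0.4)
    cfg <- encoder_config(d_model = 8, n_heads = 2, n_layers = 1,
                          activation = c("gelu", "relu")[[1 + seed %% 2]])
    lp <- hgt_layer_params(node_types(g), meta_relations(g), cfg,
                           rng_seed = seed)
    H <- random_states(g, 8, seed + 50)
    fast <- hgt_aggregate(hgt_attention(g, H, lp), hgt_messages(g, H, lp), H, lp, g)
    slow <- oracle_hgt_layer(g, H, lp)
    for (ty in node_types(g))
      expect_lt(max(abs(fast[[ty]] - slow[[ty]])), 1e-6)
  }
})

test_that("with one node type and shared relation parameters the layer is homogeneous", {
  # two relation labels over the same type pair, identical parameters ==
  # a single relation holding the union of the edges
  nodes <- list(n = sprintf("v%d", 1:6))
  e1 <- list(relation = "r1", src_type = "n", dst_type = "n",
             src = c("v1", "v2", "v3"), dst = c("v2", "v3", "v4"))
  e2 <- list(relation = "r2", src_type = "n", dst_type = "n",
             src = c("v5", "v6"), dst = c("v2", "v4"))
  g_split <- hetero_graph(nodes, list(r1 = e1, r2 = e2))
  merged <- list(relation = "r1", src_type = "n", dst_type = "n",
                 src = c(e1$src, e2$src), dst = c(e1$dst, e2$dst))
  g_merged <- hetero_graph(nodes, list(r1 = merged))
  cfg <- encoder_config(d_model = 4, n_heads = 2, n_layers = 1)
  lp <- hgt_layer_params("n", meta_relations(g_split), cfg, rng_seed = 77)
  lp$par$att$r2 <- lp$par$att$r1
  lp$par$msg$r2 <- lp$par$msg$r1
  lp$par$mu$r2 <- lp$par$mu$r1
  lp_m <- lp
  lp_m$par$att$r2 <- NULL; lp_m$par$msg$r2 <- NULL; lp_m$par$mu$r2 <- NULL
  H <- random_states(g_split, 4, 78)
  out_split <- hgt_aggregate(hgt_attention(g_split, H, lp),
                             hgt_messages(g_split, H, lp), H, lp, g_split)
  out_merged <- hgt_aggregate(hgt_attention(g_merged, H, lp_m),
                              hgt_messages(g_merged, H, lp_m), H, lp_m, g_merged)
  expect_equal(out_split$n, out_merged$n, tolerance = 1e-10)
})

test_that("input projection clips, drops out and checks shapes", {
  g <- toy_graph()
  ge <- attach_embeddings(g, random_embeddings(g, 12L, rng_seed = 1))
  enc <- encoder_params(ge, encoder_config(d_model = 4, n_heads = 2,
                                           n_layers = 1), rng_seed = 2)
  h0 <- lapply(ge$embeddings, function(e) e$vectors)
  # zero input with zero bias -> zero output
  encz <- enc
  for (ty in names(encz$inp)) encz$inp[[ty]]$b <- rep(0, 4)
  hz <- lapply(h0, function(m) m * 0)
  out <- project_input(hz, encz, "eval")
  expect_true(all(vapply(out, function(m) all(m == 0), TRUE)))
  # eval mode is deterministic
  expect_identical(project_input(h0, enc, "eval"), project_input(h0, enc, "eval"))
  # negative pre-activation is clipped by the ReLU
  enc1 <- enc
  enc1$inp$drug <- list(W = matrix(1, 12, 4), b = rep(0, 4))
  hneg <- h0
  hneg$drug[] <- 0; hneg$drug[, 1] <- -3
  expect_true(all(project_input(hneg, enc1, "eval")$drug == 0))
  # dimension mismatch names the type
  hbad <- h0; hbad$drug <- hbad$drug[, 1:5]
  expect_error(project_input(hbad, enc, "eval"), "drug", class = "hgt_shape_error")
})

test_that("encode composes the exposed operations and keeps width d_model", {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 12, n_disease = 8,
                                          n_protein = 15, n_pathway = 4,
                                          embed_dim = 10, rng_seed = 21))
  g <- add_reverse_relations(embedded_graph(sim))
  cfg <- encoder_config(d_model = 8, n_heads = 2, n_layers = 3)
  enc <- encoder_params(g, cfg, rng_seed = 9)
  h0 <- lapply(g$embeddings, function(e) e$vectors)
  feat <- encode(g, h0, enc, "eval")
  for (ty in node_types(g)) {
    expect_equal(ncol(feat[[ty]]), 8L)
    expect_equal(nrow(feat[[ty]]), n_nodes(g, ty))
  }
  # manual composition: project -> L x (attention/messages/aggregate) ->
  # concat -> head linear -> relu
  H <- project_input(h0, enc, "eval")
  Hs <- list()
  for (l in 1:3) {
    lp <- enc$layers[[l]]
    H <- hgt_aggregate(hgt_attention(g, H, lp), hgt_messages(g, H, lp), H, lp, g)
    Hs[[l]] <- H
  }
  for (ty in node_types(g)) {
    CC <- do.call(cbind, lapply(Hs, `[[`, ty))
    manual <- pmax(sweep(CC %*% enc$head$W, 2, enc$head$b, `+`), 0)
    expect_equal(feat[[ty]], manual, tolerance = 1e-12)
  }
})

test_that("encoding is equivariant to node order within a type", {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 10, n_disease = 8,
                                          n_protein = 12, n_pathway = 0,
                                          embed_dim = 6, rng_seed = 31))
  g <- add_reverse_relations(embedded_graph(sim))
  cfg <- encoder_config(d_model = 8, n_heads = 2, n_layers = 2)
  enc <- encoder_params(g, cfg, rng_seed = 4)
  h0 <- lapply(g$embeddings, function(e) e$vectors)
  feat <- encode(g, h0, enc, "eval")
  perm <- with_seed(99, sample(n_nodes(g, "drug")))
  g2 <- g
  g2$nodes$drug <- g$nodes$drug[perm]
  h2 <- h0
  h2$drug <- h0$drug[perm, ]
  feat2 <- encode(g2, h2, enc, "eval")
  expect_equal(feat2$drug, feat$drug[perm, ], tolerance = 1e-10)
  expect_equal(feat2$protein, feat$protein, tolerance = 1e-10)
})

test_that("an unseen meta-relation raises an informative error", {
  g <- toy_graph()
  cfg <- encoder_config(d_model = 4, n_heads = 2, n_layers = 1)
  lp <- hgt_layer_params(node_types(g),
                         meta_relations(g)[1, , drop = FALSE], cfg, rng_seed = 1)
  H <- random_states(g, 4, 1)
  expect_error(hgt_attention(g, H, lp), "drug_protein",
               class = "hgt_unseen_relation_error")
})
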