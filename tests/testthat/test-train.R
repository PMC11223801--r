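small_training_setup <- function(seed = 3) {
  sim <- generate_synthetic_kg(synth_spec(n_drug = 12, n_disease = 8,
                                          n_protein = 14, n_pathway = 0,
                                          embed_dim = 5, p_in = 0.5,
                                          p_out = 0.05, rng_seed = seed))
  g <- embedded_graph(sim)
  split <- split_indications(g, "indication", 0.8, rng_seed = seed + 1)
  list(g = g, split = split)
}

test_that("training defaults follow the published protocol", {
  tc <- training_config()
  expect_equal(tc$epochs, 300L)
  expect_equal(tc$optimizer, "adamw")
  expect_equal(tc$schedule, "cosine")
  expect_equal(tc$mask_fraction, 0.8)
  expect_equal(tc$sampler$batch_size, 164L)
  expect_equal(tc$sampler$budget, 512L)
  expect_equal(tc$sampler$depth, 3L)
  ec <- encoder_config()
  expect_equal(ec$d_model, 64L)
  expect_equal(ec$n_heads, 8L)
  expect_equal(ec$n_layers, 3L)
  expect_equal(ec$dropout_in, 0.5)
  dc <- decoder_config()
  expect_equal(dc$dropout, 0.2)
})

test_that("cosine annealing spans lr to lr_min over the epoch range", {
  tc <- training_config(epochs = 101, lr = 1e-3, lr_min = 1e-5)
  expect_equal(cosine_lr(tc, 1), 1e-3)
  expect_equal(cosine_lr(tc, 101), 1e-5)
  expect_equal(cosine_lr(tc, 51), (1e-3 + 1e-5) / 2, tolerance = 1e-9)
  expect_equal(cosine_lr(training_config(schedule = "constant", lr = 2e-3), 57),
               2e-3)
})

test_that("a one-epoch run on a small graph records one loss value", {
  st <- small_training_setup()
  fit <- train_link_predictor(
    st$g, st$split, encoder_config(d_model = 8, n_heads = 2, n_layers = 2),
    decoder_config(),
    training_config(epochs = 1, sampler = sampler_config(depth = 2, budget = 100,
                                                         batch_size = 12),
                    rng_seed = 4))
  expect_equal(nrow(fit$history), 1L)
  expect_true(is.finite(fit$history$loss[1]))
  expect_gte(fit$history$loss[1], 0)
})

test_that("training is reproducible under identical seeds", {
  st <- small_training_setup()
  cfg <- training_config(epochs = 3, sampler = sampler_config(depth = 2,
                                                              budget = 100,
                                                              batch_size = 6),
                         rng_seed = 11)
  f1 <- train_link_predictor(st$g, st$split,
                             encoder_config(d_model = 8, n_heads = 2, n_layers = 1),
                             decoder_config(), cfg)
  f2 <- train_link_predictor(st$g, st$split,
                             encoder_config(d_model = 8, n_heads = 2, n_layers = 1),
                             decoder_config(), cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$encoder$head$W, f2$model$encoder$head$W)
})

test_that("analytic gradients match finite differences end to end", {
  st <- small_training_setup()
  g <- st$g; split <- st$split
  gm <- add_reverse_relations(apply_split(g, split))
  gm$embeddings <- g$embeddings
  enc_cfg <- encoder_config(d_model = 8, n_heads = 2, n_layers = 2,
                            dropout_in = 0)
  model <- init_model(apply_split(g, split), enc_cfg,
                      decoder_config(dropout = 0), rng_seed = 5)
  view <- build_compute_view(gm)
  h0 <- lapply(gm$embeddings, function(e) e$vectors)
  pos <- split$masked; pos$label <- 1L
  neg <- sample_negatives(gm, nrow(pos), rbind(split$masked, split$unmasked),
                          rng_seed = 6)
  pairs <- rbind(pos[c("drug", "disease", "label")],
                 neg[c("drug", "disease", "label")])
  loss_of <- function(model) {
    ec <- encode_cached(view, h0, model$encoder, "train")
    di <- unname(view$index$drug[pairs$drug])
    si <- unname(view$index$disease[pairs$disease])
    X <- cbind(ec$Feat$drug[di, , drop = FALSE],
               ec$Feat$disease[si, , drop = FALSE])
    fw <- decoder_forward(X, model$decoder, "train")
    list(loss = bce_loss(pairs$label, fw$score), ec = ec, fw = fw,
         di = di, si = si)
  }
  full <- loss_of(model)
  dz2 <- (full$fw$score - pairs$label) / nrow(pairs)
  bw <- decoder_backward(full$fw$cache, dz2, model$decoder)
  dFeat <- lapply(view$types, function(ty) matrix(0, view$n[[ty]], 8))
  names(dFeat) <- view$types
  dFeat$drug <- scatter_add(dFeat$drug, full$di, bw$dX[, 1:8, drop = FALSE])
  dFeat$disease <- scatter_add(dFeat$disease, full$si,
                               bw$dX[, 8 + 1:8, drop = FALSE])
  genc <- encode_backward(view, full$ec, dFeat, model$encoder)
  probes <- list(
    list(get = function(m) m$decoder$l1$W[5, 3],
         set = function(m, v) { m$decoder$l1$W[5, 3] <- v; m },
         grad = bw$grads$l1$W[5, 3]),
    list(get = function(m) m$decoder$gamma[2],
         set = function(m, v) { m$decoder$gamma[2] <- v; m },
         grad = bw$grads$gamma[2]),
    list(get = function(m) m$encoder$inp$protein$W[3, 4],
         set = function(m, v) { m$encoder$inp$protein$W[3, 4] <- v; m },
         grad = genc$inp$protein$W[3, 4]),
    list(get = function(m) m$encoder$layers[[1]]$par$k$protein$W[2, 6],
         set = function(m, v) { m$encoder$layers[[1]]$par$k$protein$W[2, 6] <- v; m },
         grad = genc$layers[[1]]$k$protein$W[2, 6]),
    list(get = function(m) m$encoder$layers[[2]]$par$msg$drug_protein[1, 3, 2],
         set = function(m, v) { m$encoder$layers[[2]]$par$msg$drug_protein[1, 3, 2] <- v; m },
         grad = genc$layers[[2]]$msg$drug_protein[1, 3, 2]),
    list(get = function(m) m$encoder$layers[[1]]$par$mu$rev.indication,
         set = function(m, v) { m$encoder$layers[[1]]$par$mu$rev.indication <- v; m },
         grad = genc$layers[[1]]$mu$rev.indication))
  eps <- 1e-6
  for (p in probes) {
    fd <- (loss_of(p$set(model, p$get(model) + eps))$loss -
             loss_of(p$set(model, p$get(model) - eps))$loss) / (2 * eps)
    if (abs(fd) < 1e-10) expect_lt(abs(p$grad), 1e-8)
    else expect_lt(abs(p$grad - fd) / abs(fd), 1e-4)
  }
})

test_that("checkpoints reload bit-exactly and score identically", {
  st <- small_training_setup()
  fit <- train_link_predictor(
    st$g, st$split, encoder_config(d_model = 8, n_heads = 2, n_layers = 2),
    decoder_config(),
    training_config(epochs = 2, sampler = sampler_config(depth = 2, budget = 100,
                                                         batch_size = 6),
                    rng_seed = 9))
  dir <- tempfile()
  save_checkpoint(fit, dir)
  back <- load_checkpoint(dir)
  expect_identical(back$model$encoder$head$W, fit$model$encoder$head$W)
  expect_identical(back$model$encoder$layers[[1]]$par$att$indication,
                   fit$model$encoder$layers[[1]]$par$att$indication)
  expect_identical(back$model$decoder$run_mean, fit$model$decoder$run_mean)
  pairs <- st$split$masked
  s1 <- suppressWarnings(score_with_model(fit, st$g, pairs, split = st$split,
                                          rng_seed = 21))
  s2 <- suppressWarnings(score_with_model(back, st$g, pairs, split = st$split,
                                          rng_seed = 21))
  expect_identical(s1$score, s2$score)
})

test_that("negatives never collide with known positives during training", {
  st <- small_training_setup()
  split <- st$split
  forb <- pair_key(c(split$masked$drug, split$unmasked$drug),
                   c(split$masked$disease, split$unmasked$disease))
  gm <- add_reverse_relations(apply_split(st$g, split))
  for (seed in 1:10) {
    neg <- sample_negatives(gm, 10, rbind(split$masked, split$unmasked),
                            rng_seed = seed)
    expect_length(intersect(pair_key(neg$drug, neg$disease), forb), 0)
  }
})

test_that("the benchmark fit shows a learning signal by epoch 50", {
  hist <- bench_fit()$history
  expect_lt(hist$loss[50], hist$loss[1])
  expect_equal(nrow(hist), 200L)
})
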