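# Evaluation protocols: k-fold cross-validation over target pairs,
# relation-removal robustness, relation retargeting, the new-disease
# holdout, and novel-pair ranking.

#' Describe a link-prediction task over one relation
#'
#' Infers the endpoint types of the target relation from the graph schema.
#' When both endpoints share a type, pairs are unordered with self-pairs
#' excluded.
#'
#' @param g a `hetero_graph`.
#' @param target_relation relation key or label.
#' @return a `task_config`: `target_relation` (key), `drug_type`,
#'   `disease_type` (generic endpoint roles), `self_paired`.
#' @export
task_config <- function(g, target_relation) {
  r <- get_relation(g, target_relation)
  structure(list(target_relation = resolve_relation_key(g, target_relation),
                 drug_type = r$src_type, disease_type = r$dst_type,
                 self_paired = r$src_type == r$dst_type),
            class = "task_config")
}

#' Retarget the pipeline to another relation
#'
#' The identical machinery (splits, negatives, scoring) runs over the new
#' relation's endpoint-type pair: retargeting to drug-protein draws negatives
#' from drug x protein, retargeting to a self-paired relation such as
#' protein-protein switches to unordered pairs without self-pairs.
#' Retargeting to the current relation is a no-op.
#'
#' @param config a `task_config`.
#' @param g the `hetero_graph` supplying the schema.
#' @param new_target_relation relation key or label.
#' @return the updated `task_config`.
#' @export
retarget <- function(config, g, new_target_relation) {
  task_config(g, new_target_relation)
}

metric_report <- function(per_fold) {
  structure(list(per_fold = per_fold,
                 auroc = mean(per_fold$auroc, na.rm = TRUE),
                 aupr = mean(per_fold$aupr, na.rm = TRUE)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> mean AUROC %.3f / mean AUPR %.3f over %d fold(s)\n",
              x$auroc, x$aupr, nrow(x$per_fold)))
  invisible(x)
}

# negatives for validation scoring: uniform over the endpoint-type pair grid
# of the full graph, excluding every known positive
validation_negatives <- function(g, task, n, known_pairs, rng_seed) {
  sample_negatives(g, n, known_pairs, rng_seed,
                   drug_type = task$drug_type, disease_type = task$disease_type)
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold the fold's pairs are removed from the graph entirely, the
#' remaining pairs are split masked/unmasked, a fresh model is trained, and
#' the fold's pairs plus an equal number of fresh negatives are scored with
#' batched subgraph encoding. Per-fold AUROC/AUPR and their means are
#' reported.
#'
#' @param g an embedded, filtered `hetero_graph`.
#' @param target_relation relation key or label.
#' @param encoder,decoder,training model and optimisation configurations.
#' @param k fold count. Default 5.
#' @param rng_seed master seed (folds, splits, negatives and evaluation
#'   sampling derive independent streams).
#' @param mask_over `"train"` (default): `mask_fraction` applies to the
#'   non-validation pairs; `"all"`: the masked count is computed on the full
#'   pair set, capped at the training-pool size.
#' @return a `metric_report` with `per_fold` data.frame.
#' @export
cross_validate <- function(g, target_relation, encoder = encoder_config(),
                           decoder = decoder_config(),
                           training = training_config(), k = 5L, rng_seed = 1L,
                           mask_over = c("train", "all")) {
  mask_over <- match.arg(mask_over)
  task <- task_config(g, target_relation)
  pairs <- indication_pairs(g, target_relation)
  folds <- make_folds(pairs, k, derive_seed(rng_seed, "folds"))
  rows <- lapply(seq_len(k), function(f) {
    val <- pairs[folds$assignments == f, , drop = FALSE]
    frac <- training$mask_fraction
    if (mask_over == "all") {
      n_pool <- nrow(pairs) - nrow(val)
      frac <- min(1, round_half_away(training$mask_fraction * nrow(pairs)) / n_pool)
    }
    split <- split_indications(g, target_relation, frac,
                               derive_seed(rng_seed, paste0("split/", f)),
                               validation = val)
    fit <- train_link_predictor(g, split, encoder, decoder,
                                local_training_seed(training, rng_seed, f))
    val$label <- 1L
    neg <- validation_negatives(g, task, nrow(val), pairs,
                                derive_seed(rng_seed, paste0("valneg/", f)))
    scored <- score_with_model(fit, g, rbind(val, neg[c("drug", "disease", "label")]),
                               split = split,
                               rng_seed = derive_seed(rng_seed, paste0("evalsample/", f)))
    if (!sum(scored$label == 1))
      return(data.frame(fold = f, auroc = NA_real_, aupr = NA_real_,
                        n_val = nrow(val), n_scored = nrow(scored)))
    data.frame(fold = f, auroc = auroc(scored), aupr = aupr(scored),
               n_val = nrow(val), n_scored = nrow(scored))
  })
  metric_report(do.call(rbind, rows))
}

local_training_seed <- function(training, rng_seed, tag) {
  training$rng_seed <- derive_seed(rng_seed, paste0("train/", tag))
  training
}

#' Relation-removal robustness sweep
#'
#' Re-runs cross-validation once per dropped relation (plus a no-drop
#' baseline) under identical seeds, reporting per-condition metrics.
#'
#' @param g an embedded, filtered `hetero_graph`.
#' @param relations_to_drop character vector of relation keys/labels.
#' @param target_relation the prediction target.
#' @param ... passed to [cross_validate()] (`encoder`, `decoder`, `training`,
#'   `k`, `rng_seed`).
#' @param include_baseline include the nothing-removed condition. Default TRUE.
#' @return named list of `metric_report` (first entry `baseline` if included).
#' @export
robustness_sweep <- function(g, relations_to_drop, target_relation, ...,
                             include_baseline = TRUE) {
  conditions <- list()
  if (include_baseline) conditions$baseline <- g
  for (rel in relations_to_drop) {
    if (identical(resolve_relation_key(g, rel), resolve_relation_key(g, target_relation)))
      stop_hgt("cannot remove the target relation itself", class = "hgt_config_error")
    conditions[[rel]] <- remove_relation(g, rel)
  }
  lapply(conditions, function(gc) cross_validate(gc, target_relation, ...))
}

#' New-disease scenario: disease-level holdout without text embeddings
#'
#' Emulates prediction for diseases with next to no prior information: a
#' fraction of diseases is held out, every disease's text-derived embedding
#' is replaced by the seeded random fallback, and only one indication per
#' held-out disease is kept available to training; the rest are scored
#' against fresh negatives restricted to the held-out diseases.
#'
#' @param g an embedded, filtered `hetero_graph`.
#' @param target_relation relation key or label.
#' @param test_fraction fraction of diseases held out, in (0, 1). Default 0.1.
#' @param encoder,decoder,training configurations.
#' @param rng_seed master seed.
#' @param embed_dim dimension of the fallback disease embeddings. Defaults to
#'   the current disease embedding width.
#' @return a `metric_report` (single pseudo-fold) with extra fields
#'   `held_out_diseases` and `excluded` (held-out diseases with fewer than
#'   two indications, which cannot be scored).
#' @export
new_disease_scenario <- function(g, target_relation, test_fraction = 0.1,
                                 encoder = encoder_config(),
                                 decoder = decoder_config(),
                                 training = training_config(), rng_seed = 1L,
                                 embed_dim = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_hgt("test_fraction must lie in (0, 1)", class = "hgt_config_error")
  task <- task_config(g, target_relation)
  pairs <- indication_pairs(g, target_relation)
  diseases <- g$nodes[[task$disease_type]]
  n_held <- floor(test_fraction * length(diseases))
  held <- with_seed(derive_seed(rng_seed, "newdisease/held"),
                    sample(diseases, n_held))
  # strip literature-style information: all disease embeddings fall back to
  # the seeded random initialiser
  dim_d <- embed_dim %||% g$embeddings[[task$disease_type]]$dim
  dis_ids <- g$nodes[[task$disease_type]]
  fb <- with_seed(derive_seed(rng_seed, "newdisease/embed"),
                  matrix(stats::rnorm(length(dis_ids) * dim_d),
                         length(dis_ids), dim_d))
  rownames(fb) <- dis_ids
  g$embeddings[[task$disease_type]] <- embedding_table(task$disease_type, fb)

  held_pairs <- pairs[pairs$disease %in% held, , drop = FALSE]
  counts <- table(held_pairs$disease)
  excluded <- names(counts)[counts < 2L]
  if (length(excluded))
    message(sprintf("%d held-out disease(s) with <2 indications excluded from scoring",
                    length(excluded)))
  keep_one <- do.call(rbind, lapply(split(held_pairs, held_pairs$disease), function(df) {
    i <- with_seed(derive_seed(rng_seed, paste0("newdisease/keep/", df$disease[1])),
                   sample.int(nrow(df), 1L))
    df[i, , drop = FALSE]
  }))
  keep_key <- pair_key(keep_one$drug, keep_one$disease)
  val <- held_pairs[!pair_key(held_pairs$drug, held_pairs$disease) %in% keep_key &
                      !held_pairs$disease %in% excluded, , drop = FALSE]
  split <- split_indications(g, target_relation, training$mask_fraction,
                             derive_seed(rng_seed, "newdisease/split"),
                             validation = val)
  fit <- train_link_predictor(g, split, encoder, decoder,
                              local_training_seed(training, rng_seed, "newdisease"))
  val$label <- 1L
  g_held <- g
  g_held$nodes[[task$disease_type]] <- setdiff(held, excluded)  # negatives on held-out diseases only
  neg <- sample_negatives(g_held, nrow(val), pairs,
                          derive_seed(rng_seed, "newdisease/neg"),
                          drug_type = task$drug_type, disease_type = task$disease_type)
  scored <- score_with_model(fit, g, rbind(val, neg[c("drug", "disease", "label")]),
                             split = split,
                             rng_seed = derive_seed(rng_seed, "newdisease/eval"))
  rep <- metric_report(data.frame(fold = 1L, auroc = auroc(scored),
                                  aupr = aupr(scored), n_val = nrow(val),
                                  n_scored = nrow(scored)))
  rep$held_out_diseases <- held
  rep$excluded <- excluded
  rep
}

#' Rank novel drug-disease pairs with a trained model
#'
#' Repurposing-mode inference: with every known indication present in the
#' graph, all drug x disease pairs co-occurring in sampled subgraphs across
#' `n_sets` full passes over the seed drugs are scored; known positives are
#' excluded and the rest returned in descending score order (scores averaged
#' over the batches that saw a pair).
#'
#' @param fit a trained `hgtdr_fit`.
#' @param g the embedded graph with all target pairs present.
#' @param target_relation relation key or label.
#' @param n_sets number of passes over the seed drugs. Default 10 (with the
#'   default batch size on the full PrimeKG-scale graph this is the 110-batch
#'   protocol).
#' @param sampler optional [sampler_config()] override.
#' @param rng_seed seed of the inference sampling stream.
#' @return data.frame `drug`, `disease`, `score`, `n_batches`, sorted
#'   non-increasing by score; known positives never appear.
#' @export
rank_novel <- function(fit, g, target_relation, n_sets = 10L, sampler = NULL,
                       rng_seed = 1L) {
  task <- task_config(g, target_relation)
  known <- indication_pairs(g, target_relation)
  known_keys <- c(pair_key(known$drug, known$disease),
                  pair_key(known$disease, known$drug))
  sampler <- sampler %||% fit$training$sampler
  g_mp <- add_reverse_relations(g)
  g_mp$embeddings <- g$embeddings
  adj <- build_adjacency(g_mp)
  drugs <- g$nodes[[task$drug_type]]
  acc <- new.env(parent = emptyenv())
  for (s in seq_len(n_sets)) {
    batches <- partition_seeds(drugs, sampler$batch_size,
                               derive_seed(rng_seed, paste0("novel-seeds/", s)))
    for (b in seq_along(batches)) {
      sb <- sample_subgraph(g_mp, batches[[b]], sampler,
                            rng_seed = derive_seed(rng_seed, paste0("novel-sample/", s, "/", b)),
                            seed_type = task$drug_type, adj = adj)
      sg <- sb$subgraph
      dr <- sg$nodes[[task$drug_type]]; ds <- sg$nodes[[task$disease_type]]
      if (!length(dr) || !length(ds)) next
      grid <- expand.grid(drug = dr, disease = ds, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      if (task$self_paired) grid <- grid[grid$drug < grid$disease, , drop = FALSE]
      grid <- grid[!pair_key(grid$drug, grid$disease) %in% known_keys, , drop = FALSE]
      if (!nrow(grid)) next
      view <- build_compute_view(sg)
      ec <- encode_cached(view, subgraph_h_init(g_mp, sg), fit$model$encoder, "eval")
      di <- unname(view$index[[task$drug_type]][grid$drug])
      si <- unname(view$index[[task$disease_type]][grid$disease])
      X <- cbind(ec$Feat[[task$drug_type]][di, , drop = FALSE],
                 ec$Feat[[task$disease_type]][si, , drop = FALSE])
      fw <- decoder_forward(X, fit$model$decoder, "eval")
      keys <- pair_key(grid$drug, grid$disease)
      for (i in seq_along(keys)) {
        prev <- acc[[keys[i]]]
        if (is.null(prev)) acc[[keys[i]]] <- c(fw$score[i], 1)
        else acc[[keys[i]]] <- prev + c(fw$score[i], 1)
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(drug = character(), disease = character(),
                      score = numeric(), n_batches = integer()))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  vals <- vapply(keys, function(k) acc[[k]], numeric(2))
  out <- data.frame(drug = vapply(parts, `[`, "", 1),
                    disease = vapply(parts, `[`, "", 2),
                    score = vals[1, ] / vals[2, ],
                    n_batches = as.integer(vals[2, ]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$score), , drop = FALSE]
}
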