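# End-to-end training: sample a subgraph per seed batch, encode, score the
# batch's usable masked positives plus freshly drawn negatives, take the
# binary cross-entropy, and update every encoder and decoder parameter
# jointly with AdamW under a cosine-annealed learning rate.

#' Training configuration
#'
#' @param epochs training epochs. Default 300.
#' @param lr base learning rate of AdamW. Default 1e-3.
#' @param weight_decay decoupled weight decay of AdamW. Default 1e-2.
#' @param lr_min floor of the cosine schedule. Default 0.
#' @param optimizer only `"adamw"` is provided.
#' @param schedule `"cosine"` (annealing over all epochs, no restarts) or
#'   `"constant"`.
#' @param mask_fraction fraction of target pairs masked for training.
#'   Default 0.8.
#' @param negatives_per_positive negatives drawn per usable positive in each
#'   batch, resampled fresh every epoch. Default 1.
#' @param sampler a [sampler_config()].
#' @param rng_seed master seed; per-component streams (parameter init,
#'   sampling, dropout, negatives) are derived from it.
#' @param loss_pooling `"batch"` (mean per batch, then averaged over batches
#'   for the epoch history) — the only implemented pooling.
#' @param verbose print per-epoch loss.
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 300L, lr = 1e-3, weight_decay = 1e-2,
                            lr_min = 0, optimizer = "adamw",
                            schedule = c("cosine", "constant"),
                            mask_fraction = 0.8, negatives_per_positive = 1,
                            sampler = sampler_config(), rng_seed = 1L,
                            loss_pooling = "batch", verbose = FALSE) {
  schedule <- match.arg(schedule)
  if (epochs < 1L) stop_hgt("epochs must be >= 1", class = "hgt_config_error")
  if (negatives_per_positive <= 0)
    stop_hgt("negatives_per_positive must be > 0", class = "hgt_config_error")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, lr_min = lr_min,
                 optimizer = optimizer, schedule = schedule,
                 mask_fraction = mask_fraction,
                 negatives_per_positive = negatives_per_positive,
                 sampler = sampler, rng_seed = as.integer(rng_seed),
                 loss_pooling = loss_pooling, verbose = verbose),
            class = "training_config")
}

cosine_lr <- function(cfg, epoch) {
  if (cfg$schedule == "constant") return(cfg$lr)
  t <- epoch - 1L
  cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) * (1 + cos(pi * t / max(cfg$epochs - 1L, 1L)))
}

# One AdamW step over a nested parameter/grad tree. state holds m/v trees and
# the step counter.
adamw_init <- function(par) list(m = tree_zeros(par), v = tree_zeros(par), t = 0L)

adamw_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-2) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  r <- upd(par, grad, state$m, state$v)
  list(par = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Gather the trainable parameter tree of a model and write it back.
model_par <- function(model) {
  list(enc = list(inp = model$encoder$inp,
                  layers = lapply(model$encoder$layers, `[[`, "par"),
                  head = model$encoder$head),
       dec = list(l1 = model$decoder$l1, gamma = model$decoder$gamma,
                  beta = model$decoder$beta, l2 = model$decoder$l2))
}

model_set_par <- function(model, par) {
  model$encoder$inp <- par$enc$inp
  for (l in seq_along(model$encoder$layers))
    model$encoder$layers[[l]]$par <- par$enc$layers[[l]]
  model$encoder$head <- par$enc$head
  model$decoder$l1 <- par$dec$l1
  model$decoder$gamma <- par$dec$gamma
  model$decoder$beta <- par$dec$beta
  model$decoder$l2 <- par$dec$l2
  model
}

#' Initialise an end-to-end model for a graph
#'
#' @param g an embedded `hetero_graph`; parameters are created for every node
#'   type and every relation of `add_reverse_relations(g)`, so reverse
#'   message-passing relations are covered.
#' @param encoder an [encoder_config()].
#' @param decoder a [decoder_config()] (its `d_model` is forced to the
#'   encoder's).
#' @param rng_seed integer seed.
#' @return an `hgtdr_model`: `encoder` ([encoder_params()]), `decoder`
#'   ([decoder_params()]).
#' @export
init_model <- function(g, encoder = encoder_config(), decoder = decoder_config(),
                       rng_seed = 1L) {
  g_mp <- add_reverse_relations(g)
  decoder$d_model <- encoder$d_model
  structure(list(
    encoder = encoder_params(g_mp, encoder, rng_seed = derive_seed(rng_seed, "enc")),
    decoder = decoder_params(decoder, rng_seed = derive_seed(rng_seed, "dec"))),
    class = "hgtdr_model")
}

# initial embedding rows for the nodes of a subgraph, in subgraph order
subgraph_h_init <- function(g_embedded, sg) {
  out <- list()
  for (ty in node_types(sg)) {
    emb <- g_embedded$embeddings[[ty]]
    if (is.null(emb))
      stop_hgt("graph carries no embeddings for type '%s'", ty,
               class = "hgt_config_error")
    out[[ty]] <- emb$vectors[sg$nodes[[ty]], , drop = FALSE]
  }
  out
}

#' Train encoder and decoder end to end
#'
#' Each epoch partitions the drugs into seed batches, samples a type-budgeted
#' subgraph per batch from the masked graph view, encodes it, scores the
#' batch's usable masked positives together with freshly sampled negatives,
#' and backpropagates the binary cross-entropy through decoder and encoder.
#' Fully reproducible given the same seeds and arithmetic.
#'
#' @param g an embedded `hetero_graph` (all target pairs still present; the
#'   masked view is derived internally via [apply_split()]).
#' @param split an `indication_split` whose masked pairs act as training
#'   positives.
#' @param encoder an [encoder_config()].
#' @param decoder a [decoder_config()].
#' @param training a [training_config()].
#' @param model optional pre-initialised `hgtdr_model` to continue training.
#' @return an `hgtdr_fit`: `model`, `history` (data.frame epoch, loss, lr,
#'   n_batches, skipped), plus the configs and the split bookkeeping needed
#'   for scoring.
#' @export
train_link_predictor <- function(g, split, encoder = encoder_config(),
                                 decoder = decoder_config(),
                                 training = training_config(), model = NULL) {
  g_view <- apply_split(g, split)
  g_mp <- add_reverse_relations(g_view)
  g_mp$embeddings <- g$embeddings
  if (is.null(model))
    model <- init_model(g_view, encoder, decoder,
                        rng_seed = derive_seed(training$rng_seed, "init"))
  adj <- build_adjacency(g_mp)
  par <- model_par(model)
  state <- adamw_init(par)
  drugs <- g$nodes[[split$drug_type]]
  forbidden <- rbind(split$unmasked, split$masked, split$validation)
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                        n_batches = integer(), skipped = integer())
  scfg <- training$sampler
  for (epoch in seq_len(training$epochs)) {
    lr <- cosine_lr(training, epoch)
    batches <- partition_seeds(drugs, scfg$batch_size,
                               derive_seed(training$rng_seed, paste0("seeds/", epoch)))
    losses <- numeric(); skipped <- 0L
    for (b in seq_along(batches)) {
      tag <- paste0(epoch, "/", b)
      sb <- sample_subgraph(g_mp, batches[[b]], scfg,
                            rng_seed = derive_seed(training$rng_seed, paste0("sample/", tag)),
                            seed_type = split$drug_type, adj = adj)
      sg <- sb$subgraph
      ok <- split$masked$drug %in% sg$nodes[[split$drug_type]] &
        split$masked$disease %in% sg$nodes[[split$disease_type]]
      pos <- split$masked[ok, , drop = FALSE]
      if (!nrow(pos)) {
        warning(sprintf("epoch %d batch %d: no usable positives, skipped", epoch, b))
        skipped <- skipped + 1L
        next
      }
      n_neg <- max(1L, round_half_away(nrow(pos) * training$negatives_per_positive))
      neg <- tryCatch(
        sample_negatives(sb, n_neg, forbidden,
                         rng_seed = derive_seed(training$rng_seed, paste0("neg/", tag)),
                         drug_type = split$drug_type,
                         disease_type = split$disease_type),
        hgt_pool_exhausted_error = function(e) NULL)
      pos$label <- 1L
      pairs <- rbind(pos[c("drug", "disease", "label")],
                     if (!is.null(neg)) neg[c("drug", "disease", "label")])
      view <- build_compute_view(sg)
      h_init <- subgraph_h_init(g_mp, sg)
      set.seed(derive_seed(training$rng_seed, paste0("dropout/", tag)))
      ec <- encode_cached(view, h_init, model$encoder, "train")
      di <- unname(view$index[[split$drug_type]][pairs$drug])
      si <- unname(view$index[[split$disease_type]][pairs$disease])
      X <- cbind(ec$Feat[[split$drug_type]][di, , drop = FALSE],
                 ec$Feat[[split$disease_type]][si, , drop = FALSE])
      fw <- decoder_forward(X, model$decoder, "train")
      model$decoder <- fw$dec  # running batch-norm statistics advance
      y <- pairs$label
      s <- pmin(pmax(fw$score, 1e-15), 1 - 1e-15)
      losses <- c(losses, -mean(y * log(s) + (1 - y) * log(1 - s)))
      # sigmoid + BCE collapse to (score - label)/n at the logit
      dz2 <- (fw$score - y) / length(y)
      bw <- decoder_backward(fw$cache, dz2, model$decoder)
      d <- model$encoder$cfg$d_model
      dFeat <- lapply(view$types, function(ty)
        matrix(0, view$n[[ty]], d))
      names(dFeat) <- view$types
      dFeat[[split$drug_type]] <- scatter_add(dFeat[[split$drug_type]], di,
                                              bw$dX[, seq_len(d), drop = FALSE])
      dFeat[[split$disease_type]] <- scatter_add(dFeat[[split$disease_type]], si,
                                                 bw$dX[, d + seq_len(d), drop = FALSE])
      genc <- encode_backward(view, ec, dFeat, model$encoder)
      grads <- list(enc = genc, dec = bw$grads)
      stepped <- adamw_step(model_par(model), grads, state, lr,
                            weight_decay = training$weight_decay)
      state <- stepped$state
      model <- model_set_par(model, stepped$par)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = if (length(losses)) mean(losses) else NA_real_,
      lr = lr, n_batches = length(losses), skipped = skipped))
    if (training$verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.2e", epoch, mean(losses), lr))
  }
  structure(list(model = model, history = history,
                 encoder_config = model$encoder$cfg,
                 training = training, split_meta = list(
                   target_relation = split$target_relation,
                   drug_type = split$drug_type,
                   disease_type = split$disease_type)),
            class = "hgtdr_fit")
}

#' @export
print.hgtdr_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<hgtdr_fit> %d epoch(s); final mean loss %.4f\n",
              n, x$history$loss[n]))
  invisible(x)
}

#' Score pairs with a trained model via batched subgraph encoding
#'
#' Mirrors the training protocol at evaluation time: the drugs are
#' partitioned into seed batches, a subgraph is sampled per batch (from the
#' masked view, so held-out links stay invisible), each subgraph is encoded
#' in eval mode and every requested pair whose two endpoints are present is
#' scored. Pairs hit by several batches keep the mean score.
#'
#' @param fit an `hgtdr_fit` (or `hgtdr_model` plus metadata via `...`).
#' @param g the embedded graph to score on (the masked view is derived from
#'   `split` when given).
#' @param pairs data.frame `drug`, `disease` (optional `label` carried
#'   through).
#' @param split optional `indication_split` used to mask the graph view.
#' @param sampler a [sampler_config()]; defaults to the fit's training
#'   sampler.
#' @param rng_seed seed of the evaluation sampling stream.
#' @param n_sets number of full passes over the seed drugs.
#' @return data.frame `drug`, `disease`, `score`, `label`, `n_batches`
#'   (how many subgraphs scored the pair; 0 rows are dropped with a warning).
#' @export
score_with_model <- function(fit, g, pairs, split = NULL,
                             sampler = NULL, rng_seed = 1L, n_sets = 1L) {
  model <- fit$model
  meta <- fit$split_meta
  sampler <- sampler %||% fit$training$sampler
  g_view <- if (is.null(split)) g else apply_split(g, split)
  g_mp <- add_reverse_relations(g_view)
  g_mp$embeddings <- g$embeddings
  adj <- build_adjacency(g_mp)
  drugs <- g$nodes[[meta$drug_type]]
  acc_score <- stats::setNames(numeric(nrow(pairs)), NULL)
  acc_n <- integer(nrow(pairs))
  pk <- pair_key(pairs$drug, pairs$disease)
  for (s in seq_len(n_sets)) {
    batches <- partition_seeds(drugs, sampler$batch_size,
                               derive_seed(rng_seed, paste0("eval-seeds/", s)))
    for (b in seq_along(batches)) {
      sb <- sample_subgraph(g_mp, batches[[b]], sampler,
                            rng_seed = derive_seed(rng_seed, paste0("eval-sample/", s, "/", b)),
                            seed_type = meta$drug_type, adj = adj)
      sg <- sb$subgraph
      ok <- pairs$drug %in% sg$nodes[[meta$drug_type]] &
        pairs$disease %in% sg$nodes[[meta$disease_type]]
      if (!any(ok)) next
      view <- build_compute_view(sg)
      ec <- encode_cached(view, subgraph_h_init(g_mp, sg), model$encoder, "eval")
      di <- unname(view$index[[meta$drug_type]][pairs$drug[ok]])
      si <- unname(view$index[[meta$disease_type]][pairs$disease[ok]])
      X <- cbind(ec$Feat[[meta$drug_type]][di, , drop = FALSE],
                 ec$Feat[[meta$disease_type]][si, , drop = FALSE])
      fw <- decoder_forward(X, model$decoder, "eval")
      acc_score[ok] <- acc_score[ok] + fw$score
      acc_n[ok] <- acc_n[ok] + 1L
    }
  }
  scored <- data.frame(drug = pairs$drug, disease = pairs$disease,
                       score = ifelse(acc_n > 0, acc_score / pmax(acc_n, 1), NA_real_),
                       label = if ("label" %in% names(pairs)) pairs$label else NA_integer_,
                       n_batches = acc_n, stringsAsFactors = FALSE)
  if (any(acc_n == 0L)) {
    warning(sprintf("%d pair(s) never co-occurred in a sampled subgraph and were dropped",
                    sum(acc_n == 0L)))
    scored <- scored[acc_n > 0L, , drop = FALSE]
  }
  scored
}
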