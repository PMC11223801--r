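# Fully connected pair-scoring decoder: concat(drug, disease) -> linear ->
# batch norm -> ReLU -> dropout -> linear -> sigmoid.

#' Decoder configuration
#'
#' @param d_model encoder feature width the decoder consumes. First layer maps
#'   `2 * d_model -> d_model` (e.g. 128 -> 64 at defaults), second
#'   `d_model -> 1`.
#' @param dropout dropout probability after the first layer's ReLU. Default 0.2.
#' @param bn_momentum running-statistics momentum of the batch-norm layer.
#' @param bn_eps numerical floor inside the batch-norm square root.
#' @return a `decoder_config` list.
#' @export
decoder_config <- function(d_model = 64L, dropout = 0.2, bn_momentum = 0.1,
                           bn_eps = 1e-5) {
  if (dropout < 0 || dropout > 1)
    stop_hgt("dropout must lie in [0,1]", class = "hgt_config_error")
  structure(list(d_model = as.integer(d_model), dropout = dropout,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "decoder_config")
}

#' Initialise decoder parameters
#'
#' @param cfg a [decoder_config()].
#' @param rng_seed integer seed.
#' @return a `decoder_params` object: two linear layers, batch-norm
#'   scale/shift and running statistics.
#' @export
decoder_params <- function(cfg = decoder_config(), rng_seed = 1L) {
  d <- cfg$d_model
  with_seed(rng_seed, {
    structure(list(cfg = cfg,
                   l1 = init_linear(2L * d, d),
                   gamma = rep(1, d), beta = rep(0, d),
                   run_mean = rep(0, d), run_var = rep(1, d),
                   l2 = init_linear(d, 1L)),
              class = "decoder_params")
  })
}

# Forward pass on a feature matrix X (pairs x 2*d_model). Training mode uses
# batch statistics (and updates the running ones); eval mode uses running
# statistics and disables dropout. Returns scores plus the backward cache and
# the (possibly updated) decoder.
decoder_forward <- function(X, dec, mode = "eval") {
  cfg <- dec$cfg
  Z1 <- lin_fwd(X, dec$l1)
  n <- nrow(Z1)
  if (mode == "train") {
    mu <- colMeans(Z1)
    va <- colMeans(sweep(Z1, 2, mu)^2)           # biased, used for normalisation
    unb <- if (n > 1) va * n / (n - 1) else va   # unbiased, tracked
    m <- cfg$bn_momentum
    dec$run_mean <- (1 - m) * dec$run_mean + m * mu
    dec$run_var <- (1 - m) * dec$run_var + m * unb
  } else {
    mu <- dec$run_mean; va <- dec$run_var
  }
  inv_sd <- 1 / sqrt(va + cfg$bn_eps)
  Xc <- sweep(Z1, 2, mu)
  Xhat <- sweep(Xc, 2, inv_sd, `*`)
  B <- sweep(sweep(Xhat, 2, dec$gamma, `*`), 2, dec$beta, `+`)
  A <- pmax(B, 0)
  mask <- NULL
  Hd <- A
  if (mode == "train" && cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(A), 1, 1 - cfg$dropout) / (1 - cfg$dropout),
                   nrow(A), ncol(A))
    Hd <- A * mask
  }
  z2 <- lin_fwd(Hd, dec$l2)[, 1]
  score <- 1 / (1 + exp(-z2))
  list(score = score, dec = dec,
       cache = list(X = X, Z1 = Z1, Xc = Xc, Xhat = Xhat, inv_sd = inv_sd,
                    B = B, A = A, mask = mask, Hd = Hd, z2 = z2,
                    mode = mode, n = n))
}

# Backward from dz2 (gradient wrt the pre-sigmoid logit, length n).
# Returns parameter grads plus dX (pairs x 2*d_model).
decoder_backward <- function(cache, dz2, dec) {
  gr <- list(l1 = list(W = 0 * dec$l1$W, b = 0 * dec$l1$b),
             gamma = 0 * dec$gamma, beta = 0 * dec$beta,
             l2 = list(W = 0 * dec$l2$W, b = 0 * dec$l2$b))
  dz2 <- matrix(dz2, ncol = 1)
  gr$l2$W <- crossprod(cache$Hd, dz2)
  gr$l2$b <- colSums(dz2)
  dHd <- dz2 %*% t(dec$l2$W)
  dA <- if (is.null(cache$mask)) dHd else dHd * cache$mask
  dB <- dA * (cache$B > 0)
  gr$gamma <- colSums(dB * cache$Xhat)
  gr$beta <- colSums(dB)
  dXhat <- sweep(dB, 2, dec$gamma, `*`)
  n <- cache$n
  if (cache$mode == "train") {
    # batch-norm backward through the batch statistics
    dva <- colSums(dXhat * cache$Xc) * (-0.5) * cache$inv_sd^3
    dmu <- colSums(dXhat) * (-cache$inv_sd) + dva * colMeans(-2 * cache$Xc)
    dZ1 <- sweep(dXhat, 2, cache$inv_sd, `*`) +
      sweep(cache$Xc, 2, 2 * dva / n, `*`) +
      matrix(dmu / n, n, length(dmu), byrow = TRUE)
  } else {
    dZ1 <- sweep(dXhat, 2, cache$inv_sd, `*`)
  }
  gr$l1$W <- crossprod(cache$X, dZ1)
  gr$l1$b <- colSums(dZ1)
  dX <- dZ1 %*% t(dec$l1$W)
  list(grads = gr, dX = dX)
}

#' Score drug-disease pairs from encoded features
#'
#' `score = sigmoid(L2(dropout(ReLU(batchnorm(L1(concat(feat_drug,
#' feat_disease)))))))`. Eval mode is deterministic (dropout off, running
#' batch-norm statistics); scores lie strictly in (0, 1).
#'
#' @param feat named list of per-type feature matrices with node-id rownames,
#'   e.g. the output of [encode()] after row naming, or any list where
#'   `feat[[type]][id, ]` resolves.
#' @param pairs data.frame with columns `drug`, `disease` (and optionally
#'   `label`).
#' @param dec a `decoder_params` object.
#' @param mode `"eval"` (default) or `"train"`.
#' @param drug_type,disease_type names of the two feature blocks.
#' @return data.frame `drug`, `disease`, `score`, `label` (NA when unknown).
#' @export
score_pairs <- function(feat, pairs, dec, mode = c("eval", "train"),
                        drug_type = "drug", disease_type = "disease") {
  mode <- match.arg(mode)
  fd <- feat[[drug_type]]; fs <- feat[[disease_type]]
  miss_d <- setdiff(unique(pairs$drug), rownames(fd))
  miss_s <- setdiff(unique(pairs$disease), rownames(fs))
  if (length(miss_d) || length(miss_s))
    stop_hgt("pair endpoint(s) missing from features (first: %s)",
             c(miss_d, miss_s)[1], class = "hgt_lookup_error")
  X <- cbind(fd[pairs$drug, , drop = FALSE], fs[pairs$disease, , drop = FALSE])
  fw <- decoder_forward(X, dec, mode)
  data.frame(drug = pairs$drug, disease = pairs$disease,
             score = unname(fw$score),
             label = if ("label" %in% names(pairs)) pairs$label else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Mean binary cross-entropy of scored pairs
#'
#' `-mean(y * log(s) + (1 - y) * log(1 - s))`; scores are clamped away from 0
#' and 1 by 1e-15 for numerical safety.
#'
#' @param scored data.frame with `score` and `label` columns, or a numeric
#'   vector of labels (then `scores` must be given).
#' @param scores optional numeric score vector when `scored` is a label vector.
#' @return non-negative scalar loss.
#' @export
bce_loss <- function(scored, scores = NULL) {
  if (is.data.frame(scored)) {
    y <- scored$label; s <- scored$score
  } else {
    y <- scored; s <- scores
  }
  if (length(y) == 0L)
    stop_hgt("cannot compute a loss over zero pairs", class = "hgt_config_error")
  s <- pmin(pmax(s, 1e-15), 1 - 1e-15)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

#' Draw negative drug-disease pairs from a subgraph
#'
#' Uniform over all drug x disease pairs of the subgraph that are not
#' forbidden (known positives), without replacement.
#'
#' @param batch a `subgraph_batch` (or a `hetero_graph`).
#' @param n_neg number of pairs to draw.
#' @param forbidden data.frame of pairs (`drug`, `disease`) that must not be
#'   drawn, in either orientation.
#' @param rng_seed integer seed.
#' @param drug_type,disease_type endpoint node types. When they coincide,
#'   pairs are unordered and self-pairs are excluded.
#' @return data.frame `drug`, `disease`, `label` (all 0).
#' @export
sample_negatives <- function(batch, n_neg, forbidden = NULL, rng_seed = 1L,
                             drug_type = "drug", disease_type = "disease") {
  g <- if (inherits(batch, "hetero_graph")) batch else batch$subgraph
  drugs <- g$nodes[[drug_type]]; diseases <- g$nodes[[disease_type]]
  if (!length(drugs) || !length(diseases))
    stop_hgt("subgraph lacks %s or %s nodes", drug_type, disease_type,
             class = "hgt_pool_exhausted_error")
  pool <- expand.grid(drug = drugs, disease = diseases,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (drug_type == disease_type) {
    keep <- pool$drug < pool$disease
    pool <- pool[keep, , drop = FALSE]
  }
  if (!is.null(forbidden) && nrow(forbidden)) {
    bad <- c(pair_key(forbidden$drug, forbidden$disease),
             pair_key(forbidden$disease, forbidden$drug))
    pool <- pool[!pair_key(pool$drug, pool$disease) %in% bad, , drop = FALSE]
  }
  if (nrow(pool) < n_neg)
    stop_hgt("admissible negative pool (%d pairs) smaller than requested %d",
             nrow(pool), n_neg, class = "hgt_pool_exhausted_error")
  idx <- with_seed(rng_seed, sample.int(nrow(pool), n_neg))
  out <- pool[idx, , drop = FALSE]
  out$label <- 0L
  rownames(out) <- NULL
  out
}
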