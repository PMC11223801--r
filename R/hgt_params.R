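# Parameter banks for the heterogeneous graph transformer.
#
# Weights are keyed by node type (key/query/message/aggregation linears) and
# by relation (bilinear attention and message matrices), with one learnable
# scalar prior mu per meta-relation; this is what lets a single layer treat
# each semantic edge class with its own projection while sharing the
# attention machinery.

# fan-in-scaled uniform init, as conventional for dense layers
init_linear <- function(d_in, d_out) {
  bound <- 1 / sqrt(d_in)
  list(W = matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out),
       b = stats::runif(d_out, -bound, bound))
}

lin_fwd <- function(x, lin) sweep(x %*% lin$W, 2, lin$b, `+`)

hcols <- function(i, d_head) ((i - 1L) * d_head + 1L):(i * d_head)

activation_fns <- function(name) {
  switch(name,
    gelu = list(f = function(x) x * stats::pnorm(x),
                g = function(x) stats::pnorm(x) + x * stats::dnorm(x)),
    relu = list(f = function(x) pmax(x, 0),
                g = function(x) (x > 0) * 1),
    stop_hgt("unknown activation '%s'", name, class = "hgt_config_error"))
}

#' Encoder configuration
#'
#' @param d_model layer width (input and output feature size of every
#'   attention layer). Default 64.
#' @param n_heads attention head count; must divide `d_model`. Default 8.
#' @param n_layers number of attention layers L. Default 3.
#' @param activation post-aggregation non-linearity, `"gelu"` (default) or
#'   `"relu"`.
#' @param dropout_in dropout probability applied after the ReLU of the input
#'   projection (training mode only). Default 0.5.
#' @param head_shared if `TRUE` (default) the concatenation head linear is
#'   shared across node types; `FALSE` keys it per type.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(d_model = 64L, n_heads = 8L, n_layers = 3L,
                           activation = c("gelu", "relu"), dropout_in = 0.5,
                           head_shared = TRUE) {
  activation <- match.arg(activation)
  d_model <- as.integer(d_model); n_heads <- as.integer(n_heads)
  if (d_model %% n_heads != 0L)
    stop_hgt("d_model (%d) must be divisible by n_heads (%d)", d_model, n_heads,
             class = "hgt_config_error")
  if (n_layers < 1L) stop_hgt("need at least one layer", class = "hgt_config_error")
  if (dropout_in < 0 || dropout_in > 1)
    stop_hgt("dropout_in must lie in [0,1]", class = "hgt_config_error")
  structure(list(d_model = d_model, n_heads = n_heads,
                 d_head = d_model %/% n_heads, n_layers = as.integer(n_layers),
                 activation = activation, dropout_in = dropout_in,
                 head_shared = head_shared),
            class = "encoder_config")
}

#' Initialise one attention layer's parameter bank
#'
#' @param types character vector of node types the layer must serve.
#' @param relations data.frame as returned by [meta_relations()] (one row per
#'   relation record; key/src_type/dst_type columns).
#' @param cfg an [encoder_config()].
#' @param rng_seed integer seed.
#' @return an `hgt_layer_params` object: per-type key/query/message linears
#'   (`d_model -> d_model`, head blocks of width `d_head`), per-type
#'   aggregation linear, per-relation `d_head x d_head x n_heads` attention
#'   and message arrays, and the meta-relation prior `mu` (initialised to 1).
#' @export
hgt_layer_params <- function(types, relations, cfg, rng_seed = 1L) {
  d <- cfg$d_model; dh <- cfg$d_head; h <- cfg$n_heads
  with_seed(rng_seed, {
    par <- list(k = list(), q = list(), m = list(), a = list(),
                att = list(), msg = list(), mu = list())
    for (ty in types) {
      par$k[[ty]] <- init_linear(d, d)
      par$q[[ty]] <- init_linear(d, d)
      par$m[[ty]] <- init_linear(d, d)
      par$a[[ty]] <- init_linear(d, d)
    }
    bound <- 1 / sqrt(dh)
    for (key in relations$key) {
      par$att[[key]] <- array(stats::runif(dh * dh * h, -bound, bound), c(dh, dh, h))
      par$msg[[key]] <- array(stats::runif(dh * dh * h, -bound, bound), c(dh, dh, h))
      par$mu[[key]] <- 1
    }
    structure(list(d_model = d, d_head = dh, h = h,
                   activation = cfg$activation, par = par),
              class = "hgt_layer_params")
  })
}

#' Initialise the full encoder parameter set
#'
#' @param g a `hetero_graph` carrying embeddings (or `input_dims` given).
#' @param cfg an [encoder_config()].
#' @param input_dims named integer vector type -> initial embedding width;
#'   taken from `g$embeddings` when omitted.
#' @param rng_seed integer seed.
#' @return an `encoder_params` object: input projections (one per type,
#'   `input_dim -> d_model`), `n_layers` layer banks, and the concatenation
#'   head (`n_layers * d_model -> d_model`).
#' @export
encoder_params <- function(g, cfg = encoder_config(), input_dims = NULL,
                           rng_seed = 1L) {
  types <- node_types(g)
  if (is.null(input_dims)) {
    if (is.null(g$embeddings))
      stop_hgt("graph carries no embeddings and input_dims not given",
               class = "hgt_config_error")
    input_dims <- vapply(g$embeddings, `[[`, 0L, "dim")[types]
  }
  rel <- meta_relations(g)
  layers <- lapply(seq_len(cfg$n_layers), function(l)
    hgt_layer_params(types, rel, cfg, derive_seed(rng_seed, paste0("layer/", l))))
  par <- with_seed(derive_seed(rng_seed, "proj"), {
    inp <- lapply(types, function(ty) init_linear(input_dims[[ty]], cfg$d_model))
    names(inp) <- types
    head <- if (cfg$head_shared) init_linear(cfg$n_layers * cfg$d_model, cfg$d_model)
      else { hs <- lapply(types, function(ty)
               init_linear(cfg$n_layers * cfg$d_model, cfg$d_model))
             names(hs) <- types; hs }
    list(inp = inp, head = head)
  })
  structure(list(cfg = cfg, types = types, input_dims = input_dims,
                 relations = rel$key, inp = par$inp, layers = layers,
                 head = par$head),
            class = "encoder_params")
}
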