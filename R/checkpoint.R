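# Plain-text parameter checkpoints: a JSON config header plus one line per
# named parameter array. Values are written as C99 hex floats (%a), which
# reload bit-exactly on any IEEE-754 platform.

flatten_tree <- function(x, prefix = character()) {
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- paste0("#", seq_along(x))
    out <- list()
    for (i in seq_along(x))
      out <- c(out, flatten_tree(x[[i]], c(prefix, nms[i])))
    return(out)
  }
  stats::setNames(list(x), paste(prefix, collapse = "\x1f"))
}

insert_path <- function(tree, path, value) {
  if (length(path) == 1L) { tree[[path]] <- value; return(tree) }
  if (is.null(tree[[path[1]]])) tree[[path[1]]] <- list()
  tree[[path[1]]] <- insert_path(tree[[path[1]]], path[-1], value)
  tree
}

unflatten_tree <- function(flat) {
  tree <- list()
  for (nm in names(flat))
    tree <- insert_path(tree, strsplit(nm, "\x1f", fixed = TRUE)[[1]], flat[[nm]])
  fix_idx <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, fix_idx)
    if (length(x) && all(grepl("^#[0-9]+$", names(x)))) {
      x <- x[order(as.integer(sub("#", "", names(x))))]
      names(x) <- NULL
    }
    x
  }
  fix_idx(tree)
}

#' Save a trained model as a plain-text checkpoint
#'
#' Writes `config.json` (architecture, configs, split metadata) and
#' `params.tsv` (one named parameter array per line, hex-float encoded) into
#' `dir`; [load_checkpoint()] restores the fit bit-exactly.
#'
#' @param fit an `hgtdr_fit`.
#' @param dir checkpoint directory (created).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- fit$model$encoder; dec <- fit$model$decoder
  header <- list(
    encoder_config = unclass(enc$cfg), decoder_config = unclass(dec$cfg),
    types = enc$types, input_dims = as.list(enc$input_dims),
    relations = enc$relations,
    training = unclass_deep(fit$training), split_meta = fit$split_meta)
  jsonlite::write_json(header, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  numeric_tree <- list(par = model_par(fit$model),
                       bn = list(run_mean = dec$run_mean, run_var = dec$run_var))
  flat <- flatten_tree(numeric_tree)
  lines <- vapply(names(flat), function(nm) {
    v <- flat[[nm]]
    d <- dim(v) %||% length(v)
    paste(gsub("\x1f", "/", nm), paste(d, collapse = ","),
          paste(sprintf("%a", as.numeric(v)), collapse = " "), sep = "\t")
  }, "")
  writeLines(lines, file.path(dir, "params.tsv"))
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Load a plain-text checkpoint
#'
#' @param dir directory written by [save_checkpoint()].
#' @return an `hgtdr_fit` (without the training history) ready for
#'   [score_with_model()] and [rank_novel()].
#' @export
load_checkpoint <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  lines <- readLines(file.path(dir, "params.tsv"))
  flat <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    dims <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    vals <- as.numeric(strsplit(parts[3], " ", fixed = TRUE)[[1]])
    if (length(dims) > 1L) dim(vals) <- dims
    flat[[gsub("/", "\x1f", parts[1], fixed = TRUE)]] <- vals
  }
  tree <- unflatten_tree(flat)
  ecfg <- do.call(encoder_config, header$encoder_config[
    c("d_model", "n_heads", "n_layers", "activation", "dropout_in", "head_shared")])
  dcfg <- do.call(decoder_config, header$decoder_config[
    c("d_model", "dropout", "bn_momentum", "bn_eps")])
  encoder <- structure(list(
    cfg = ecfg, types = header$types,
    input_dims = unlist(header$input_dims), relations = header$relations,
    inp = tree$par$enc$inp,
    layers = lapply(tree$par$enc$layers, function(p)
      structure(list(d_model = ecfg$d_model, d_head = ecfg$d_head,
                     h = ecfg$n_heads, activation = ecfg$activation, par = p),
                class = "hgt_layer_params")),
    head = tree$par$enc$head), class = "encoder_params")
  decoder <- structure(c(list(cfg = dcfg), tree$par$dec,
                         list(run_mean = as.numeric(tree$bn$run_mean),
                              run_var = as.numeric(tree$bn$run_var))),
                       class = "decoder_params")
  decoder <- decoder[c("cfg", "l1", "gamma", "beta", "run_mean", "run_var", "l2")]
  class(decoder) <- "decoder_params"
  tr <- header$training
  tr$sampler <- do.call(sampler_config, tr$sampler[c("depth", "budget", "batch_size", "rng_seed")])
  training <- do.call(training_config, tr[c("epochs", "lr", "weight_decay", "lr_min",
                                            "mask_fraction", "negatives_per_positive",
                                            "rng_seed")])
  training$sampler <- tr$sampler
  structure(list(model = structure(list(encoder = encoder, decoder = decoder),
                                   class = "hgtdr_model"),
                 history = NULL, encoder_config = ecfg, training = training,
                 split_meta = header$split_meta),
            class = "hgtdr_fit")
}
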