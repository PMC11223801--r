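#' Remove drugs and diseases with no indication support
#'
#' Drops every node of the target relation's two endpoint types that does not
#' participate in at least one target-relation (indication) edge, together
#' with all edges incident to a dropped node. Keeping such nodes inflates
#' apparent accuracy, because predicting "no indication" for them is easy;
#' removing them makes results comparable across methods. Other node types
#' are untouched, and the operation is idempotent.
#'
#' @param g a `hetero_graph`.
#' @param target_relation relation key or label (e.g. `"indication"`).
#' @return the filtered `hetero_graph`.
#' @export
filter_unindicated <- function(g, target_relation) {
  tr <- get_relation(g, target_relation)
  drug_type <- tr$src_type; disease_type <- tr$dst_type
  keep_drug <- unique(tr$src)
  keep_disease <- unique(tr$dst)
  if (drug_type == disease_type) keep_drug <- keep_disease <- unique(c(tr$src, tr$dst))
  selection <- g$nodes
  selection[[drug_type]] <- intersect(selection[[drug_type]], keep_drug)
  selection[[disease_type]] <- intersect(selection[[disease_type]], keep_disease)
  induce_subgraph(g, selection)
}

#' Collect the target-relation pair set
#'
#' Indication edges are treated as unordered (drug, disease) pairs: both
#' stored orientations of the same pair collapse to one pair. With
#' `pair_semantics = "directed"` each stored orientation counts separately.
#'
#' @param g a `hetero_graph`.
#' @param target_relation relation key or label.
#' @param pair_semantics `"unordered"` (default) or `"directed"`.
#' @return data.frame with columns `drug`, `disease` (ids in the relation's
#'   source/target type namespaces).
#' @export
indication_pairs <- function(g, target_relation,
                             pair_semantics = c("unordered", "directed")) {
  pair_semantics <- match.arg(pair_semantics)
  tr <- get_relation(g, target_relation)
  df <- data.frame(drug = tr$src, disease = tr$dst, stringsAsFactors = FALSE)
  if (pair_semantics == "unordered") {
    if (tr$src_type == tr$dst_type) {
      # self-paired relation: canonicalise to drug <= disease, no self-pairs
      df <- data.frame(drug = pmin(df$drug, df$disease),
                       disease = pmax(df$drug, df$disease),
                       stringsAsFactors = FALSE)
      df <- df[df$drug != df$disease, , drop = FALSE]
    }
    df <- unique(df)
    rownames(df) <- NULL
  }
  df
}

#' Split indication edges into masked and unmasked sets
#'
#' Masked indications are hidden from the input graph and act as training
#' positives; unmasked ones stay in the graph as ordinary edges. This is the
#' training-time simulation of drug repurposing: the model must score links
#' it cannot see. The default masks 80\% of indications.
#'
#' @param g a `hetero_graph`.
#' @param target_relation relation key or label.
#' @param mask_fraction fraction of target pairs to mask, in \[0, 1\].
#'   The masked count is `round(mask_fraction * N)` with half away from zero.
#' @param rng_seed integer seed; the same seed reproduces the split.
#' @param validation optional data.frame of pairs (columns `drug`, `disease`)
#'   held out entirely (removed from the graph and from the mask pool), used
#'   by cross-validation.
#' @param pair_semantics see [indication_pairs()].
#' @return an object of class `indication_split` with fields
#'   `target_relation`, `drug_type`, `disease_type`, `unmasked`, `masked`,
#'   `validation`, `negatives` (initially empty), and `seed`.
#' @export
split_indications <- function(g, target_relation, mask_fraction = 0.8,
                              rng_seed = 1L, validation = NULL,
                              pair_semantics = c("unordered", "directed")) {
  pair_semantics <- match.arg(pair_semantics)
  if (mask_fraction < 0 || mask_fraction > 1)
    stop_hgt("mask_fraction must lie in [0, 1]", class = "hgt_config_error")
  tr <- get_relation(g, target_relation)
  pairs <- indication_pairs(g, target_relation, pair_semantics)
  empty <- pairs[0, ]
  validation <- if (is.null(validation)) empty else validation[c("drug", "disease")]
  vkey <- pair_key(validation$drug, validation$disease)
  pool <- pairs[!pair_key(pairs$drug, pairs$disease) %in% vkey, ]
  n_mask <- round_half_away(mask_fraction * nrow(pool))
  idx <- with_seed(rng_seed, sample.int(nrow(pool), n_mask))
  masked <- pool[sort(idx), ]
  unmasked <- pool[-sort(idx), ]
  if (n_mask == 0L) { masked <- empty; unmasked <- pool }
  rownames(masked) <- rownames(unmasked) <- NULL
  structure(list(target_relation = resolve_relation_key(g, target_relation),
                 drug_type = tr$src_type, disease_type = tr$dst_type,
                 unmasked = unmasked, masked = masked, validation = validation,
                 negatives = empty, seed = rng_seed,
                 pair_semantics = pair_semantics),
            class = "indication_split")
}

#' @export
print.indication_split <- function(x, ...) {
  cat(sprintf("<indication_split> %s: %d unmasked / %d masked / %d validation / %d negatives\n",
              x$target_relation, nrow(x$unmasked), nrow(x$masked),
              nrow(x$validation), nrow(x$negatives)))
  invisible(x)
}

# All pairs known positive under a split (any role except negatives).
#' @keywords internal
known_positive_keys <- function(split) {
  c(pair_key(split$unmasked$drug, split$unmasked$disease),
    pair_key(split$masked$drug, split$masked$disease),
    pair_key(split$validation$drug, split$validation$disease))
}

#' Graph view with masked and validation indications hidden
#'
#' Restricts the target relation to the split's unmasked pairs. Both stored
#' orientations of a masked pair are removed, so neither the sampler nor the
#' encoder can see held-out links.
#'
#' @param g a `hetero_graph`.
#' @param split an `indication_split`.
#' @return the masked `hetero_graph` view.
#' @export
apply_split <- function(g, split) {
  key <- split$target_relation
  r <- g$relations[[key]]
  if (is.null(r)) stop_hgt("graph lacks relation '%s'", key, class = "hgt_config_error")
  ok <- pair_key(r$src, r$dst) %in% pair_key(split$unmasked$drug, split$unmasked$disease) |
    pair_key(r$dst, r$src) %in% pair_key(split$unmasked$drug, split$unmasked$disease)
  g$relations[[key]]$src <- r$src[ok]
  g$relations[[key]]$dst <- r$dst[ok]
  g
}

#' Assign pairs to cross-validation folds
#'
#' @param pairs data.frame with columns `drug`, `disease`.
#' @param k number of folds (>= 2).
#' @param rng_seed integer seed.
#' @return a `fold_plan`: list with `k`, `assignments` (integer fold index per
#'   row of `pairs`), `pairs`, `seed`. Fold sizes differ by at most one.
#' @export
make_folds <- function(pairs, k = 5L, rng_seed = 1L) {
  if (k < 2L) stop_hgt("fold count k must be >= 2", class = "hgt_config_error")
  n <- nrow(pairs)
  if (n < k) stop_hgt("need at least k pairs to form k folds", class = "hgt_config_error")
  # rep_len over a shuffled order gives sizes differing by <= 1
  assignments <- with_seed(rng_seed, sample(rep_len(seq_len(k), n)))
  structure(list(k = as.integer(k), assignments = assignments,
                 pairs = pairs, seed = rng_seed),
            class = "fold_plan")
}

#' Write a split (and optional fold plan) as a tidy table
#'
#' @param split an `indication_split`.
#' @param path output TSV path.
#' @param folds optional `fold_plan` over the union of masked, unmasked and
#'   validation pairs.
#' @return the path, invisibly.
#' @export
write_split_table <- function(split, path, folds = NULL) {
  pieces <- list(unmasked = split$unmasked, masked = split$masked,
                 validation = split$validation, negative = split$negatives)
  pieces <- pieces[vapply(pieces, nrow, 0L) > 0L]
  rows <- do.call(rbind, lapply(names(pieces), function(role)
    cbind(pieces[[role]], role = role)))
  rows$fold <- NA_integer_
  if (!is.null(folds)) {
    m <- match(pair_key(rows$drug, rows$disease),
               pair_key(folds$pairs$drug, folds$pairs$disease))
    rows$fold <- folds$assignments[m]
  }
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
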