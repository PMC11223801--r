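# Type-budgeted, importance-weighted neighbourhood sampling (HGSampling
# style). Starting from seed drugs, every already-sampled node spreads
# normalised-degree importance onto its unsampled neighbours; each of L
# iterations then draws up to `budget` nodes per node type with probability
# proportional to squared accumulated importance, which keeps the sampled
# subgraph dense and balanced across types.

#' Sampler configuration
#'
#' @param depth number of sampling iterations L (>= 1). Default 3, matching
#'   the encoder depth so sampled context covers the receptive field.
#' @param budget maximum number of nodes newly added per node type per
#'   iteration. Default 512.
#' @param batch_size seed drugs per mini-batch. Default 164.
#' @param rng_seed integer seed.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(depth = 3L, budget = 512L, batch_size = 164L,
                           rng_seed = 1L) {
  if (depth < 1L || budget < 1L || batch_size < 1L)
    stop_hgt("depth, budget and batch_size must all be >= 1",
             class = "hgt_config_error")
  structure(list(depth = as.integer(depth), budget = as.integer(budget),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "sampler_config")
}

#' Adjacency index for repeated sampling
#'
#' Precomputes, per node, its neighbour lists (both edge directions pooled
#' over all relations) and total degree. Build once per graph view and pass
#' to [sample_subgraph()] when sampling repeatedly.
#'
#' @param g a `hetero_graph`.
#' @return an opaque adjacency structure.
#' @export
build_adjacency <- function(g) {
  adj <- lapply(g$nodes, function(x) list())
  deg <- lapply(g$nodes, function(ids) stats::setNames(rep(0, length(ids)), ids))
  for (r in g$relations) {
    if (!length(r$src)) next
    adj[[r$src_type]] <- c(adj[[r$src_type]],
                           list(list(nbr_type = r$dst_type, nbrs = split(r$dst, r$src))))
    adj[[r$dst_type]] <- c(adj[[r$dst_type]],
                           list(list(nbr_type = r$src_type, nbrs = split(r$src, r$dst))))
    ts <- table(r$src); td <- table(r$dst)
    deg[[r$src_type]][names(ts)] <- deg[[r$src_type]][names(ts)] + as.numeric(ts)
    deg[[r$dst_type]][names(td)] <- deg[[r$dst_type]][names(td)] + as.numeric(td)
  }
  list(adj = adj, deg = deg)
}

#' Partition seed drugs into shuffled mini-batches
#'
#' @param drug_ids character vector of seed node ids.
#' @param batch_size batch size (last batch may be smaller).
#' @param rng_seed integer seed.
#' @return list of character vectors.
#' @export
partition_seeds <- function(drug_ids, batch_size = 164L, rng_seed = 1L) {
  if (batch_size < 1L) stop_hgt("batch_size must be >= 1", class = "hgt_config_error")
  ids <- with_seed(rng_seed, sample(drug_ids))
  split(ids, ceiling(seq_along(ids) / batch_size))
}

#' Sample a type-budgeted subgraph around seed nodes
#'
#' Runs `depth` iterations; each adds at most `budget` nodes per node type,
#' drawn without replacement with probability proportional to the square of
#' the importance accumulated from already-sampled neighbours (importance
#' contribution of a sampled node to each neighbour is 1/degree). Seeds are
#' always included and do not count against any budget. The returned
#' subgraph is the induced subgraph on all selected nodes.
#'
#' @param g a `hetero_graph` (typically the masked training view, so held-out
#'   links are invisible to the sampler).
#' @param seeds character vector of seed ids, or named list type -> ids.
#' @param cfg a [sampler_config()].
#' @param rng_seed seed overriding `cfg$rng_seed` (optional).
#' @param seed_type node type of unnamed `seeds`. Default `"drug"`.
#' @param adj optional precomputed [build_adjacency()] of `g`.
#' @return a `subgraph_batch`: `subgraph`, `seed_nodes`, `index`
#'   (per-type id -> local index maps), `new_per_iter` (per-iteration
#'   per-type counts of newly sampled nodes).
#' @export
sample_subgraph <- function(g, seeds, cfg = sampler_config(), rng_seed = NULL,
                            seed_type = "drug", adj = NULL) {
  if (is.null(adj)) adj <- build_adjacency(g)
  if (!is.list(seeds)) seeds <- stats::setNames(list(seeds), seed_type)
  if (!sum(lengths(seeds)))
    stop_hgt("empty seed set", class = "hgt_config_error")
  for (ty in names(seeds)) {
    bad <- setdiff(seeds[[ty]], g$nodes[[ty]])
    if (length(bad))
      stop_hgt("seed id '%s' not a %s node", bad[1], ty, class = "hgt_lookup_error")
  }
  seed <- rng_seed %||% cfg$rng_seed
  sampled <- lapply(g$nodes, function(x) character())
  budget <- lapply(g$nodes, function(x) numeric())  # named importance scores
  add_importance <- function(ty, new_nodes) {
    for (rec in adj$adj[[ty]]) {
      nb <- rec$nbrs[new_nodes]
      nb <- nb[!vapply(nb, is.null, TRUE)]
      if (!length(nb)) next
      w <- rep(1 / pmax(adj$deg[[ty]][names(nb)], 1), lengths(nb))
      flat <- unlist(nb, use.names = FALSE)
      keep <- !(flat %in% sampled[[rec$nbr_type]])
      if (!any(keep)) next
      inc <- rowsum(w[keep], flat[keep])
      cur <- budget[[rec$nbr_type]]
      ids <- rownames(inc)
      known <- ids %in% names(cur)
      cur[ids[known]] <- cur[ids[known]] + inc[known, 1]
      if (any(!known))
        cur <- c(cur, stats::setNames(inc[!known, 1], ids[!known]))
      budget[[rec$nbr_type]] <<- cur
    }
  }
  for (ty in names(seeds)) {
    sampled[[ty]] <- unique(seeds[[ty]])
  }
  for (ty in names(seeds)) add_importance(ty, sampled[[ty]])
  new_per_iter <- list()
  with_seed(seed, {
    for (it in seq_len(cfg$depth)) {
      counts <- stats::setNames(integer(length(sampled)), names(sampled))
      new_nodes <- list()
      for (ty in names(sampled)) {
        pool <- budget[[ty]]
        pool <- pool[!(names(pool) %in% sampled[[ty]])]
        if (!length(pool)) next
        n_draw <- min(cfg$budget, length(pool))
        picked <- if (n_draw == length(pool)) names(pool)
          else names(pool)[sample.int(length(pool), n_draw, prob = pool^2)]
        sampled[[ty]] <- c(sampled[[ty]], picked)
        budget[[ty]] <- budget[[ty]][!(names(budget[[ty]]) %in% picked)]
        counts[[ty]] <- n_draw
        new_nodes[[ty]] <- picked
      }
      # budgets update only after the whole iteration's draws, so one
      # iteration expands the frontier by exactly one hop
      for (ty in names(new_nodes)) add_importance(ty, new_nodes[[ty]])
      new_per_iter[[it]] <- counts
    }
  })
  sg <- induce_subgraph(g, sampled)
  structure(list(subgraph = sg,
                 seed_nodes = seeds,
                 index = lapply(sg$nodes, function(ids)
                   stats::setNames(seq_along(ids), ids)),
                 new_per_iter = new_per_iter),
            class = "subgraph_batch")
}

#' @export
print.subgraph_batch <- function(x, ...) {
  cat(sprintf("<subgraph_batch> %d nodes, %d edges, %d seed(s)\n",
              n_nodes(x$subgraph), n_edges(x$subgraph), sum(lengths(x$seed_nodes))))
  invisible(x)
}

#' Usable positives per sampled batch
#'
#' Counts, per batch, the masked target pairs whose two endpoints both lie
#' inside the batch's subgraph (only those can enter the batch loss).
#'
#' @param batches list of `subgraph_batch`.
#' @param split an `indication_split`.
#' @return data.frame `batch`, `usable_positives`, `n_drug`, `n_disease`.
#' @export
coverage_report <- function(batches, split) {
  if (!length(batches)) stop_hgt("no batches given", class = "hgt_config_error")
  rows <- lapply(seq_along(batches), function(i) {
    sg <- batches[[i]]$subgraph
    dr <- sg$nodes[[split$drug_type]]; ds <- sg$nodes[[split$disease_type]]
    ok <- split$masked$drug %in% dr & split$masked$disease %in% ds
    data.frame(batch = i, usable_positives = sum(ok),
               n_drug = length(dr), n_disease = length(ds))
  })
  do.call(rbind, rows)
}
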