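#' Build an embedding table for one node type
#'
#' @param node_type node type label.
#' @param vectors numeric matrix, one row per node, rownames = node ids.
#' @return an `embedding_table` with fields `node_type`, `dim`, `vectors`.
#' @export
embedding_table <- function(node_type, vectors) {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors)))
    stop_hgt("embedding vectors need node ids as rownames", class = "hgt_format_error")
  storage.mode(vectors) <- "double"
  structure(list(node_type = node_type, dim = ncol(vectors), vectors = vectors),
            class = "embedding_table")
}

#' Seeded random initial embeddings
#'
#' Stands in for pretrained text/molecule-model vectors: standard-normal
#' entries, reproducible under the same seed. Dimensions may differ per type;
#' the encoder's input projection absorbs the heterogeneity.
#'
#' @param g a `hetero_graph`.
#' @param dim_per_type named integer vector or list: type -> dimension; a
#'   single unnamed value applies to every type. Default 768, matching common
#'   language-model output widths.
#' @param rng_seed integer seed.
#' @return named list of `embedding_table`, one per node type of `g`.
#' @export
random_embeddings <- function(g, dim_per_type = 768L, rng_seed = 1L) {
  types <- node_types(g)
  dims <- if (is.null(names(dim_per_type)))
    stats::setNames(rep(as.integer(dim_per_type[[1]]), length(types)), types)
  else unlist(dim_per_type)[types]
  out <- list()
  for (ty in types) {
    d <- as.integer(dims[[ty]])
    if (is.na(d) || d < 1L)
      stop_hgt("embedding dimension for type '%s' must be a positive integer", ty,
               class = "hgt_config_error")
    n <- n_nodes(g, ty)
    m <- with_seed(derive_seed(rng_seed, paste0("init/", ty)),
                   matrix(stats::rnorm(n * d), nrow = n, ncol = d))
    rownames(m) <- g$nodes[[ty]]
    out[[ty]] <- embedding_table(ty, m)
  }
  out
}

#' Attach per-node initial feature vectors to a graph
#'
#' Never alters topology; the graph simply carries `H_init`. Per-type
#' dimensions may differ (a 768-dim text embedding for proteins can coexist
#' with a 384-dim structure embedding for drugs).
#'
#' @param g a `hetero_graph`.
#' @param tables named list of `embedding_table`, one per node type.
#' @param missing `"strict"` (error listing ids without a vector) or
#'   `"impute-random"` (fill gaps with seeded standard-normal vectors).
#' @param rng_seed seed for imputation.
#' @return the graph with an `embeddings` field.
#' @export
attach_embeddings <- function(g, tables, missing = c("strict", "impute-random"),
                              rng_seed = 1L) {
  missing <- match.arg(missing)
  emb <- list()
  for (ty in node_types(g)) {
    tab <- tables[[ty]]
    if (is.null(tab))
      stop_hgt("no embedding table supplied for node type '%s'", ty,
               class = "hgt_missing_embedding_error")
    extra <- setdiff(rownames(tab$vectors), g$nodes[[ty]])
    if (length(extra))
      stop_hgt("embedding table for '%s' keyed by unknown id '%s'", ty, extra[1],
               class = "hgt_lookup_error")
    absent <- setdiff(g$nodes[[ty]], rownames(tab$vectors))
    vecs <- tab$vectors
    if (length(absent)) {
      if (missing == "strict")
        stop_hgt("type '%s': %d node(s) lack an embedding (first: %s)",
                 ty, length(absent), absent[1], class = "hgt_missing_embedding_error")
      fill <- with_seed(derive_seed(rng_seed, paste0("impute/", ty)),
                        matrix(stats::rnorm(length(absent) * tab$dim),
                               nrow = length(absent)))
      rownames(fill) <- absent
      vecs <- rbind(vecs, fill)
      message(sprintf("imputed %d missing '%s' embedding(s)", length(absent), ty))
    }
    emb[[ty]] <- embedding_table(ty, vecs[g$nodes[[ty]], , drop = FALSE])
  }
  g$embeddings <- emb
  g
}

#' Read an embedding table from a delimited file
#'
#' First column: node id; remaining columns: numeric coordinates.
#'
#' @param path CSV/TSV path.
#' @param node_type type label the ids belong to.
#' @return an `embedding_table` with `dim = ncol - 1`.
#' @export
load_embedding_file <- function(path, node_type) {
  dt <- data.table::fread(path, showProgress = FALSE)
  if (ncol(dt) < 2L)
    stop_hgt("embedding file '%s' needs an id column plus >=1 numeric column",
             path, class = "hgt_format_error")
  ids <- as.character(dt[[1]])
  num <- dt[, -1]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop_hgt("embedding file '%s': non-numeric value in column %d, row %d",
               path, j + 1L, bad %||% 1L, class = "hgt_format_error")
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  colnames(m) <- NULL
  embedding_table(node_type, m)
}

#' Write an embedding table to CSV
#'
#' Full-precision round-trip partner of [load_embedding_file()].
#' @param table an `embedding_table`.
#' @param path output path.
#' @export
write_embedding_file <- function(table, path) {
  dt <- data.table::data.table(id = rownames(table$vectors))
  # 17 significant digits: doubles round-trip exactly through the text form
  num <- apply(unname(table$vectors), 2, function(col) sprintf("%.17g", col))
  dt <- cbind(dt, data.table::as.data.table(matrix(num, nrow = nrow(dt))))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}
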