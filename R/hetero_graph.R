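#' Construct a heterogeneous knowledge graph
#'
#' A `hetero_graph` holds typed nodes and typed directed edges. Each node
#' lives in the namespace of its type (the same raw identifier may appear
#' under two types and denotes two distinct nodes). Each relation declares its
#' endpoint types, so the meta-relation
#' \eqn{\langle\tau(s), \phi(e), \tau(t)\rangle} of every edge is well defined.
#'
#' @param nodes named list: node type -> character vector of unique node ids.
#' @param relations named list of relation records, each a list with fields
#'   `relation` (label), `src_type`, `dst_type`, `src`, `dst` (parallel
#'   character vectors of endpoint ids). Names of the list are the relation
#'   keys used throughout the package; by default the key equals the label,
#'   with `label.srctype.dsttype` used to disambiguate a label shared by
#'   several endpoint-type pairs.
#' @param node_names optional named list: type -> named character vector
#'   mapping node id to a display name.
#' @return an object of class `hetero_graph`.
#' @export
hetero_graph <- function(nodes = list(), relations = list(), node_names = list()) {
  nodes <- lapply(nodes, as.character)
  g <- structure(list(nodes = nodes, relations = relations,
                      node_names = node_names),
                 class = "hetero_graph")
  validate_hetero_graph(g)
}

#' @keywords internal
validate_hetero_graph <- function(g) {
  for (ty in names(g$nodes)) {
    if (anyDuplicated(g$nodes[[ty]]))
      stop_hgt("duplicated node ids within type '%s'", ty, class = "hgt_schema_error")
  }
  for (key in names(g$relations)) {
    r <- g$relations[[key]]
    for (f in c("relation", "src_type", "dst_type", "src", "dst"))
      if (is.null(r[[f]]))
        stop_hgt("relation '%s' lacks field '%s'", key, f, class = "hgt_schema_error")
    if (length(r$src) != length(r$dst))
      stop_hgt("relation '%s': src/dst length mismatch", key, class = "hgt_schema_error")
    for (side in c("src", "dst")) {
      ty <- r[[paste0(side, "_type")]]
      if (!ty %in% names(g$nodes))
        stop_hgt("relation '%s' references undeclared node type '%s'", key, ty,
                 class = "hgt_schema_error")
      bad <- setdiff(r[[side]], g$nodes[[ty]])
      if (length(bad))
        stop_hgt("relation '%s': %s endpoint id(s) missing from type '%s' (first: %s)",
                 key, side, ty, bad[1], class = "hgt_schema_error")
    }
  }
  g
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("<hetero_graph> %d node types, %d relations, %d nodes, %d edges\n",
              length(x$nodes), length(x$relations),
              sum(lengths(x$nodes)), n_edges(x)))
  invisible(x)
}

#' Node types of a graph
#' @param g a `hetero_graph`.
#' @return character vector of node type labels.
#' @export
node_types <- function(g) names(g$nodes)

#' Relation keys of a graph
#' @param g a `hetero_graph`.
#' @return character vector of relation keys.
#' @export
relation_keys <- function(g) names(g$relations)

#' Number of nodes, optionally per type
#' @param g a `hetero_graph`.
#' @param type optional node type.
#' @export
n_nodes <- function(g, type = NULL) {
  if (is.null(type)) return(sum(lengths(g$nodes)))
  length(g$nodes[[type]])
}

#' Number of directed edges, optionally per relation
#' @param g a `hetero_graph`.
#' @param relation optional relation key or label.
#' @export
n_edges <- function(g, relation = NULL) {
  if (is.null(relation)) return(sum(vapply(g$relations, function(r) length(r$src), 0L)))
  length(get_relation(g, relation)$src)
}

# Resolve a relation key or label to its record; errors on unknown/ambiguous.
#' @keywords internal
get_relation <- function(g, relation) {
  if (relation %in% names(g$relations)) return(g$relations[[relation]])
  hits <- which(vapply(g$relations, function(r) identical(r$relation, relation), TRUE))
  if (length(hits) == 1L) return(g$relations[[hits]])
  if (length(hits) > 1L)
    stop_hgt("relation label '%s' is ambiguous; use one of the keys: %s",
             relation, paste(names(g$relations)[hits], collapse = ", "),
             class = "hgt_config_error")
  stop_hgt("unknown relation '%s'", relation, class = "hgt_config_error")
}

resolve_relation_key <- function(g, relation) {
  if (relation %in% names(g$relations)) return(relation)
  hits <- which(vapply(g$relations, function(r) identical(r$relation, relation), TRUE))
  if (length(hits) == 1L) return(names(g$relations)[hits])
  get_relation(g, relation) # delegates error handling
}

#' Enumerate the meta-relations of a graph
#'
#' @param g a `hetero_graph`.
#' @return data.frame with columns `key`, `relation`, `src_type`, `dst_type`,
#'   `n_edges`, one row per relation record.
#' @export
meta_relations <- function(g) {
  data.frame(
    key = names(g$relations) %||% character(),
    relation = vapply(g$relations, `[[`, "", "relation"),
    src_type = vapply(g$relations, `[[`, "", "src_type"),
    dst_type = vapply(g$relations, `[[`, "", "dst_type"),
    n_edges = vapply(g$relations, function(r) length(r$src), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Induce the subgraph on a node selection
#'
#' Keeps exactly the selected nodes and every edge of `g` whose two endpoints
#' are both selected.
#'
#' @param g a `hetero_graph`.
#' @param selection named list: type -> character vector of node ids to keep.
#'   Types absent from `selection` keep no nodes.
#' @return the induced `hetero_graph`.
#' @export
induce_subgraph <- function(g, selection) {
  nodes <- list()
  for (ty in names(g$nodes)) {
    sel <- selection[[ty]] %||% character()
    unknown <- setdiff(sel, g$nodes[[ty]])
    if (length(unknown))
      stop_hgt("selection for type '%s' contains unknown id(s) (first: %s)",
               ty, unknown[1], class = "hgt_lookup_error")
    nodes[[ty]] <- g$nodes[[ty]][g$nodes[[ty]] %in% sel]  # preserve order
  }
  relations <- list()
  for (key in names(g$relations)) {
    r <- g$relations[[key]]
    keep <- r$src %in% nodes[[r$src_type]] & r$dst %in% nodes[[r$dst_type]]
    relations[[key]] <- list(relation = r$relation, src_type = r$src_type,
                             dst_type = r$dst_type,
                             src = r$src[keep], dst = r$dst[keep])
  }
  node_names <- lapply(names(g$node_names) %||% character(), function(ty) {
    nm <- g$node_names[[ty]]
    nm[names(nm) %in% nodes[[ty]]]
  })
  names(node_names) <- names(g$node_names) %||% character()
  hetero_graph(nodes, relations, node_names)
}

#' Remove one relation type from a graph
#'
#' Drops every edge of the relation; node sets and all other relations are
#' untouched. The relation record itself is kept with zero edges so the schema
#' (and any parameters keyed by it) stays enumerable.
#'
#' @param g a `hetero_graph`.
#' @param relation relation key or label.
#' @return the graph without that relation's edges.
#' @export
remove_relation <- function(g, relation) {
  key <- resolve_relation_key(g, relation)
  g$relations[[key]]$src <- character()
  g$relations[[key]]$dst <- character()
  g
}

#' Materialise reverse relations for message passing
#'
#' The encoder aggregates into target nodes from source nodes only, so every
#' stored relation not already paired with its reverse orientation gets a
#' `rev.`-prefixed reverse twin. Information can then flow both ways along any
#' edge.
#'
#' @param g a `hetero_graph`.
#' @return graph with reverse relations added.
#' @export
add_reverse_relations <- function(g) {
  mr <- meta_relations(g)
  for (key in names(g$relations)) {
    r <- g$relations[[key]]
    # a same-label record with swapped endpoint types counts as the reverse
    paired <- any(mr$relation == r$relation & mr$src_type == r$dst_type &
                    mr$dst_type == r$src_type & mr$key != key)
    if (r$src_type == r$dst_type) {
      # same-type relation: add the reversed edges into the same record unless
      # it is already symmetric as an edge set
      k1 <- pair_key(r$src, r$dst); k2 <- pair_key(r$dst, r$src)
      if (!all(k2 %in% k1)) {
        add <- !(k2 %in% k1)
        g$relations[[key]]$src <- c(r$src, r$dst[add])
        g$relations[[key]]$dst <- c(r$dst, r$src[add])
      }
    } else if (!paired) {
      rev_key <- paste0("rev.", key)
      if (!rev_key %in% names(g$relations))
        g$relations[[rev_key]] <- list(relation = paste0("rev.", r$relation),
                                       src_type = r$dst_type, dst_type = r$src_type,
                                       src = r$dst, dst = r$src)
    }
  }
  g
}

#' Column mapping for PrimeKG-style edge tables
#'
#' @param relation,src_type,src_id,dst_type,dst_id,src_name,dst_name column
#'   names in the CSV. Defaults follow the PrimeKG release
#'   (`relation`, `x_type`, `x_id`, `y_type`, `y_id`, `x_name`, `y_name`).
#' @return a dialect list consumed by [load_edge_table()].
#' @export
primekg_dialect <- function(relation = "relation",
                            src_type = "x_type", src_id = "x_id",
                            dst_type = "y_type", dst_id = "y_id",
                            src_name = "x_name", dst_name = "y_name") {
  list(relation = relation, src_type = src_type, src_id = src_id,
       dst_type = dst_type, dst_id = dst_id,
       src_name = src_name, dst_name = dst_name)
}

#' Read a heterogeneous graph from a CSV edge table
#'
#' One row per stored directed edge. Node sets are the union of endpoint ids
#' per type; exact duplicate edges are collapsed (set semantics, so per-type
#' counts match deduplicated row counts).
#'
#' @param path CSV/TSV file path.
#' @param dialect column mapping, see [primekg_dialect()].
#' @param node_types optional declared node type set; rows mentioning a type
#'   outside it raise a schema error. `NULL` accepts all types found.
#' @param dedupe collapse exact duplicate (relation, src, dst) rows.
#' @return a `hetero_graph`.
#' @export
load_edge_table <- function(path, dialect = primekg_dialect(),
                            node_types = NULL, dedupe = TRUE) {
  if (!file.exists(path))
    stop_hgt("edge table '%s' does not exist", path, class = "hgt_format_error")
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  if (nrow(dt) == 0L)
    stop_hgt("edge table '%s' is empty", path, class = "hgt_empty_graph_error")
  required <- c("relation", "src_type", "src_id", "dst_type", "dst_id")
  for (f in required) {
    col <- dialect[[f]]
    if (is.null(col) || !col %in% names(dt))
      stop_hgt("edge table '%s' is missing required column '%s' (%s)",
               path, col %||% f, f, class = "hgt_format_error")
  }
  rel <- dt[[dialect$relation]]
  sty <- dt[[dialect$src_type]]; sid <- dt[[dialect$src_id]]
  dty <- dt[[dialect$dst_type]]; did <- dt[[dialect$dst_id]]
  if (!is.null(node_types)) {
    bad <- setdiff(unique(c(sty, dty)), node_types)
    if (length(bad))
      stop_hgt("edge table references undeclared node type(s): %s",
               paste(bad, collapse = ", "), class = "hgt_schema_error")
  }
  types <- unique(c(sty, dty))
  nodes <- lapply(types, function(ty)
    unique(c(sid[sty == ty], did[dty == ty])))
  names(nodes) <- types

  node_names <- list()
  if (!is.null(dialect$src_name) && dialect$src_name %in% names(dt)) {
    snm <- dt[[dialect$src_name]]; dnm <- dt[[dialect$dst_name]]
    for (ty in types) {
      ids <- c(sid[sty == ty], did[dty == ty])
      nms <- c(snm[sty == ty], dnm[dty == ty])
      keep <- !duplicated(ids)
      node_names[[ty]] <- stats::setNames(nms[keep], ids[keep])
    }
  }

  grp <- paste(rel, sty, dty, sep = "\r")
  relations <- list()
  for (gkey in unique(grp)) {
    idx <- which(grp == gkey)
    parts <- strsplit(gkey, "\r", fixed = TRUE)[[1]]
    src <- sid[idx]; dst <- did[idx]
    if (dedupe) {
      keep <- !duplicated(pair_key(src, dst))
      src <- src[keep]; dst <- dst[keep]
    }
    relations[[length(relations) + 1L]] <-
      list(relation = parts[1], src_type = parts[2], dst_type = parts[3],
           src = src, dst = dst)
  }
  labels <- vapply(relations, `[[`, "", "relation")
  keys <- labels
  dup <- labels %in% labels[duplicated(labels)]
  keys[dup] <- paste(labels[dup],
                     vapply(relations, `[[`, "", "src_type")[dup],
                     vapply(relations, `[[`, "", "dst_type")[dup], sep = ".")
  names(relations) <- keys
  hetero_graph(nodes, relations, node_names)
}

#' Write a graph back to a CSV edge table
#'
#' Inverse of [load_edge_table()]: the written file, re-read, reproduces the
#' per-relation directed edge multisets.
#'
#' @param g a `hetero_graph`.
#' @param path output CSV path.
#' @param dialect column mapping, see [primekg_dialect()].
#' @export
write_edge_table <- function(g, path, dialect = primekg_dialect()) {
  rows <- lapply(names(g$relations), function(key) {
    r <- g$relations[[key]]
    if (!length(r$src)) return(NULL)
    lookup_name <- function(ty, ids) {
      nm <- g$node_names[[ty]]
      if (is.null(nm)) ids else unname(ifelse(is.na(nm[ids]), ids, nm[ids]))
    }
    out <- data.table::data.table(r$relation, r$src_type, r$src,
                                  lookup_name(r$src_type, r$src),
                                  r$dst_type, r$dst,
                                  lookup_name(r$dst_type, r$dst))
    data.table::setnames(out, c(dialect$relation, dialect$src_type,
                                dialect$src_id, dialect$src_name,
                                dialect$dst_type, dialect$dst_id,
                                dialect$dst_name))
    out
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path)
  invisible(path)
}
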