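# Forward pass of the heterogeneous graph transformer.
#
# A "compute view" flattens a hetero_graph into per-target-type inboxes of
# integer-indexed edges grouped by relation, so attention, messages and
# aggregation run as a handful of dense matrix products per relation segment
# instead of per-edge loops.

#' Build the integer-indexed compute view of a graph
#'
#' @param g a `hetero_graph`.
#' @return a `compute_view`: per-type node counts and id->index maps, and per
#'   target type an inbox of incoming edges segmented by relation.
#' @export
build_compute_view <- function(g) {
  types <- node_types(g)
  n <- vapply(g$nodes, length, 0L)
  index <- lapply(g$nodes, function(ids) stats::setNames(seq_along(ids), ids))
  inbox <- stats::setNames(vector("list", length(types)), types)
  mkeys <- character()
  for (key in names(g$relations)) {
    r <- g$relations[[key]]
    if (!length(r$src)) next
    tt <- r$dst_type
    seg <- list(key = key, mkey = paste(r$src_type, r$relation, r$dst_type, sep = "|"),
                src_type = r$src_type,
                src_idx = unname(index[[r$src_type]][r$src]),
                dst_idx = unname(index[[tt]][r$dst]),
                n = length(r$src))
    mkeys <- c(mkeys, seg$mkey)
    inbox[[tt]]$segs <- c(inbox[[tt]]$segs, list(seg))
  }
  for (tt in types) {
    ib <- inbox[[tt]]
    if (is.null(ib)) { inbox[[tt]] <- list(E = 0L); next }
    dst_all <- unlist(lapply(ib$segs, `[[`, "dst_idx"))
    ugrp <- sort(unique(dst_all))
    gidx <- match(dst_all, ugrp)
    inbox[[tt]] <- list(segs = ib$segs, E = length(dst_all), dst_all = dst_all,
                        ugrp = ugrp, gidx = gidx,
                        gsplit = split(seq_along(dst_all), gidx))
  }
  structure(list(types = types, n = n, index = index, inbox = inbox,
                 mkeys = unique(mkeys), graph = g),
            class = "compute_view")
}

# softmax over edges sharing a target node (per head), with max subtraction
seg_softmax <- function(x, ib) {
  mx <- vapply(ib$gsplit, function(ix) max(x[ix]), numeric(1))
  ex <- exp(x - mx[ib$gidx])
  denom <- rowsum(ex, ib$gidx)[, 1]
  ex / denom[ib$gidx]
}

# rowsum-based scatter-add: M[idx[e], cols] += X[e, ] with duplicate idx
scatter_add <- function(M, idx, X, cols = seq_len(ncol(M))) {
  rs <- rowsum(X, idx)
  r <- as.integer(rownames(rs))
  M[r, cols] <- M[r, cols] + rs
  M
}

check_layer_covers <- function(view, lp) {
  for (tt in view$types) {
    ib <- view$inbox[[tt]]
    if (ib$E == 0L) next
    for (seg in ib$segs)
      if (is.null(lp$par$att[[seg$key]]))
        stop_hgt("no layer parameters for relation '%s' (meta-relation %s)",
                 seg$key, seg$mkey, class = "hgt_unseen_relation_error")
  }
  invisible(TRUE)
}

# One full attention layer. Returns updated states plus the cache needed for
# the backward pass.
hgt_layer_forward <- function(view, H, lp) {
  d <- lp$d_model; h <- lp$h; dh <- lp$d_head
  actf <- activation_fns(lp$activation)
  check_layer_covers(view, lp)
  KQM <- list()
  for (ty in view$types) {
    x <- H[[ty]]
    KQM[[ty]] <- list(K = lin_fwd(x, lp$par$k[[ty]]),
                      Q = lin_fwd(x, lp$par$q[[ty]]),
                      M = lin_fwd(x, lp$par$m[[ty]]))
  }
  out <- H
  cache <- list(KQM = KQM, H = H, tts = list())
  for (tt in view$types) {
    ib <- view$inbox[[tt]]
    n_tt <- view$n[[tt]]
    if (ib$E > 0L) {
      BASE <- matrix(0, ib$E, h); MSG <- matrix(0, ib$E, d)
      off <- 0L
      for (seg in ib$segs) {
        rows <- off + seq_len(seg$n)
        Ksrc <- KQM[[seg$src_type]]$K[seg$src_idx, , drop = FALSE]
        Msrc <- KQM[[seg$src_type]]$M[seg$src_idx, , drop = FALSE]
        Qdst <- KQM[[tt]]$Q[seg$dst_idx, , drop = FALSE]
        for (i in seq_len(h)) {
          cols <- hcols(i, dh)
          P <- Ksrc[, cols, drop = FALSE] %*% lp$par$att[[seg$key]][, , i]
          BASE[rows, i] <- rowSums(P * Qdst[, cols, drop = FALSE]) / sqrt(dh)
          MSG[rows, cols] <- Msrc[, cols, drop = FALSE] %*% lp$par$msg[[seg$key]][, , i]
        }
        off <- off + seg$n
      }
      mu_e <- unlist(lapply(ib$segs, function(s) rep(lp$par$mu[[s$key]], s$n)))
      S <- BASE * mu_e
      ALPHA <- matrix(0, ib$E, h)
      for (i in seq_len(h)) ALPHA[, i] <- seg_softmax(S[, i], ib)
      Ht <- matrix(0, n_tt, d)
      for (i in seq_len(h)) {
        cols <- hcols(i, dh)
        Ht <- scatter_add(Ht, ib$dst_all, ALPHA[, i] * MSG[, cols, drop = FALSE], cols)
      }
      cache$tts[[tt]] <- list(BASE = BASE, MU = mu_e, ALPHA = ALPHA, MSG = MSG)
    } else {
      Ht <- matrix(0, n_tt, d)
      cache$tts[[tt]] <- list()
    }
    Z <- lin_fwd(Ht, lp$par$a[[tt]])
    out[[tt]] <- actf$f(Z) + H[[tt]]
    cache$tts[[tt]]$Ht <- Ht
    cache$tts[[tt]]$Z <- Z
  }
  list(H = out, cache = cache)
}

#' Per-edge multi-head attention coefficients
#'
#' For every target node the weights over its in-neighbours are a per-head
#' softmax of the meta-relation-scaled bilinear key/query scores
#' \eqn{(K_i(s)\, W^{att}_{\phi(e)}\, Q_i(t)^\top)\,\mu / \sqrt{d_{head}}},
#' so each head's weights over a target's in-neighbours sum to one.
#'
#' @param g a `hetero_graph` (or `compute_view`).
#' @param h_prev named list of per-type state matrices (width `d_model`).
#' @param lp an [hgt_layer_params()] bank.
#' @return named list per target type: `edges` (data.frame `src_type`,
#'   `relation`, `src`, `dst`) aligned with `weights` (edges x heads matrix).
#' @export
hgt_attention <- function(g, h_prev, lp) {
  view <- if (inherits(g, "compute_view")) g else build_compute_view(g)
  fw <- hgt_layer_forward(view, h_prev, lp)
  out <- list()
  for (tt in view$types) {
    ib <- view$inbox[[tt]]
    if (ib$E == 0L) next
    out[[tt]] <- list(edges = inbox_edges(view, tt),
                      weights = fw$cache$tts[[tt]]$ALPHA)
  }
  out
}

#' Per-edge message vectors
#'
#' Head `i`'s message for edge (s, t) is the source state passed through the
#' source-type message linear and the relation's message matrix; heads are
#' concatenated to width `d_model`.
#'
#' @inheritParams hgt_attention
#' @return named list per target type: `edges` plus `messages`
#'   (edges x `d_model` matrix).
#' @export
hgt_messages <- function(g, h_prev, lp) {
  view <- if (inherits(g, "compute_view")) g else build_compute_view(g)
  fw <- hgt_layer_forward(view, h_prev, lp)
  out <- list()
  for (tt in view$types) {
    ib <- view$inbox[[tt]]
    if (ib$E == 0L) next
    out[[tt]] <- list(edges = inbox_edges(view, tt),
                      messages = fw$cache$tts[[tt]]$MSG)
  }
  out
}

inbox_edges <- function(view, tt) {
  ib <- view$inbox[[tt]]
  g <- view$graph
  do.call(rbind, lapply(ib$segs, function(seg) data.frame(
    src_type = seg$src_type, relation = seg$key,
    src = g$nodes[[seg$src_type]][seg$src_idx],
    dst = g$nodes[[tt]][seg$dst_idx], stringsAsFactors = FALSE)))
}

#' Attention-weighted aggregation with residual update
#'
#' Sums each target's incoming messages weighted per head by the attention
#' coefficients, maps the sum through the target-type aggregation linear and
#' the activation, and adds the previous state (residual). Targets with no
#' in-neighbours receive `activation(A_linear(0)) + previous state`.
#'
#' @param weights output of [hgt_attention()].
#' @param msgs output of [hgt_messages()] (same graph and states).
#' @param h_prev named list of per-type state matrices.
#' @param lp an [hgt_layer_params()] bank.
#' @param g the `hetero_graph` the weights/messages came from.
#' @return updated named list of per-type state matrices.
#' @export
hgt_aggregate <- function(weights, msgs, h_prev, lp, g) {
  view <- if (inherits(g, "compute_view")) g else build_compute_view(g)
  d <- lp$d_model; dh <- lp$d_head
  actf <- activation_fns(lp$activation)
  out <- h_prev
  for (tt in view$types) {
    ib <- view$inbox[[tt]]
    Ht <- matrix(0, view$n[[tt]], d)
    if (ib$E > 0L) {
      AL <- weights[[tt]]$weights; MS <- msgs[[tt]]$messages
      for (i in seq_len(lp$h)) {
        cols <- hcols(i, dh)
        Ht <- scatter_add(Ht, ib$dst_all, AL[, i] * MS[, cols, drop = FALSE], cols)
      }
    }
    out[[tt]] <- actf$f(lin_fwd(Ht, lp$par$a[[tt]])) + h_prev[[tt]]
  }
  out
}

#' Project heterogeneous initial embeddings into the model width
#'
#' Per-type linear to `d_model`, ReLU, then dropout (training mode only).
#'
#' @param h_init named list of per-type initial embedding matrices.
#' @param enc an [encoder_params()] object.
#' @param mode `"train"` (dropout on, drawn from the current RNG stream) or
#'   `"eval"`.
#' @return named list of per-type `d_model`-wide state matrices.
#' @export
project_input <- function(h_init, enc, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  project_input_cached(h_init, enc, mode)$H
}

project_input_cached <- function(h_init, enc, mode) {
  H <- list(); cache <- list()
  p <- enc$cfg$dropout_in
  for (ty in names(h_init)) {
    lin <- enc$inp[[ty]]
    if (is.null(lin))
      stop_hgt("no input projection for node type '%s'", ty, class = "hgt_shape_error")
    if (ncol(h_init[[ty]]) != nrow(lin$W))
      stop_hgt("input dim mismatch for type '%s': got %d, expected %d",
               ty, ncol(h_init[[ty]]), nrow(lin$W), class = "hgt_shape_error")
    Z <- lin_fwd(h_init[[ty]], lin)
    A <- pmax(Z, 0)
    if (mode == "train" && p > 0) {
      mask <- matrix(stats::rbinom(length(A), 1, 1 - p) / (1 - p),
                     nrow(A), ncol(A))
      H[[ty]] <- A * mask
      cache[[ty]] <- list(Z = Z, mask = mask)
    } else {
      H[[ty]] <- A
      cache[[ty]] <- list(Z = Z, mask = NULL)
    }
  }
  list(H = H, cache = cache)
}

#' Encode a (sub)graph into node features
#'
#' Runs the input projection, `n_layers` attention layers, concatenates the
#' per-layer outputs and maps them through a final linear + ReLU back to
#' `d_model`. Deterministic in eval mode.
#'
#' @param g a `hetero_graph` or `compute_view`.
#' @param h_init named list of per-type initial embedding matrices (rows in
#'   graph node order).
#' @param enc an [encoder_params()] object.
#' @param mode `"eval"` (default, deterministic) or `"train"` (dropout).
#' @return named list of per-type feature matrices, width `d_model`.
#' @export
encode <- function(g, h_init, enc, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  view <- if (inherits(g, "compute_view")) g else build_compute_view(g)
  encode_cached(view, h_init, enc, mode)$Feat
}

encode_cached <- function(view, h_init, enc, mode) {
  L <- enc$cfg$n_layers
  proj <- project_input_cached(h_init, enc, mode)
  H <- proj$H
  layer_caches <- vector("list", L)
  Hs <- vector("list", L)
  for (l in seq_len(L)) {
    fw <- hgt_layer_forward(view, H, enc$layers[[l]])
    H <- fw$H
    layer_caches[[l]] <- fw$cache
    Hs[[l]] <- H
  }
  Feat <- list(); head_cache <- list()
  for (ty in view$types) {
    CC <- do.call(cbind, lapply(Hs, `[[`, ty))
    lin <- if (enc$cfg$head_shared) enc$head else enc$head[[ty]]
    Zf <- lin_fwd(CC, lin)
    Feat[[ty]] <- pmax(Zf, 0)
    head_cache[[ty]] <- list(CC = CC, Zf = Zf)
  }
  list(Feat = Feat, proj = proj, layers = layer_caches, head = head_cache,
       h_init = h_init)
}
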