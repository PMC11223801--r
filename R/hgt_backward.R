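# Reverse-mode gradients for the encoder, derived by hand from the forward
# equations. Each *_backward mirrors its forward twin and returns gradients
# in the same nested structure as the parameter banks, so the optimiser can
# walk parameters and gradients in lockstep.

tree_zeros <- function(x) if (is.list(x)) lapply(x, tree_zeros) else x * 0

tree_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

# Backward through one attention layer.
# dH_out: gradient of the loss wrt the layer's output states.
# Returns dH (gradient wrt the layer's input states) and grads mirroring
# lp$par.
hgt_layer_backward <- function(view, cache, dH_out, lp) {
  d <- lp$d_model; h <- lp$h; dh <- lp$d_head
  actg <- activation_fns(lp$activation)$g
  gr <- tree_zeros(lp$par)
  KQM <- cache$KQM
  dK <- lapply(view$types, function(ty) matrix(0, view$n[[ty]], d))
  names(dK) <- view$types
  dQ <- dK; dM <- dK
  dH <- dH_out  # residual path
  for (tt in view$types) {
    cc <- cache$tts[[tt]]
    ib <- view$inbox[[tt]]
    dZ <- dH_out[[tt]] * actg(cc$Z)
    gr$a[[tt]]$W <- gr$a[[tt]]$W + crossprod(cc$Ht, dZ)
    gr$a[[tt]]$b <- gr$a[[tt]]$b + colSums(dZ)
    if (ib$E == 0L) next
    dHt <- dZ %*% t(lp$par$a[[tt]]$W)
    ALPHA <- cc$ALPHA; MSG <- cc$MSG
    dMSG <- matrix(0, ib$E, d); dS <- matrix(0, ib$E, h)
    for (i in seq_len(h)) {
      cols <- hcols(i, dh)
      dHt_e <- dHt[ib$dst_all, cols, drop = FALSE]
      dal <- rowSums(dHt_e * MSG[, cols, drop = FALSE])
      dMSG[, cols] <- ALPHA[, i] * dHt_e
      gsum <- rowsum(ALPHA[, i] * dal, ib$gidx)[, 1]
      dS[, i] <- ALPHA[, i] * (dal - gsum[ib$gidx])
    }
    dBASE <- dS * cc$MU
    off <- 0L
    for (seg in ib$segs) {
      rows <- off + seq_len(seg$n)
      gr$mu[[seg$key]] <- gr$mu[[seg$key]] +
        sum(dS[rows, , drop = FALSE] * cc$BASE[rows, , drop = FALSE])
      Ksrc <- KQM[[seg$src_type]]$K[seg$src_idx, , drop = FALSE]
      Msrc <- KQM[[seg$src_type]]$M[seg$src_idx, , drop = FALSE]
      Qdst <- KQM[[tt]]$Q[seg$dst_idx, , drop = FALSE]
      for (i in seq_len(h)) {
        cols <- hcols(i, dh)
        att_i <- lp$par$att[[seg$key]][, , i]
        msg_i <- lp$par$msg[[seg$key]][, , i]
        Kh <- Ksrc[, cols, drop = FALSE]; Qh <- Qdst[, cols, drop = FALSE]
        P <- Kh %*% att_i
        db <- dBASE[rows, i] / sqrt(dh)
        dP <- db * Qh
        gr$att[[seg$key]][, , i] <- gr$att[[seg$key]][, , i] + crossprod(Kh, dP)
        dK[[seg$src_type]] <- scatter_add(dK[[seg$src_type]], seg$src_idx,
                                          dP %*% t(att_i), cols)
        dQ[[tt]] <- scatter_add(dQ[[tt]], seg$dst_idx, db * P, cols)
        dm <- dMSG[rows, cols, drop = FALSE]
        gr$msg[[seg$key]][, , i] <- gr$msg[[seg$key]][, , i] +
          crossprod(Msrc[, cols, drop = FALSE], dm)
        dM[[seg$src_type]] <- scatter_add(dM[[seg$src_type]], seg$src_idx,
                                          dm %*% t(msg_i), cols)
      }
      off <- off + seg$n
    }
  }
  for (ty in view$types) {
    Hty <- cache$H[[ty]]
    gr$k[[ty]]$W <- gr$k[[ty]]$W + crossprod(Hty, dK[[ty]])
    gr$k[[ty]]$b <- gr$k[[ty]]$b + colSums(dK[[ty]])
    gr$q[[ty]]$W <- gr$q[[ty]]$W + crossprod(Hty, dQ[[ty]])
    gr$q[[ty]]$b <- gr$q[[ty]]$b + colSums(dQ[[ty]])
    gr$m[[ty]]$W <- gr$m[[ty]]$W + crossprod(Hty, dM[[ty]])
    gr$m[[ty]]$b <- gr$m[[ty]]$b + colSums(dM[[ty]])
    dH[[ty]] <- dH[[ty]] + dK[[ty]] %*% t(lp$par$k[[ty]]$W) +
      dQ[[ty]] %*% t(lp$par$q[[ty]]$W) + dM[[ty]] %*% t(lp$par$m[[ty]]$W)
  }
  list(dH = dH, grads = gr)
}

# Backward through the whole encoder given dFeat (per-type gradient of the
# loss wrt the encoded features). Returns gradients for every encoder
# parameter (input projections, layer banks, concatenation head).
encode_backward <- function(view, cache, dFeat, enc) {
  L <- enc$cfg$n_layers
  d <- enc$cfg$d_model
  gr <- list(inp = tree_zeros(enc$inp),
             layers = lapply(enc$layers, function(lp) tree_zeros(lp$par)),
             head = tree_zeros(enc$head))
  # per-layer accumulated output gradients from the concat head
  dHs <- lapply(seq_len(L), function(l)
    lapply(view$types, function(ty) matrix(0, view$n[[ty]], d)))
  for (l in seq_len(L)) names(dHs[[l]]) <- view$types
  for (ty in view$types) {
    hc <- cache$head[[ty]]
    dF <- dFeat[[ty]]
    if (is.null(dF)) next
    dZf <- dF * (hc$Zf > 0)
    lin <- if (enc$cfg$head_shared) enc$head else enc$head[[ty]]
    gW <- crossprod(hc$CC, dZf); gb <- colSums(dZf)
    if (enc$cfg$head_shared) {
      gr$head$W <- gr$head$W + gW; gr$head$b <- gr$head$b + gb
    } else {
      gr$head[[ty]]$W <- gr$head[[ty]]$W + gW
      gr$head[[ty]]$b <- gr$head[[ty]]$b + gb
    }
    dCC <- dZf %*% t(lin$W)
    for (l in seq_len(L))
      dHs[[l]][[ty]] <- dHs[[l]][[ty]] + dCC[, (l - 1L) * d + seq_len(d), drop = FALSE]
  }
  carry <- dHs[[L]]
  for (l in rev(seq_len(L))) {
    bw <- hgt_layer_backward(view, cache$layers[[l]], carry, enc$layers[[l]])
    gr$layers[[l]] <- tree_add(gr$layers[[l]], bw$grads)
    carry <- bw$dH
    if (l > 1L) for (ty in view$types)
      carry[[ty]] <- carry[[ty]] + dHs[[l - 1L]][[ty]]
  }
  # input projection backward
  for (ty in view$types) {
    pc <- cache$proj$cache[[ty]]
    dA <- carry[[ty]]
    if (!is.null(pc$mask)) dA <- dA * pc$mask
    dZ <- dA * (pc$Z > 0)
    gr$inp[[ty]]$W <- gr$inp[[ty]]$W + crossprod(cache$h_init[[ty]], dZ)
    gr$inp[[ty]]$b <- gr$inp[[ty]]$b + colSums(dZ)
  }
  gr
}
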