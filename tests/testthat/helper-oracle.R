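# Independent dense brute-force implementation of one attention layer:
# explicit per-node, per-edge loops straight from the update equations, kept
# deliberately separate from the package's vectorised path.

oracle_hgt_layer <- function(g, H, lp) {
  types <- node_types(g)
  d <- lp$d_model; dh <- lp$d_head; h <- lp$h
  act <- if (lp$activation == "gelu") function(x) x * stats::pnorm(x)
    else function(x) pmax(x, 0)
  lin <- function(x, l) as.numeric(x %*% l$W + l$b)
  out <- H
  for (tt in types) {
    res <- H[[tt]]
    for (t in seq_along(g$nodes[[tt]])) {
      tid <- g$nodes[[tt]][t]
      inc <- list()
      for (key in names(g$relations)) {
        r <- g$relations[[key]]
        if (r$dst_type != tt) next
        for (e in seq_along(r$src)) if (r$dst[e] == tid)
          inc[[length(inc) + 1L]] <- list(key = key, s_type = r$src_type,
                                          s = match(r$src[e], g$nodes[[r$src_type]]))
      }
      Htil <- numeric(d)
      if (length(inc)) {
        for (i in seq_len(h)) {
          cols <- ((i - 1L) * dh + 1L):(i * dh)
          Qt <- lin(H[[tt]][t, , drop = FALSE], lp$par$q[[tt]])[cols]
          scores <- vapply(inc, function(ed) {
            Ks <- lin(H[[ed$s_type]][ed$s, , drop = FALSE], lp$par$k[[ed$s_type]])[cols]
            as.numeric(Ks %*% lp$par$att[[ed$key]][, , i] %*% Qt) *
              lp$par$mu[[ed$key]] / sqrt(dh)
          }, numeric(1))
          al <- exp(scores - max(scores)); al <- al / sum(al)
          for (jj in seq_along(inc)) {
            ed <- inc[[jj]]
            Ms <- lin(H[[ed$s_type]][ed$s, , drop = FALSE], lp$par$m[[ed$s_type]])[cols]
            Htil[cols] <- Htil[cols] + al[jj] * as.numeric(Ms %*% lp$par$msg[[ed$key]][, , i])
          }
        }
      }
      res[t, ] <- act(lin(matrix(Htil, 1), lp$par$a[[tt]])) + H[[tt]][t, ]
    }
    out[[tt]] <- res
  }
  out
}
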