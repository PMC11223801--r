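# Seeded generator of small heterogeneous knowledge graphs with planted
# indication structure. Drugs, diseases and proteins carry latent classes;
# the target (indication) relation links within-class pairs with probability
# p_in and across classes with p_out, and the auxiliary relations
# (drug-protein, disease-protein, protein-protein) are correlated with the
# same classes so that graph context is informative about held-out links.

#' Specification of a synthetic knowledge graph
#'
#' @param n_drug,n_disease,n_protein,n_pathway node counts. Defaults
#'   100/80/200/30.
#' @param n_classes number of latent classes B (assigned round-robin, so
#'   class sizes are balanced and expectations are exact). Default 4.
#' @param p_in,p_out indication probability for class-matched / mismatched
#'   drug-disease pairs. Defaults 0.30 / 0.01.
#' @param p_drug_protein,p_disease_protein in/out probability pairs (length-2
#'   numeric) for the class-correlated auxiliary relations.
#' @param p_protein_protein in/out probabilities for protein-protein links.
#' @param p_pathway class-agnostic protein-pathway density; this relation
#'   carries no planted signal and serves as a pure-noise ablation target.
#' @param degree_exponent Pareto tail exponent of the per-node degree
#'   propensities (heavy-tailed degrees, emulating blockbuster drugs and
#'   common diseases); `0` disables heterogeneity. Propensities multiply the
#'   block probabilities of every relation, target included, and are shared
#'   across relations, so a node's activity is consistent graph-wide.
#'   Expected edge counts stay closed-form via the returned probability
#'   matrix. Default 2.
#' @param propensity_cap upper bound on a propensity (before rescaling to
#'   mean one). Default 5.
#' @param holdout_fraction fraction of drawn indication edges withheld from
#'   the graph as ground-truth positives for recovery tests. Default 0.1.
#' @param embed_dim initial embedding width (all types). Default 16.
#' @param embed_mode `"informative"` (scaled one-hot of the latent class plus
#'   Gaussian noise) or `"noise"` (pure noise ablation).
#' @param embed_noise_sd noise standard deviation. Default 0.5.
#' @param rng_seed integer seed; the same spec and seed give an identical
#'   graph.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_drug = 100L, n_disease = 80L, n_protein = 200L,
                       n_pathway = 30L, n_classes = 4L,
                       p_in = 0.30, p_out = 0.01,
                       p_drug_protein = c(0.20, 0.01),
                       p_disease_protein = c(0.15, 0.01),
                       p_protein_protein = c(0.05, 0.005),
                       p_pathway = 0.02,
                       degree_exponent = 2, propensity_cap = 5,
                       holdout_fraction = 0.1,
                       embed_dim = 16L,
                       embed_mode = c("informative", "noise"),
                       embed_noise_sd = 0.5, rng_seed = 1L) {
  embed_mode <- match.arg(embed_mode)
  probs <- c(p_in, p_out, p_drug_protein, p_disease_protein,
             p_protein_protein, p_pathway)
  if (any(probs < 0 | probs > 1))
    stop_hgt("all link probabilities must lie in [0,1]", class = "hgt_spec_error")
  if (any(c(n_drug, n_disease, n_protein, n_classes) < 1L))
    stop_hgt("node and class counts must be positive", class = "hgt_spec_error")
  structure(as.list(environment())[c(
    "n_drug", "n_disease", "n_protein", "n_pathway", "n_classes",
    "p_in", "p_out", "p_drug_protein", "p_disease_protein",
    "p_protein_protein", "p_pathway", "degree_exponent", "propensity_cap",
    "holdout_fraction", "embed_dim", "embed_mode", "embed_noise_sd",
    "rng_seed")], class = "synth_spec")
}

synth_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

# per-node multiplicative propensities: capped Pareto, rescaled to mean 1
synth_propensities <- function(n, exponent, cap, seed) {
  if (exponent <= 0) return(rep(1, n))
  w <- with_seed(seed, (1 - stats::runif(n))^(-1 / exponent))
  w <- pmin(w, cap)
  w / mean(w)
}

# Bernoulli bipartite block: classes ca (rows), cb (cols); returns index pairs
draw_block_edges <- function(ca, cb, p_in, p_out, seed, wa = NULL, wb = NULL,
                             symmetric = FALSE) {
  P <- matrix(p_out, length(ca), length(cb))
  P[outer(ca, cb, `==`)] <- p_in
  if (!is.null(wa)) P <- P * outer(wa, wb)
  P <- pmin(P, 1)
  if (symmetric) P[lower.tri(P, diag = TRUE)] <- 0
  hit <- with_seed(seed, matrix(stats::runif(length(P)), nrow(P)) < P)
  idx <- which(hit, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2], prob = P)
}

#' Generate a synthetic knowledge graph with planted indications
#'
#' Draws the target relation from the latent-class block model, the
#' class-correlated auxiliary relations, per-type initial embeddings, and
#' withholds `holdout_fraction` of the drawn indication edges as ground
#' truth. Fully reproducible from the spec.
#'
#' @param spec a [synth_spec()].
#' @return list with `graph` (a `hetero_graph`), `truth` (held-out positive
#'   pairs, data.frame `drug`/`disease`), `embeddings` (named list of
#'   `embedding_table`), `classes` (named list of per-type latent class
#'   vectors), `prob_target` (the exact drug x disease link probability
#'   matrix, for expectation checks), and `spec`.
#' @export
generate_synthetic_kg <- function(spec = synth_spec()) {
  s <- spec
  if (!inherits(s, "synth_spec"))
    stop_hgt("spec must be a synth_spec()", class = "hgt_spec_error")
  # expected target edges may not exceed the number of distinct pairs
  n_pairs <- s$n_drug * s$n_disease
  exp_edges <- sum(outer(rep_len(seq_len(s$n_classes), s$n_drug),
                         rep_len(seq_len(s$n_classes), s$n_disease), `==`) *
                     (s$p_in - s$p_out)) + n_pairs * s$p_out
  if (exp_edges > n_pairs)
    stop_hgt("infeasible spec: expected target edges (%.0f) exceed possible pairs (%d)",
             exp_edges, n_pairs, class = "hgt_spec_error")
  ids <- list(drug = synth_ids("DR", s$n_drug),
              disease = synth_ids("DI", s$n_disease),
              protein = synth_ids("PR", s$n_protein),
              pathway = synth_ids("PW", max(s$n_pathway, 0L)))
  if (s$n_pathway == 0L) ids$pathway <- NULL
  cls <- list(drug = rep_len(seq_len(s$n_classes), s$n_drug),
              disease = rep_len(seq_len(s$n_classes), s$n_disease),
              protein = rep_len(seq_len(s$n_classes), s$n_protein))
  wp <- list(drug = synth_propensities(s$n_drug, s$degree_exponent, s$propensity_cap,
                                       derive_seed(s$rng_seed, "prop/drug")),
             disease = synth_propensities(s$n_disease, s$degree_exponent, s$propensity_cap,
                                          derive_seed(s$rng_seed, "prop/disease")),
             protein = synth_propensities(s$n_protein, s$degree_exponent, s$propensity_cap,
                                          derive_seed(s$rng_seed, "prop/protein")))

  tgt <- draw_block_edges(cls$drug, cls$disease, s$p_in, s$p_out,
                          derive_seed(s$rng_seed, "edges/indication"),
                          wa = wp$drug, wb = wp$disease)
  n_t <- length(tgt$i)
  n_hold <- round_half_away(s$holdout_fraction * n_t)
  hold_idx <- with_seed(derive_seed(s$rng_seed, "holdout"),
                        sample.int(n_t, n_hold))
  keep <- setdiff(seq_len(n_t), hold_idx)
  truth <- data.frame(drug = ids$drug[tgt$i[hold_idx]],
                      disease = ids$disease[tgt$j[hold_idx]],
                      stringsAsFactors = FALSE)

  dp <- draw_block_edges(cls$drug, cls$protein,
                         s$p_drug_protein[1], s$p_drug_protein[2],
                         derive_seed(s$rng_seed, "edges/drug_protein"),
                         wa = wp$drug, wb = wp$protein)
  sp <- draw_block_edges(cls$disease, cls$protein,
                         s$p_disease_protein[1], s$p_disease_protein[2],
                         derive_seed(s$rng_seed, "edges/disease_protein"),
                         wa = wp$disease, wb = wp$protein)
  pp <- draw_block_edges(cls$protein, cls$protein,
                         s$p_protein_protein[1], s$p_protein_protein[2],
                         derive_seed(s$rng_seed, "edges/protein_protein"),
                         wa = wp$protein, wb = wp$protein, symmetric = TRUE)
  relations <- list(
    indication = list(relation = "indication", src_type = "drug",
                      dst_type = "disease",
                      src = ids$drug[tgt$i[keep]], dst = ids$disease[tgt$j[keep]]),
    drug_protein = list(relation = "drug_protein", src_type = "drug",
                        dst_type = "protein",
                        src = ids$drug[dp$i], dst = ids$protein[dp$j]),
    disease_protein = list(relation = "disease_protein", src_type = "disease",
                           dst_type = "protein",
                           src = ids$disease[sp$i], dst = ids$protein[sp$j]),
    protein_protein = list(relation = "protein_protein", src_type = "protein",
                           dst_type = "protein",
                           src = ids$protein[pp$i], dst = ids$protein[pp$j]))
  if (!is.null(ids$pathway)) {
    pw <- draw_block_edges(rep(0L, s$n_protein), rep(1L, s$n_pathway),
                           0, s$p_pathway,
                           derive_seed(s$rng_seed, "edges/pathway"))
    relations$protein_pathway <- list(relation = "protein_pathway",
                                      src_type = "protein", dst_type = "pathway",
                                      src = ids$protein[pw$i], dst = ids$pathway[pw$j])
  }
  g <- hetero_graph(ids, relations)

  emb <- list()
  for (ty in names(ids)) {
    n <- length(ids[[ty]])
    m <- with_seed(derive_seed(s$rng_seed, paste0("embed/", ty)),
                   matrix(stats::rnorm(n * s$embed_dim, sd = s$embed_noise_sd),
                          n, s$embed_dim))
    if (s$embed_mode == "informative" && !is.null(cls[[ty]])) {
      for (b in seq_len(min(s$n_classes, s$embed_dim)))
        m[cls[[ty]] == b, b] <- m[cls[[ty]] == b, b] + 1
    }
    rownames(m) <- ids[[ty]]
    emb[[ty]] <- embedding_table(ty, m)
  }
  list(graph = g, truth = truth, embeddings = emb, classes = cls,
       prob_target = tgt$prob, spec = s)
}

# Table of the 30 PrimeKG relation labels with their endpoint types.
primekg_schema <- function() {
  txt <- c(
    "anatomy_protein_present|anatomy|protein",
    "anatomy_protein_absent|anatomy|protein",
    "drug_drug|drug|drug",
    "protein_protein|protein|protein",
    "disease_phenotype_positive|disease|phenotype",
    "disease_phenotype_negative|disease|phenotype",
    "bioprocess_protein|biological_process|protein",
    "cellcomp_protein|cellular_component|protein",
    "disease_protein|disease|protein",
    "molfunc_protein|molecular_function|protein",
    "drug_phenotype|drug|phenotype",
    "bioprocess_bioprocess|biological_process|biological_process",
    "pathway_protein|pathway|protein",
    "disease_disease|disease|disease",
    "contraindication|drug|disease",
    "drug_protein|drug|protein",
    "phenotype_phenotype|phenotype|phenotype",
    "anatomy_anatomy|anatomy|anatomy",
    "molfunc_molfunc|molecular_function|molecular_function",
    "indication|drug|disease",
    "cellcomp_cellcomp|cellular_component|cellular_component",
    "phenotype_protein|phenotype|protein",
    "off_label_use|drug|disease",
    "pathway_pathway|pathway|pathway",
    "exposure_disease|exposure|disease",
    "exposure_exposure|exposure|exposure",
    "exposure_bioprocess|exposure|biological_process",
    "exposure_protein|exposure|protein",
    "exposure_molfunc|exposure|molecular_function",
    "exposure_cellcomp|exposure|cellular_component")
  parts <- strsplit(txt, "|", fixed = TRUE)
  data.frame(relation = vapply(parts, `[`, "", 1),
             src_type = vapply(parts, `[`, "", 2),
             dst_type = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Miniature graph with the PrimeKG schema
#'
#' A small random graph carrying the 10 node types and 30 relation labels of
#' the PrimeKG knowledge graph, for schema, round-trip and filtering tests.
#' A controlled subset of drugs and diseases is constructed with zero
#' indication edges (returned in the attributes `unindicated_drugs` /
#' `unindicated_diseases`) so node-filtering behaviour is verifiable by
#' construction.
#'
#' @param n_per_type nodes per type. Default 20.
#' @param edges_per_relation directed edges drawn per relation. Default 30.
#' @param unindicated_fraction fraction of drugs/diseases kept out of every
#'   indication edge. Default 0.3.
#' @param rng_seed integer seed.
#' @return a `hetero_graph` (synthetic; schema mimic only, no biological
#'   meaning).
#' @export
primekg_miniature <- function(n_per_type = 20L, edges_per_relation = 30L,
                              unindicated_fraction = 0.3, rng_seed = 1L) {
  sch <- primekg_schema()
  types <- unique(c(sch$src_type, sch$dst_type))
  ids <- lapply(types, function(ty) sprintf("%s_%03d", toupper(substr(ty, 1, 3)), 1:n_per_type))
  names(ids) <- types
  n_un <- max(1L, floor(unindicated_fraction * n_per_type))
  un_drug <- ids$drug[seq_len(n_un)]
  un_disease <- ids$disease[seq_len(n_un)]
  relations <- list()
  with_seed(rng_seed, {
    for (r in seq_len(nrow(sch))) {
      st <- sch$src_type[r]; dt <- sch$dst_type[r]
      src_pool <- ids[[st]]; dst_pool <- ids[[dt]]
      if (sch$relation[r] == "indication") {
        src_pool <- setdiff(src_pool, un_drug)
        dst_pool <- setdiff(dst_pool, un_disease)
      }
      src <- sample(src_pool, edges_per_relation, replace = TRUE)
      dst <- sample(dst_pool, edges_per_relation, replace = TRUE)
      keep <- !(st == dt & src == dst)
      keep <- keep & !duplicated(pair_key(paste(sch$relation[r], src), dst))
      relations[[sch$relation[r]]] <-
        list(relation = sch$relation[r], src_type = st, dst_type = dt,
             src = src[keep], dst = dst[keep])
    }
  })
  g <- hetero_graph(ids, relations)
  attr(g, "unindicated_drugs") <- un_drug
  attr(g, "unindicated_diseases") <- un_disease
  g
}

#' Write a synthetic knowledge graph to a run directory
#'
#' Emits the PrimeKG-dialect edge CSV, one embedding CSV per node type and
#' the held-out truth table, so the full command-line pipeline can run on
#' generated data unchanged.
#'
#' @param sim output of [generate_synthetic_kg()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_synthetic_kg <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_table(sim$graph, file.path(dir, "edges.csv"))
  for (ty in names(sim$embeddings))
    write_embedding_file(sim$embeddings[[ty]],
                         file.path(dir, paste0("embeddings_", ty, ".csv")))
  data.table::fwrite(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
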