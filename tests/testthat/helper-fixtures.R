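# Small in-code fixtures shared across test files.

tiny_compounds <- function() {
  data.frame(
    compound_id = c("c1", "c2", "c3"),
    smiles = c("c1ccccc1O", "CCOc1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
    ob = c(35, 30, 25), dl = c(0.20, 0.18, 0.50),
    admet_as = c(2, 3, 1), admet_bbb = c(1, 2, 3), admet_cyp2d6 = c(0, 1, 0),
    admet_hepatotox = c(1, 0, 1), admet_ppb = c(2, 2, 1),
    stringsAsFactors = FALSE)
}

tiny_sequences <- function() {
  data.frame(
    target_id = rep(c("T1", "T2"), 2),
    variant = rep(c("full", "motif"), each = 2),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "GIGAVLKVLTTGLPALISWIKRKRQQ",
                 "AYIAKQRQISFVK", "VLTTGLPALISW"),
    stringsAsFactors = FALSE)
}

# One-of-everything chain: one compound docks one target, the target sits in
# one pathway, the pathway links one disease.
tiny_chain_tables <- function(s_i = 45, s_m = 50, combined = NULL) {
  list(
    compounds = data.frame(compound_id = "c1", smiles = NA, ob = 40, dl = 0.3,
                           stringsAsFactors = FALSE),
    docking = data.frame(compound_id = "c1", target_id = "T1",
                         s_i = s_i, s_m = s_m, success = TRUE,
                         stringsAsFactors = FALSE),
    ppi = data.frame(target_a = character(), target_b = character(),
                     combined_score = numeric(), stringsAsFactors = FALSE),
    pathways = data.frame(pathway_id = "P1", name = "p", p_value = 1e-10,
                          q_value = 1e-9, member_targets = "T1",
                          diseases = "D1", stringsAsFactors = FALSE))
}

build_tiny_network <- function(...) {
  tb <- tiny_chain_tables(...)
  build_network(tb$compounds, tb$docking, tb$ppi, tb$pathways)
}

# Independent single-source Dijkstra used as the shortest-path oracle.
dijkstra_oracle <- function(A, src) {
  n <- nrow(A)
  dist <- rep(Inf, n); dist[src] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (v in seq_len(n)) {
      if (!done[v] && is.finite(A[u, v]) && dist[u] + A[u, v] < dist[v]) {
        dist[v] <- dist[u] + A[u, v]
      }
    }
  }
  dist
}

# Random symmetric weighted adjacency with weights in (0.5, 1).
random_adjacency <- function(n, p_edge = 0.4) {
  A <- matrix(Inf, n, n)
  diag(A) <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p_edge) {
        w <- stats::runif(1, 0.5, 1)
        A[i, j] <- w; A[j, i] <- w
      }
    }
  }
  dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
  A
}

# Brute-force AUC: fraction of positive-negative pairs correctly ordered,
# ties counting 1/2.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
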