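# Weighted compound-target-pathway-disease network (CTPDN).
#
# Raw edge scores S are turned into lengths L = 1/S (absent interactions are
# +Inf), lengths into weights W = 1/(1 + exp(-L)) with the single exception
# that pathway-disease edges carry W = 1 exactly. Compounds are then valued
# by the Floyd-Warshall shortest weighted path from each compound node to
# each disease node, averaging over diseases.

#' Docking-score ratio for a compound-target edge
#'
#' Raw compound-target interaction score `S = s_i / s_m`: the docking
#' interaction score of the candidate compound relative to the score of the
#' reference (native) ligand on the same target. `S > 1` means the candidate
#' binds more strongly than the reference.
#'
#' @param s_i candidate docking interaction score (sign-flipped CDOCKER-style
#'   interaction energy; larger is stronger binding).
#' @param s_m reference-ligand score on the same scale; must be positive.
#' @return numeric ratio(s) `S`.
#' @export
cti_score <- function(s_i, s_m) {
  if (any(!is.finite(s_i))) stop("s_i must be finite")
  if (any(!(s_m > 0))) stop("invalid reference score: s_m must be > 0")
  s_i / s_m
}

#' Edge length from a raw score
#'
#' `L = 1/S` for interacting pairs; `+Inf` when the two nodes do not
#' interact (for example a failed docking).
#'
#' @param S raw score (docking ratio, PPI combined score, or membership 1).
#' @param interacts logical; `FALSE` yields `+Inf`.
#' @return numeric length(s).
#' @export
edge_length <- function(S, interacts = TRUE) {
  interacts <- rep_len(interacts, length(S))
  if (any(interacts & !(S > 0))) {
    stop("edge_length: interacting edges need S > 0")
  }
  ifelse(interacts, 1 / S, Inf)
}

#' Normalized edge weight
#'
#' Pathway-disease edges are pinned at weight 1; every other edge type is
#' squashed through the logistic `W = 1/(1 + exp(-L))`, which maps any
#' finite positive length into (0.5, 1). An infinite length on a non-PDI
#' edge stays `+Inf` (the edge is absent from the adjacency matrix).
#'
#' @param L edge length(s) from [edge_length()].
#' @param edge_type one of `"CTI"`, `"TTI"`, `"TPI"`, `"PDI"` (recycled).
#' @param sigmoid_sign `"positive"` (literal form) or `"negative"`
#'   (`1/(1 + exp(L))`), kept as an explicit switch because the two
#'   conventions order paths differently.
#' @return numeric weight(s) in (0.5, 1), exactly 1 for PDI, `+Inf` for
#'   absent non-PDI edges.
#' @export
edge_weight <- function(L, edge_type = "CTI",
                        sigmoid_sign = c("positive", "negative")) {
  sigmoid_sign <- match.arg(sigmoid_sign)
  edge_type <- rep_len(edge_type, length(L))
  if (any(!(L > 0) & edge_type != "PDI")) {
    stop("edge_weight: non-PDI edges need L > 0")
  }
  w <- if (sigmoid_sign == "positive") 1 / (1 + exp(-L)) else 1 / (1 + exp(L))
  w[is.infinite(L)] <- Inf
  w[edge_type == "PDI"] <- 1
  w
}

.EDGE_TYPES <- c(CTI = "CTI", TTI = "TTI", TPI = "TPI", PDI = "PDI")

#' Build the weighted compound-target-pathway-disease network
#'
#' Assembles typed nodes and weighted typed edges into a symmetric adjacency
#' matrix: diagonal 0, absent pairs `+Inf`, present pairs the normalized
#' weight from [edge_weight()]. Compound-target edges come from successful
#' docking records via the score ratio; target-target edges from the PPI
#' combined score; target-pathway edges from pathway membership (score 1, or
#' `-log10(q)` clipped to `[1e-3, 1e3]` under `tpi_mode = "qweight"`);
#' pathway-disease edges from the pathway's disease links (weight pinned
#' at 1). Duplicate records for a pair keep the strongest raw score with a
#' warning; edges naming undeclared nodes are an error.
#'
#' @param compounds compound table (`compound_id`, ...).
#' @param docking docking table (`compound_id`, `target_id`, `s_i`, `s_m`,
#'   `success`).
#' @param ppi PPI table (`target_a`, `target_b`, `combined_score`).
#' @param pathways pathway table (`pathway_id`, `member_targets`, `q_value`,
#'   `diseases`).
#' @param diseases character vector of disease ids; defaults to every
#'   disease named in the pathway table.
#' @param targets character vector of target ids; defaults to every target
#'   named in docking, PPI or pathway membership.
#' @param config a [ctpdn_config()] supplying `tti_mode`, `tpi_mode` and
#'   `sigmoid_sign`.
#' @return object of class `ctpdn_network`: list with `nodes` (data.frame
#'   `node_id`, `node_type`), `edges` (data.frame with raw score `S`, length
#'   `L`, weight `W`, `edge_type`) and `adjacency` (matrix).
#' @export
build_network <- function(compounds, docking, ppi, pathways, diseases = NULL,
                          targets = NULL, config = ctpdn_config()) {
  compound_ids <- sort(unique(as.character(compounds$compound_id)))
  member_list <- split_ids(pathways$member_targets)
  disease_list <- split_ids(pathways$diseases)
  if (is.null(targets)) {
    targets <- sort(unique(c(docking$target_id, ppi$target_a, ppi$target_b,
                             unlist(member_list))))
  }
  if (is.null(diseases)) diseases <- sort(unique(unlist(disease_list)))
  pathway_ids <- sort(unique(as.character(pathways$pathway_id)))
  nodes <- data.frame(
    node_id = c(compound_ids, targets, pathway_ids, diseases),
    node_type = rep(c("compound", "target", "pathway", "disease"),
                    c(length(compound_ids), length(targets),
                      length(pathway_ids), length(diseases))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(nodes$node_id)) {
    stop("node ids must be unique across layers: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
               collapse = ", "))
  }

  # CTI edges: successful dockings only
  dk <- docking[as.logical(docking$success), , drop = FALSE]
  dangling <- setdiff(c(dk$compound_id, dk$target_id), nodes$node_id)
  cti <- if (nrow(dk) > 0) {
    data.frame(from = as.character(dk$compound_id),
               to = as.character(dk$target_id),
               S = cti_score(dk$s_i, dk$s_m),
               edge_type = "CTI", stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), S = numeric(),
               edge_type = character(), stringsAsFactors = FALSE)
  }

  # TTI edges from PPI
  tti <- if (nrow(ppi) > 0) {
    data.frame(from = as.character(ppi$target_a),
               to = as.character(ppi$target_b),
               S = if (config$tti_mode == "score") ppi$combined_score else
                 1 / ppi$combined_score,
               edge_type = "TTI", stringsAsFactors = FALSE)
  } else cti[0, ]
  dangling <- c(dangling, setdiff(c(tti$from, tti$to), nodes$node_id))

  # TPI edges from membership
  tpi <- do.call(rbind, lapply(seq_len(nrow(pathways)), function(i) {
    m <- member_list[[i]]
    if (length(m) == 0) return(NULL)
    S <- if (config$tpi_mode == "exist") 1 else
      min(max(-log10(pathways$q_value[i]), 1e-3), 1e3)
    data.frame(from = m, to = as.character(pathways$pathway_id[i]),
               S = S, edge_type = "TPI", stringsAsFactors = FALSE)
  }))
  if (is.null(tpi)) tpi <- cti[0, ]
  dangling <- c(dangling, setdiff(tpi$from, nodes$node_id))

  # PDI edges from pathway-disease links
  pdi <- do.call(rbind, lapply(seq_len(nrow(pathways)), function(i) {
    d <- disease_list[[i]]
    d <- intersect(d, diseases)
    if (length(d) == 0) return(NULL)
    data.frame(from = as.character(pathways$pathway_id[i]), to = d,
               S = 1, edge_type = "PDI", stringsAsFactors = FALSE)
  }))
  if (is.null(pdi)) pdi <- cti[0, ]

  if (length(dangling) > 0) {
    stop("edges reference undeclared node ids: ",
         paste(sort(unique(dangling)), collapse = ", "))
  }

  edges <- rbind(cti, tti, pdi, tpi)
  if (nrow(edges) > 0) {
    # canonical undirected key; duplicates keep the largest raw score
    key <- ifelse(edges$from < edges$to,
                  paste(edges$from, edges$to, sep = "\r"),
                  paste(edges$to, edges$from, sep = "\r"))
    if (anyDuplicated(key)) {
      warning("duplicate edges for ", sum(duplicated(key)),
              " pair(s); keeping the largest raw score")
      ord <- order(key, -edges$S)
      edges <- edges[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    }
    edges$L <- edge_length(edges$S, interacts = TRUE)
    edges$W <- edge_weight(edges$L, edges$edge_type,
                           sigmoid_sign = config$sigmoid_sign)
  } else {
    edges$L <- numeric(0); edges$W <- numeric(0)
  }
  rownames(edges) <- NULL

  n <- nrow(nodes)
  A <- matrix(Inf, n, n, dimnames = list(nodes$node_id, nodes$node_id))
  diag(A) <- 0
  if (nrow(edges) > 0) {
    idx_from <- match(edges$from, nodes$node_id)
    idx_to <- match(edges$to, nodes$node_id)
    A[cbind(idx_from, idx_to)] <- edges$W
    A[cbind(idx_to, idx_from)] <- edges$W
  }

  structure(list(nodes = nodes, edges = edges, adjacency = A,
                 config = config),
            class = "ctpdn_network")
}

#' @export
print.ctpdn_network <- function(x, ...) {
  tab <- table(factor(x$nodes$node_type,
                      c("compound", "target", "pathway", "disease")))
  cat("Compound-target-pathway-disease network\n")
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  etab <- table(factor(x$edges$edge_type, .EDGE_TYPES))
  cat(sprintf("  edges: %d (%s)\n", nrow(x$edges),
              paste(sprintf("%s %d", names(etab), etab), collapse = ", ")))
  invisible(x)
}

#' All-pairs shortest paths by Floyd-Warshall
#'
#' Dynamic-programming all-pairs shortest paths on a non-negative weighted
#' adjacency matrix, with a next-hop matrix for path reconstruction. Ties
#' are broken deterministically: a path is only replaced on a strict
#' improvement, with intermediate nodes considered in the (lexicographic)
#' order of the matrix.
#'
#' @param A square adjacency matrix: diagonal 0, `+Inf` for absent pairs,
#'   non-negative weights otherwise; dimnames give node ids.
#' @return list with `dist` (matrix) and `next_hop` (integer matrix;
#'   `next_hop[i, j]` is the node index following `i` on a shortest path to
#'   `j`, `NA` when unreachable).
#' @export
floyd_warshall <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("floyd_warshall: negative weights are not allowed")
  if (any(diag(A) != 0)) stop("floyd_warshall: diagonal must be 0")
  n <- nrow(A)
  D <- A
  nxt <- matrix(rep(seq_len(n), each = n), n, n)
  nxt[is.infinite(D)] <- NA_integer_
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    upd <- which(via < D)
    if (length(upd) > 0) {
      D[upd] <- via[upd]
      nxt[upd] <- matrix(nxt[, k], n, n)[upd]
    }
  }
  dimnames(D) <- dimnames(A)
  list(dist = D, next_hop = nxt)
}

.reconstruct_path <- function(fw, i, j, ids) {
  if (is.na(fw$next_hop[i, j])) return(character(0))
  path <- i
  while (i != j) {
    i <- fw$next_hop[i, j]
    path <- c(path, i)
  }
  ids[path]
}

.classify_shape <- function(types) {
  sig <- paste(substr(types, 1, 1), collapse = "")
  if (sig == "ctpd") "C-T-P-D" else if (sig == "cttpd") "C-T-T-P-D" else "other"
}

#' Rank compounds by mean shortest-path length to disease nodes
#'
#' Runs [floyd_warshall()] on the network adjacency matrix, reconstructs one
#' shortest path per compound-disease pair, classifies its shape
#' (`C-T-P-D`, `C-T-T-P-D`, or `other`), and ranks compounds ascending by
#' the mean length over all diseases. Compounds that cannot reach every
#' disease are excluded from the ranking with a warning (their pairs still
#' appear in the path table with length `+Inf`).
#'
#' @param network a `ctpdn_network` from [build_network()].
#' @return list with `ranking` (data.frame `compound_id`, `mean_length`,
#'   `rank`) and `paths` (data.frame `compound_id`, `disease_id`, `length`,
#'   `shape`, `node_sequence` with `->`-joined ids).
#' @export
rank_compounds <- function(network) {
  stopifnot(inherits(network, "ctpdn_network"))
  nodes <- network$nodes
  comp <- nodes$node_id[nodes$node_type == "compound"]
  dis <- nodes$node_id[nodes$node_type == "disease"]
  if (length(comp) == 0 || length(dis) == 0) {
    stop("rank_compounds: need at least one compound and one disease node")
  }
  fw <- floyd_warshall(network$adjacency)
  ids <- nodes$node_id
  type_of <- setNames(nodes$node_type, ids)
  rows <- vector("list", length(comp) * length(dis))
  r <- 0L
  for (c_id in comp) {
    i <- match(c_id, ids)
    for (d_id in dis) {
      j <- match(d_id, ids)
      len <- fw$dist[i, j]
      seq_ids <- .reconstruct_path(fw, i, j, ids)
      shape <- if (length(seq_ids) >= 2) .classify_shape(type_of[seq_ids]) else "other"
      r <- r + 1L
      rows[[r]] <- data.frame(
        compound_id = c_id, disease_id = d_id, length = len,
        shape = if (is.finite(len)) shape else "other",
        node_sequence = paste(seq_ids, collapse = "->"),
        stringsAsFactors = FALSE)
    }
  }
  paths <- do.call(rbind, rows)
  mean_len <- tapply(paths$length, paths$compound_id, mean)
  mean_len <- mean_len[comp]
  reachable <- is.finite(mean_len)
  if (any(!reachable)) {
    warning("compound(s) excluded from ranking (unreachable disease): ",
            paste(comp[!reachable], collapse = ", "))
  }
  ranked <- data.frame(compound_id = comp[reachable],
                       mean_length = as.numeric(mean_len[reachable]),
                       stringsAsFactors = FALSE)
  ord <- order(ranked$mean_length, ranked$compound_id)
  ranked <- ranked[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  list(ranking = ranked, paths = paths)
}

#' Count how often nodes of a type appear on shortest paths
#'
#' @param paths the `paths` table from [rank_compounds()].
#' @param network the network (provides node types).
#' @param node_type `"target"` or `"pathway"` (any type accepted).
#' @return data.frame `node_id`, `count`, sorted by descending count then id.
#' @export
node_usage_counts <- function(paths, network, node_type = "target") {
  ids_of_type <- network$nodes$node_id[network$nodes$node_type == node_type]
  seqs <- strsplit(paths$node_sequence[paths$node_sequence != ""], "->",
                   fixed = TRUE)
  hits <- unlist(lapply(seqs, function(s) unique(intersect(s, ids_of_type))))
  if (length(hits) == 0) {
    return(data.frame(node_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(hits)
  out <- data.frame(node_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
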