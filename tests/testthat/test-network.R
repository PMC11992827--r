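test_that("docking-score ratio and edge length follow the defining arithmetic", {
  expect_equal(cti_score(45.2, 40.0), 1.13)
  expect_equal(cti_score(38.0, 38.0), 1.0)
  expect_error(cti_score(45, 0), "s_m")
  expect_error(cti_score(Inf, 40), "finite")

  expect_equal(edge_length(2.0), 0.5)
  expect_equal(edge_length(1.0), 1.0)
  expect_equal(edge_length(5, interacts = FALSE), Inf)
  expect_error(edge_length(-1, interacts = TRUE), "S > 0")
})

test_that("edge weights: PDI pinned at 1, others logistic in (0.5, 1)", {
  expect_identical(edge_weight(Inf, "PDI"), 1)
  expect_equal(edge_weight(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(edge_weight(1), 0.731059, tolerance = 1e-6)
  # sigmoid limit at L -> 0+
  expect_equal(edge_weight(1e-12), 0.5, tolerance = 1e-9)
  # finite non-PDI weights are strictly inside (0.5, 1)
  L <- stats::runif(200, 1e-3, 30)  # above ~36 the weight saturates to 1 in doubles
  w <- edge_weight(L, "TTI")
  expect_true(all(w > 0.5 & w < 1))
  # absent non-PDI edge stays +Inf
  expect_identical(edge_weight(Inf, "CTI"), Inf)
  # flipped-sign convention is exposed but distinct
  expect_equal(edge_weight(1, sigmoid_sign = "negative"), 1 / (1 + exp(1)))
})

test_that("a one-of-everything chain builds 4 nodes, 3 edges, 6 finite entries", {
  net <- build_tiny_network(s_i = 45, s_m = 50)
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 3)
  A <- net$adjacency
  expect_true(all(diag(A) == 0))
  expect_equal(sum(is.finite(A)) - 4, 6)  # symmetric off-diagonal entries
  expect_identical(A, t(A))
  # CTI weight chains Eqs: S=0.9, L=1/0.9, W=logistic
  expect_equal(A["c1", "T1"], 1 / (1 + exp(-1 / 0.9)), tolerance = 1e-12)
  expect_equal(A["P1", "D1"], 1)
})

test_that("PPI combined score 0.9 yields a TTI weight near 0.7525", {
  w <- edge_weight(edge_length(0.9), "TTI")
  expect_equal(w, 1 / (1 + exp(-1 / 0.9)), tolerance = 1e-12)
  expect_equal(w, 0.7525, tolerance = 1e-3)
})

test_that("network construction flags dangling ids and duplicate edges", {
  tb <- tiny_chain_tables()
  tb$docking$target_id <- "T9"  # not in any pathway/ppi declaration
  expect_error(
    build_network(tb$compounds, tb$docking, tb$ppi, tb$pathways,
                  targets = "T1"),
    "T9")

  tb2 <- tiny_chain_tables()
  tb2$docking <- rbind(tb2$docking, tb2$docking)
  tb2$docking$s_i[2] <- 55
  expect_warning(
    net <- build_network(tb2$compounds, tb2$docking, tb2$ppi, tb2$pathways),
    "duplicate")
  # strongest raw score (55/50) wins
  expect_equal(net$edges$S[net$edges$edge_type == "CTI"], 1.1)
})

test_that("floyd_warshall finds relayed shortcuts and flags bad input", {
  A <- matrix(c(0, 1, 3,
                1, 0, 1,
                3, 1, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  fw <- floyd_warshall(A)
  expect_equal(fw$dist["A", "C"], 2)
  expect_equal(ctpdn:::.reconstruct_path(fw, 1, 3, rownames(A)),
               c("A", "B", "C"))
  # disconnected pair
  A2 <- matrix(Inf, 2, 2); diag(A2) <- 0
  expect_identical(floyd_warshall(A2)$dist[1, 2], Inf)
  expect_error(floyd_warshall(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("floyd_warshall matches an independent Dijkstra oracle", {
  set.seed(202)
  for (rep_i in 1:100) {
    A <- random_adjacency(12)
    fw <- floyd_warshall(A)
    expect_identical(fw$dist, t(fw$dist))
    for (src in c(1, 7)) {
      expect_equal(unname(fw$dist[src, ]), dijkstra_oracle(A, src),
                   tolerance = 1e-9)
    }
    # triangle inequality on finite triples
    D <- fw$dist
    expect_true(all(D <= outer(D[, 3], D[3, ], `+`) + 1e-9))
  }
})

test_that("ranking sums weights along paths and averages over diseases", {
  # hand-built adjacency: C-T (0.6), T-P (0.8), P-D (1)
  tb <- tiny_chain_tables()
  net <- build_tiny_network()
  net$adjacency["c1", "T1"] <- net$adjacency["T1", "c1"] <- 0.6
  net$adjacency["T1", "P1"] <- net$adjacency["P1", "T1"] <- 0.8
  rk <- rank_compounds(net)
  expect_equal(rk$paths$length, 2.4)
  expect_equal(rk$paths$shape, "C-T-P-D")
  expect_equal(rk$paths$node_sequence, "c1->T1->P1->D1")
  expect_equal(rk$ranking$mean_length, 2.4)
  # mean over two diseases
  expect_equal(mean(c(2.4, 2.6)), 2.5)
})

test_that("path length equals the sum of member edge weights", {
  fix <- gen_network(sim_spec(seed = 5))
  net <- build_network(fix$compounds, fix$docking, fix$ppi, fix$pathways)
  rk <- suppressWarnings(rank_compounds(net))
  finite <- rk$paths[is.finite(rk$paths$length) & rk$paths$node_sequence != "", ]
  for (i in seq_len(nrow(finite))) {
    seq_ids <- strsplit(finite$node_sequence[i], "->", fixed = TRUE)[[1]]
    s <- sum(net$adjacency[cbind(seq_ids[-length(seq_ids)], seq_ids[-1])])
    expect_equal(finite$length[i], s, tolerance = 1e-9)
  }
  # canonical path shapes only walk down the layers
  expect_true(all(finite$shape %in% c("C-T-P-D", "C-T-T-P-D", "other")))
})

test_that("canonical path lengths exceed 2 under the literal weighting", {
  # every non-PDI weight is > 0.5 and PDI = 1, so C-T-P-D paths are > 2
  for (s in 1:5) {
    fix <- gen_network(sim_spec(seed = s))
    net <- build_network(fix$compounds, fix$docking, fix$ppi, fix$pathways)
    rk <- suppressWarnings(rank_compounds(net))
    canon <- rk$paths$length[rk$paths$shape == "C-T-P-D"]
    expect_true(all(canon > 2.0 & canon < 3.0))
  }
})

test_that("raising a docking score never worsens that compound's rank value", {
  fix <- gen_network(sim_spec(seed = 9))
  net0 <- build_network(fix$compounds, fix$docking, fix$ppi, fix$pathways)
  rk0 <- suppressWarnings(rank_compounds(net0))
  d2 <- fix$docking
  ok <- which(d2$success & d2$compound_id == "C02")
  d2$s_i[ok] <- d2$s_i[ok] * 1.5
  net1 <- build_network(fix$compounds, d2, fix$ppi, fix$pathways)
  rk1 <- suppressWarnings(rank_compounds(net1))
  m0 <- rk0$ranking$mean_length[rk0$ranking$compound_id == "C02"]
  m1 <- rk1$ranking$mean_length[rk1$ranking$compound_id == "C02"]
  expect_lte(m1, m0)
})

test_that("an isolated compound is excluded from the ranking with a warning", {
  tb <- tiny_chain_tables()
  tb$compounds <- rbind(tb$compounds,
                        data.frame(compound_id = "c9", smiles = NA, ob = 40,
                                   dl = 0.3, stringsAsFactors = FALSE))
  net <- build_network(tb$compounds, tb$docking, tb$ppi, tb$pathways)
  expect_warning(rk <- rank_compounds(net), "c9")
  expect_false("c9" %in% rk$ranking$compound_id)
  expect_true(any(is.infinite(rk$paths$length[rk$paths$compound_id == "c9"])))
})

test_that("node usage counts nodes on shortest paths by type", {
  paths <- data.frame(
    compound_id = c("c1", "c2", "c3"), disease_id = "d",
    length = 2.5, shape = "C-T-P-D",
    node_sequence = c("c1->AKT1->p1->d", "c2->AKT1->p2->d", "c3->CAT->p1->d"),
    stringsAsFactors = FALSE)
  net <- list(nodes = data.frame(
    node_id = c("c1", "c2", "c3", "AKT1", "CAT", "p1", "p2", "d"),
    node_type = c(rep("compound", 3), "target", "target", "pathway",
                  "pathway", "disease"), stringsAsFactors = FALSE))
  tg <- node_usage_counts(paths, net, "target")
  expect_equal(tg$node_id, c("AKT1", "CAT"))
  expect_equal(tg$count, c(2L, 1L))
  pw <- node_usage_counts(paths, net, "pathway")
  expect_equal(pw$count[pw$node_id == "p1"], 2L)
  empty <- node_usage_counts(paths[0, ], net, "target")
  expect_equal(nrow(empty), 0)
})
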