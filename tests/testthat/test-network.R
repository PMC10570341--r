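mk <- function(m, prefix = "g") {
  dimnames(m) <- list(paste0(prefix, seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  rpkm_matrix(m)
}

test_that("clr preprocessing is exact and filters sparse entities", {
  v <- mk(matrix(c(1, 1, 1,
                   0, 1, 3,
                   1, 0, 0), 3, byrow = TRUE), "v")
  e <- mk(matrix(rlnorm(9), 3), "e")
  prep <- preprocess_network(v, e, network_config(min_observations = 0))
  # column of (1,1,1)+1 has clr contributions 0 after centering
  expect_equal(unname(prep$viral_t[, 1]),
               log(c(2, 1, 2)) - mean(log(c(2, 1, 2))))
  # a sample column's clr values sum to zero
  expect_true(all(abs(colSums(prep$viral_t)) < 1e-9))
  # raw (0,1,3) + pseudo-count 1 in a sample column
  v3 <- mk(matrix(c(0, 1, 3, 1, 1, 1, 2, 2, 2), 3, byrow = FALSE), "v")
  p3 <- preprocess_network(v3, e, network_config(min_observations = 0))
  expect_equal(unname(p3$viral_t[, 1]), c(-0.6931472, 0, 0.6931472),
               tolerance = 1e-6)

  prep3 <- preprocess_network(v, e, network_config(min_observations = 3))
  expect_equal(prep3$n_viral_out, 1)   # entities seen in < 3 samples removed

  e_bad <- mk(matrix(1, 2, 2), "e")
  colnames(e_bad$rpkm) <- colnames(e_bad$detected) <- c("z1", "z2")
  expect_error(preprocess_network(v, e_bad), "intersection")
})

test_that("the default scorer retains copies and calibrates to alpha on noise", {
  set.seed(30)
  n <- 100
  base <- matrix(rlnorm(2 * n), 2, n)
  v <- mk(base, "v")
  e <- mk(base, "e")     # eukaryote block is an exact copy of the viral one
  prep <- preprocess_network(v, e, network_config())
  ed <- score_associations(prep, "Nano", network_config())
  pair <- ed[ed$virus_id == "v1" & ed$eukaryote_id == "e1", ]
  expect_equal(nrow(pair), 1)
  expect_gt(pair$weight, 0.999)
  expect_true(all(abs(ed$weight) <= 1))

  # independent noise: retention rate close to alpha
  set.seed(31)
  v2 <- mk(matrix(rlnorm(20 * n), 20, n), "v")
  e2 <- mk(matrix(rlnorm(50 * n), 50, n), "e")
  p2 <- preprocess_network(v2, e2, network_config())
  ed2 <- score_associations(p2, "Nano", network_config())
  rate <- nrow(ed2) / (20 * 50)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 1000))
})

test_that("a plugin scorer is honoured through the documented contract", {
  v <- mk(matrix(rlnorm(20), 2, 10), "v")
  e <- mk(matrix(rlnorm(20), 2, 10), "e")
  plug <- function(vt, et) {
    data.frame(virus_id = "v1", eukaryote_id = "e2", weight = 0.5,
               p_value = 1e-5, stringsAsFactors = FALSE)
  }
  prep <- preprocess_network(v, e, network_config(min_observations = 0))
  ed <- score_associations(prep, "Micro", network_config(scorer = plug))
  expect_equal(ed$virus_id, "v1")
  expect_equal(ed$weight, 0.5)
  expect_equal(ed$size_fraction, "Micro")

  cfgd <- network_config(scorer = "clr_pearson_detrended")
  expect_error(score_associations(prep, "Micro", cfgd), "covariate")
})

test_that("best-edge pooling keeps the largest absolute weight per pair", {
  e1 <- data.frame(virus_id = "v1", eukaryote_id = "e1", weight = 0.3,
                   size_fraction = "Piconano", p_value = 1e-3)
  e2 <- data.frame(virus_id = "v1", eukaryote_id = "e1", weight = -0.6,
                   size_fraction = "Nano", p_value = 1e-4)
  pooled <- pool_best_edges(list(e1, e2))
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$weight, -0.6)

  single <- pool_best_edges(list(e1))
  expect_equal(single$weight, 0.3)

  # pooled pair set is the union of the inputs, order-invariant
  set.seed(32)
  lists <- lapply(c("Piconano", "Nano", "Micro"), function(f) {
    data.frame(virus_id = sample(paste0("v", 1:6), 8, TRUE),
               eukaryote_id = sample(paste0("e", 1:4), 8, TRUE),
               weight = runif(8, -1, 1), size_fraction = f,
               p_value = runif(8), stringsAsFactors = FALSE)
  })
  pa <- pool_best_edges(lists)
  pb <- pool_best_edges(rev(lists))
  expect_setequal(paste(pa$virus_id, pa$eukaryote_id),
                  unique(unlist(lapply(lists, function(l)
                    paste(l$virus_id, l$eukaryote_id)))))
  ka <- paste(pa$virus_id, pa$eukaryote_id)
  kb <- paste(pb$virus_id, pb$eukaryote_id)
  expect_equal(pa$weight[order(ka)], pb$weight[order(kb)])
})

test_that("edge-support test separates shifted similarities and flags null", {
  set.seed(33)
  edges <- data.frame(virus_id = paste0("v", 1:10),
                      eukaryote_id = paste0("e", 1:10),
                      weight = c(rep(0.8, 5), rep(0.1, 5)),
                      size_fraction = "Nano", p_value = 1e-4)
  sims <- expand.grid(virus_id = paste0("v", 1:10),
                      eukaryote_id = paste0("e", 1:10),
                      stringsAsFactors = FALSE)
  sims$max_protein_identity <- runif(100, 20, 40)
  strong <- paste(sims$virus_id, sims$eukaryote_id) %in%
    paste(edges$virus_id, edges$eukaryote_id)[1:5]
  sims$max_protein_identity[strong] <- sims$max_protein_identity[strong] + 30
  r <- edge_support_test(edges, sims, network_config())
  expect_lt(r$p, 0.01)
  expect_gt(r$median_strong, r$median_other)
  # all strong similarities above all others: p is the minimal attainable
  expect_equal(r$p, suppressWarnings(stats::wilcox.test(
    sims$max_protein_identity[strong], sims$max_protein_identity[!strong],
    exact = FALSE)$p.value))

  sims_null <- sims
  sims_null$max_protein_identity <- runif(100, 20, 40)
  r0 <- edge_support_test(edges, sims_null, network_config())
  expect_gt(r0$p, 0.01)
})

test_that("clade enrichment p-values equal the hypergeometric oracle", {
  # 6 edges to one taxon, all inside one 6-leaf clade, 30 bearing leaves
  set.seed(35)
  tree <- polarniche:::name_internal_nodes(ape::rtree(30, rooted = TRUE))
  clade_sizes <- sapply(seq_len(tree$Nnode), function(i)
    length(polarniche:::tips_under(tree, 30 + i)))
  nd <- which(clade_sizes == 6)[1]
  inside <- polarniche:::tips_under(tree, 30 + nd)
  outside <- setdiff(tree$tip.label, inside)
  euk_taxa <- setNames(c(rep("T1", 6), rep("T2", 24)), paste0("e", 1:30))
  edges <- rbind(
    data.frame(virus_id = inside, eukaryote_id = paste0("e", 1:6),
               weight = 0.9, size_fraction = "Nano", p_value = 1e-6),
    data.frame(virus_id = outside, eukaryote_id = paste0("e", 7:30),
               weight = 0.5, size_fraction = "Nano", p_value = 1e-4))
  pred <- tim_predict(tree, edges, euk_taxa, alpha = 0.05)
  row <- pred[pred$taxon == "T1" &
                pred$node == tree$node.label[nd], ]
  expect_equal(nrow(row), 1)
  expect_equal(row$p_raw, 1 / choose(30, 6), tolerance = 1e-12)
  # every reported table agrees with the enumeration oracle
  for (r in seq_len(nrow(pred))) {
    expect_equal(pred$p_raw[r],
                 hyper_oracle(pred$a[r], pred$b[r], pred$c[r], pred$d[r]),
                 tolerance = 1e-9)
  }
})

test_that("uniformly spread associations yield no significant clade", {
  set.seed(35)
  tree <- polarniche:::name_internal_nodes(ape::rtree(40, rooted = TRUE))
  euk_taxa <- setNames(rep(c("T1", "T2"), 10), paste0("e", 1:20))
  edges <- data.frame(virus_id = tree$tip.label,
                      eukaryote_id = sample(paste0("e", 1:20), 40, TRUE),
                      weight = 0.5, size_fraction = "Nano", p_value = 1e-3)
  pred <- tim_predict(tree, edges, euk_taxa, alpha = 0.05)
  expect_equal(nrow(host_predictions(pred)), 0)
})
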