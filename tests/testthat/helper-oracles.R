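# Independent oracles and small fixtures shared across tests.

# small, fast synthetic configuration for pipeline-level tests
tiny_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genomes = 40, n_stations = 12, n_kos = 40,
         n_gccs = 12, n_hosts = 12, n_host_taxa = 4,
         n_planted_links = 2), list(...))
  do.call(synth_config, args)
}

ladder_tree <- function() {
  polarniche:::name_internal_nodes(
    ape::read.tree(text = "((A:1,B:1):1,C:2);"))
}

# exhaustive-enumeration likelihood for the 2-state equal-rates model:
# sums over every internal-state assignment the product of closed-form
# transition probabilities, with a (1/2, 1/2) root prior
er_brute_loglik <- function(tree, states, q) {
  P <- function(s1, s2, t) {
    if (s1 == s2) 0.5 + 0.5 * exp(-2 * q * t) else 0.5 - 0.5 * exp(-2 * q * t)
  }
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  sts <- c("Polar", "Nonpolar")
  tot <- 0
  for (cfgi in 0:(2^n_node - 1)) {
    internal <- sts[1 + ((cfgi %/% 2^(0:(n_node - 1))) %% 2)]
    stt <- function(i) if (i <= n_tip) states[tree$tip.label[i]] else
      internal[i - n_tip]
    pr <- 0.5
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P(stt(tree$edge[e, 1]), stt(tree$edge[e, 2]),
                   tree$edge.length[e])
    tot <- tot + pr
  }
  log(tot)
}

# random rooted binary tree with n tips and U(0.1, 2) branch lengths
random_small_tree <- function(n) {
  tree <- ape::rtree(n, rooted = TRUE)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 2)
  polarniche:::name_internal_nodes(tree)
}

# inverse-CDF weighted quantile (type-1 style): smallest value whose
# cumulative weight reaches p
weighted_quantile_oracle <- function(values, weights, p) {
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(p, function(pp) v[which(cw >= pp - 1e-12)[1]], numeric(1))
}

# one-sided (enrichment) Fisher p for table (a, b, c, d) by explicit
# combinatorial enumeration of tables at least as extreme
hyper_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  prob <- function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }
  xs <- a:min(m, k)
  sum(vapply(xs, prob, numeric(1)))
}

# direct multivariate-normal profile log-likelihood by dense algebra
# (explicit inverse and determinant), profiling mu and sigma2
mvn_profile_oracle <- function(y, C) {
  n <- length(y)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
  r <- y - mu
  s2 <- as.numeric(r %*% Ci %*% r) / n
  as.numeric(-0.5 * (n * log(2 * pi * s2) + determinant(C)$modulus + n))
}

lambda_cov_oracle <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# are the two named clades of a tree nested (one contains the other)?
clades_nested <- function(tree, a, b) {
  nt <- length(tree$tip.label)
  ta <- polarniche:::tips_under(tree, nt + match(a, tree$node.label))
  tb <- polarniche:::tips_under(tree, nt + match(b, tree$node.label))
  all(ta %in% tb) || all(tb %in% ta)
}
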