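test_that("ER pruning likelihood equals exhaustive enumeration", {
  tr <- polarniche:::name_internal_nodes(
    ape::read.tree(text = "((A:0.3,B:0.7):0.5,(C:0.2,D:0.9):0.4);"))
  st <- c(A = "Polar", B = "Nonpolar", C = "Polar", D = "Polar")
  for (q in c(0.1, 0.5, 2)) {
    expect_equal(er_loglik(tr, st, q), er_brute_loglik(tr, st, q),
                 tolerance = 1e-12)
  }

  set.seed(20)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    tree <- random_small_tree(n)
    st <- setNames(sample(c("Polar", "Nonpolar"), n, replace = TRUE),
                   tree$tip.label)
    q <- runif(1, 0.05, 3)
    expect_lt(abs(er_loglik(tree, st, q) - er_brute_loglik(tree, st, q)),
              1e-10)
  }
})

test_that("ER likelihood limits and symmetries hold", {
  tr <- random_small_tree(5)
  same <- setNames(rep("Polar", 5), tr$tip.label)
  expect_equal(er_loglik(tr, same, 0), log(0.5))
  mixed <- same; mixed[2] <- "Nonpolar"
  expect_identical(er_loglik(tr, mixed, 0), -Inf)
  # swapping the two state labels leaves the likelihood unchanged
  swapped <- ifelse(mixed == "Polar", "Nonpolar", "Polar")
  names(swapped) <- names(mixed)
  expect_equal(er_loglik(tr, mixed, 0.7), er_loglik(tr, swapped, 0.7))
  expect_error(er_loglik(tr, mixed, -1), "q")
})

test_that("ML fit matches ape::ace and reconstructs sensible states", {
  tn <- gen_tree_and_niches(synth_config(21, n_genomes = 60))
  tree <- tn$tree
  st <- tn$states
  fit <- fit_er(tree, st)
  a <- ape::ace(factor(st[tree$tip.label]), tree, type = "discrete",
                model = "ER")
  expect_equal(fit$q_hat, unname(a$rates), tolerance = 1e-4)
  # ace sums the root states unweighted; ours carries the (1/2,1/2) prior
  expect_equal(fit$loglik + log(2), a$loglik, tolerance = 1e-6)
  expect_equal(fit$node_posteriors$P_Polar, unname(a$lik.anc[, "Polar"]),
               tolerance = 1e-5)
  expect_equal(rowSums(cbind(fit$node_posteriors$P_Polar,
                             fit$node_posteriors$P_Nonpolar)),
               rep(1, tree$Nnode), tolerance = 1e-9)

  same <- setNames(rep("Polar", length(tree$tip.label)), tree$tip.label)
  fit0 <- fit_er(tree, same)
  expect_lt(fit0$q_hat, 1e-6)
  expect_true(all(fit0$node_states == "Polar"))
  expect_true(all(fit0$node_posteriors$P_Polar > 1 - 1e-6))
})

test_that("transition events are counted on state changes with RED attached", {
  tree <- random_small_tree(8)
  same <- setNames(rep("Nonpolar", 8), tree$tip.label)
  tr0 <- count_transitions(fit_er(tree, same))
  expect_equal(tr0$n_to_p + tr0$p_to_n, 0)

  # two clean clades separated by long internal branches: one event
  t2 <- polarniche:::name_internal_nodes(
    ape::read.tree(text = "((A:0.1,B:0.1):2,(C:0.1,D:0.1):2);"))
  st <- c(A = "Polar", B = "Polar", C = "Nonpolar", D = "Nonpolar")
  fit <- fit_er(t2, st)
  trs <- count_transitions(fit)
  expect_equal(trs$n_to_p + trs$p_to_n, 1)
  expect_equal(nrow(trs$events), 1)
  expect_true(trs$events$child_red >= 0 && trs$events$child_red <= 1)
})

test_that("RED follows the recursion with its boundary values", {
  lt <- ladder_tree()
  red <- red_values(lt)
  expect_equal(unname(red[c("A", "B", "C")]), c(1, 1, 1))
  expect_equal(unname(red["N1"]), 0)
  expect_equal(unname(red["N2"]), 0.5)   # 0 + 1/(1+1) * (1 - 0)

  set.seed(22)
  tree <- random_small_tree(30)
  red2 <- red_values(tree)
  expect_true(all(red2 >= 0 & red2 <= 1))
  # non-decreasing along every root-to-tip path
  n_tip <- length(tree$tip.label)
  lab <- function(i) if (i <= n_tip) tree$tip.label[i] else
    tree$node.label[i - n_tip]
  for (e in seq_len(nrow(tree$edge))) {
    expect_gte(red2[lab(tree$edge[e, 2])], red2[lab(tree$edge[e, 1])] - 1e-12)
  }
})

test_that("Faith's PD matches hand values, picante, and is monotone", {
  lt <- ladder_tree()
  expect_equal(faith_pd(lt, c("A", "B", "C")), 5)      # whole tree
  expect_equal(faith_pd(lt, c("A", "B")), 3)           # 1 + 1 + 1
  expect_equal(faith_pd(lt, "C"), 2)                   # root-to-leaf path
  expect_error(faith_pd(lt, character(0)), "empty")

  set.seed(23)
  tree <- random_small_tree(20)
  for (i in 1:5) {
    sub <- sample(tree$tip.label, sample(2:10, 1))
    comm <- matrix(as.numeric(tree$tip.label %in% sub), 1,
                   dimnames = list("s", tree$tip.label))
    expect_equal(faith_pd(tree, sub),
                 picante::pd(comm, tree, include.root = TRUE)$PD,
                 tolerance = 1e-9)
    sup <- union(sub, sample(tree$tip.label, 3))
    expect_gte(faith_pd(tree, sup), faith_pd(tree, sub) - 1e-12)
  }
})

test_that("polar/nonpolar PD ratio handles one-sided families", {
  lt <- ladder_tree()
  labels <- c(A = "Polar", B = "Polar", C = "Nonpolar")
  r <- pd_ratio(lt, c("A", "B"), labels)
  expect_false(r$defined)
  expect_equal(r$pd_nonpolar, 0)

  r2 <- pd_ratio(lt, c("A", "C"), labels)
  expect_true(r2$defined)
  expect_equal(r2$ratio, faith_pd(lt, "A") / faith_pd(lt, "C"))
})

test_that("lambda profile likelihood matches a dense-algebra oracle", {
  set.seed(24)
  tree <- ape::rphylo(5, 1, 0.2)
  C <- ape::vcv.phylo(tree)
  y <- setNames(rnorm(5), tree$tip.label)
  fit <- pagel_lambda_test(tree, y)
  expect_equal(fit$loglik_bm, mvn_profile_oracle(y[tree$tip.label], C),
               tolerance = 1e-8)
  # the fitted lambda cannot do worse than any fixed lambda
  for (lam in c(0, 0.3, 0.8, 1)) {
    expect_gte(fit$loglik_lambda + 1e-8,
               mvn_profile_oracle(y[tree$tip.label],
                                  lambda_cov_oracle(C, lam)))
  }
  expect_gte(fit$lrt_stat, 0)
  expect_true(fit$lambda_hat >= 0 && fit$lambda_hat <= 1)
})

test_that("lambda estimate agrees with phytools within its box", {
  set.seed(25)
  tree <- ape::rphylo(40, 1, 0.3)
  y <- phytools::fastBM(tree)
  fit <- pagel_lambda_test(tree, y)
  ps <- phytools::phylosig(tree, y, method = "lambda")
  if (ps$lambda <= 1) {
    expect_equal(fit$lambda_hat, ps$lambda, tolerance = 1e-3)
    expect_equal(fit$loglik_lambda, ps$logL, tolerance = 1e-4)
  } else {
    expect_equal(fit$lambda_hat, 1, tolerance = 1e-6)
  }
})

test_that("batch lambda tests flag constants and keep BH above raw p", {
  set.seed(26)
  tree <- ape::rphylo(20, 1, 0.2)
  pres <- list(K1 = tree$tip.label[1:8],
               K2 = sample(tree$tip.label, 10),
               K3 = tree$tip.label,          # constant: untestable
               K4 = sample(tree$tip.label, 5))
  out <- lambda_signal_batch(tree, pres)
  expect_false(out$testable[out$family_id == "K3"])
  ok <- out$testable
  expect_true(all(out$p_bh[ok] >= out$p_raw[ok] - 1e-12))
  expect_true(all(out$lambda_hat[ok] >= 0 & out$lambda_hat[ok] <= 1))
})
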