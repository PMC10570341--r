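test_that("largest-remainder allocation is exact and tie-stable", {
  a <- allocate_weighted_vector(1, 5, 10000)
  expect_equal(a$count, 10000L)

  b <- allocate_weighted_vector(rep(1 / 3, 3), 1:3, 10000)
  expect_equal(b$count, c(3334L, 3333L, 3333L))  # tie broken by input order

  c_ <- allocate_weighted_vector(c(0.05, 0.95), c(2, 10), 10000)
  expect_equal(c_$count, c(500L, 9500L))

  expect_error(allocate_weighted_vector(c(0.5, -0.1, 0.6), 1:3), "negative")
  expect_error(allocate_weighted_vector(c(0.5, 0.4), 1:3), "mismatch")
  expect_error(allocate_weighted_vector(c(0.5, 0.4), 1:2), "sum to 1")
})

test_that("allocation conserves the vector size for arbitrary simplex weights", {
  set.seed(10)
  for (i in 1:100) {
    k <- sample(2:12, 1)
    w <- rexp(k); w <- w / sum(w)
    a <- allocate_weighted_vector(w, seq_len(k), 10000)
    expect_identical(sum(a$count), 10000L)
  }
})

test_that("robust optimum follows the weighted-vector definition and cutoffs", {
  cfg <- niche_config()
  r <- robust_optimum(rep(1, 12), env = rep(5, 12), cfg = cfg)
  expect_true(r$defined)
  expect_equal(c(r$q1, r$q2, r$q3), c(5, 5, 5))

  r9 <- robust_optimum(rep(1, 9), env = rep(5, 9), cfg = cfg)
  expect_false(r9$defined)                      # < 10 non-NA observations

  # 25% weight at 2 degrees, 75% at 10: optimum lands on the heavy value.
  # Oracle: materialise the vector by explicit largest-remainder counts
  # (floor 833 each, remainder 4 to the first four inputs) and take
  # empirical quantiles.
  rpkm <- rep(1, 12)
  env <- c(rep(2, 3), rep(10, 9))
  r2 <- robust_optimum(rpkm, env = env, cfg = cfg)
  counts <- rep(833L, 12); counts[1:4] <- 834L
  vec <- rep(env, counts)
  q <- unname(quantile(vec, c(0.25, 0.5, 0.75), type = 7))
  expect_equal(c(r2$q1, r2$q2, r2$q3), q)
  expect_equal(r2$q2, 10)
})

test_that("optimum is shift-equivariant and bounded by the observed values", {
  set.seed(11)
  for (i in 1:20) {
    n <- 25
    rpkm <- rlnorm(n) * rbinom(n, 1, 0.8)
    env <- runif(n, -2, 30)
    env[sample(n, 3)] <- NA
    r <- robust_optimum(rpkm, env = env)
    if (!r$defined) next
    used <- which(rpkm > 0 & !is.na(env))
    expect_gte(r$q2, min(env[used]))
    expect_lte(r$q2, max(env[used]))
    r_shift <- robust_optimum(rpkm, env = env + 7)
    expect_equal(c(r_shift$q1, r_shift$q2, r_shift$q3) - 7,
                 c(r$q1, r$q2, r$q3), tolerance = 1e-9)
  }
})

test_that("gene-family profiles sum member genomes and gate eligibility", {
  m <- matrix(c(1, 0, 2, 0, 3, 0,
                0, 4, 0, 5, 0, 0), 2, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  x <- rpkm_matrix(m)
  ann <- data.frame(gene_id = c("a", "b"), genome_id = c("g1", "g2"),
                    ko_id = c("K1", "K1"), gcc_id = NA,
                    stringsAsFactors = FALSE)
  pr <- gene_family_profile(ann, x, "K1")
  expect_equal(unname(pr$rpkm), c(1, 4, 2, 5, 3, 0))  # additive over members
  expect_equal(unname(pr$detected), c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_false(pr$eligible)                           # <= 4 genomes
  expect_true(all(pr$rpkm >= apply(m, 2, max) - 1e-12))
  expect_error(gene_family_profile(ann, x, "K9"), "unknown family")
})

test_that("binary niche assignment applies zero rules, tests, and BH", {
  set.seed(12)
  nA <- 40; nB <- 40
  part <- setNames(rep(c("Polar", "Nonpolar"), c(nA, nB)),
                   paste0("s", 1:(nA + nB)))
  m <- rbind(
    polar_only = c(rlnorm(nA), rep(0, nB)),
    shifted = c(rlnorm(nA, log(10)), rlnorm(nB, log(1))),
    null1 = rlnorm(nA + nB),
    null2 = rlnorm(nA + nB),
    absent = rep(0, nA + nB))
  colnames(m) <- names(part)
  res <- assign_binary_niche(rpkm_matrix(m), part)
  expect_equal(res$label[res$entity_id == "polar_only"], "Polar")
  expect_equal(res$rule[res$entity_id == "polar_only"], "zero_rule")
  expect_equal(res$label[res$entity_id == "shifted"], "Polar")
  expect_lt(res$p_bh[res$entity_id == "shifted"], 0.05)
  expect_equal(res$label[res$entity_id == "null1"], "Unknown")
  expect_equal(res$label[res$entity_id == "absent"], "Undetected")
})

test_that("niche assignment is rank-based and order-invariant", {
  set.seed(13)
  part <- setNames(rep(c("A", "B"), each = 30), paste0("s", 1:60))
  m <- rbind(e1 = c(rlnorm(30, 1), rlnorm(30)), e2 = rlnorm(60))
  colnames(m) <- names(part)
  base <- assign_binary_niche(rpkm_matrix(m), part)
  # strictly increasing transform of one profile: same p, same label
  m2 <- m; m2["e1", ] <- m2["e1", ]^1.7
  tr <- assign_binary_niche(rpkm_matrix(m2), part)
  expect_equal(tr$p_raw, base$p_raw, tolerance = 1e-12)
  expect_equal(tr$label, base$label)
  # reordering samples changes nothing
  perm <- sample(60)
  m3 <- m[, perm]
  re <- assign_binary_niche(rpkm_matrix(m3), part)
  expect_equal(re$p_raw, base$p_raw, tolerance = 1e-12)
})

test_that("size index is the RPKM-weighted mean of the fraction constants", {
  expect_equal(size_index(c(2, 3), c("Pico", "Pico")), 1)
  expect_equal(size_index(c(2, 2), c("Pico", "Macro")), 3)
  expect_equal(size_index(c(1, 1), c("Piconano", "Broad")), 2)
  expect_true(is.na(size_index(c(0, 0), c("Pico", "Nano"))))
  expect_error(size_index(1, "Huge"), "unknown size fraction")
})

test_that("polar-specific classification uses strict cutoffs and flags undefined", {
  ok <- list(defined = TRUE, q2 = 2)
  lat70 <- list(defined = TRUE, q2 = 70)
  expect_equal(classify_polar_family(ok, lat70), "Polar-specific")
  expect_equal(classify_polar_family(list(defined = TRUE, q2 = 9.9),
                                     list(defined = TRUE, q2 = 50)),
               "Other")                        # latitude must exceed 50
  expect_equal(classify_polar_family(list(defined = TRUE, q2 = 10),
                                     lat70), "Other")
  expect_equal(classify_polar_family(list(defined = FALSE, q2 = NA), lat70),
               "Ineligible")
})
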