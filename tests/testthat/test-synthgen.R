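test_that("generation is deterministic and substreams are independent", {
  a <- synth_dataset(tiny_cfg(5))
  b <- synth_dataset(tiny_cfg(5))
  expect_identical(a$states, b$states)
  expect_identical(a$tree$edge.length, b$tree$edge.length)
  expect_identical(a$abundance$rpkm, b$abundance$rpkm)
  expect_identical(a$annotations, b$annotations)

  # changing the number of KOs must not perturb tree, samples, abundance
  c_ <- synth_dataset(tiny_cfg(5, n_kos = 25))
  expect_identical(a$tree$edge.length, c_$tree$edge.length)
  expect_identical(a$samples, c_$samples)
  expect_identical(a$abundance$rpkm, c_$abundance$rpkm)
})

test_that("config validation rejects non-viable processes and missing seed", {
  expect_error(synth_config(1, death_rate = 2), "non-viable")
  expect_error(synth_config(), "seed")
})

test_that("trait simulation at rate zero keeps the root state everywhere", {
  tn <- gen_tree_and_niches(tiny_cfg(3, er_rate_q = 0))
  expect_equal(length(unique(tn$states)), 1)
  expect_equal(tn$transitions$n_to_p + tn$transitions$p_to_n, 0)
})

test_that("realized switch counts match the Poisson expectation of the rate", {
  cfg <- synth_config(seed = 11, n_genomes = 500)
  tn <- gen_tree_and_niches(cfg)
  L <- sum(tn$tree$edge.length)
  n_events <- nrow(tn$transitions$events)
  expect_lt(abs(n_events - cfg$er_rate_q * L),
            3 * sqrt(cfg$er_rate_q * L))
})

test_that("stations follow the temperature and biome rules", {
  cfg <- tiny_cfg(9, temp_noise_sd = 0, temp_missing = 0)
  s <- gen_samples(cfg)
  st <- unique(s[, c("station_id", "latitude", "temperature", "biome")])
  o <- order(abs(st$latitude))
  expect_true(all(diff(st$temperature[o]) <= 1e-9))
  expect_true(all((abs(st$latitude) > 60) == (st$biome == "Polar")))

  s2 <- gen_samples(tiny_cfg(9, temp_missing = 0.2))
  expect_equal(sum(is.na(s2$temperature)), round(0.2 * nrow(s2)))
})

test_that("abundance generator respects zero inflation and thermal structure", {
  cfg0 <- tiny_cfg(4, zero_inflation = 1)
  tn <- gen_tree_and_niches(cfg0)
  s <- gen_samples(cfg0)
  ab <- gen_abundance(tn, s, cfg0)
  expect_true(all(ab$abundance$rpkm == 0))

  # a polar-optimum genome accumulates more RPKM in polar samples
  cfg <- strong_signal_config(4)
  ds <- synth_dataset(cfg)
  polar_samples <- ds$samples$sample_id[ds$samples$biome == "Polar"]
  cold <- names(ds$optima)[ds$optima < 2]
  cum_polar <- rowSums(ds$abundance$rpkm[cold, polar_samples, drop = FALSE])
  cum_other <- rowSums(ds$abundance$rpkm[cold,
                                         setdiff(colnames(ds$abundance$rpkm),
                                                 polar_samples), drop = FALSE])
  expect_true(mean(cum_polar > cum_other) > 0.9)
})

test_that("annotations are unique per gene and the polar bias is planted", {
  ds <- synth_dataset(tiny_cfg(6))
  expect_false(anyDuplicated(ds$annotations$gene_id) > 0)

  # with no effect, truly-polar KOs occur at equal rates in both niches
  cfg1 <- tiny_cfg(6, ko_effect = 1)
  tn <- gen_tree_and_niches(cfg1)
  ann <- gen_annotations(tn, cfg1)
  tab <- ann$annotations[!is.na(ann$annotations$ko_id), ]
  tab <- tab[tab$ko_id %in% ann$true_polar_kos, ]
  rate_polar <- nrow(tab[tn$states[tab$genome_id] == "Polar", ]) /
    sum(tn$states == "Polar")
  rate_non <- nrow(tab[tn$states[tab$genome_id] == "Nonpolar", ]) /
    sum(tn$states == "Nonpolar")
  expect_lt(abs(rate_polar - rate_non), 0.5)

  # planted pathway is composed mostly of truly-polar KOs
  planted <- ds$pathways$ko_id[ds$pathways$pathway_id == ds$planted_pathway]
  expect_gte(mean(planted %in% ds$true_polar_kos), 0.8)
})

test_that("planted host links hit the configured coupling strength", {
  cfg <- synth_config(21, link_correlation = 0.9)
  ds <- synth_dataset(cfg)
  net <- ds$network
  expect_true(all(net$true_links$virus_id %in% ds$tree$tip.label))
  expect_true(all(net$true_links$eukaryote_id %in% net$euks))
  skey <- paste(ds$samples$station_id, ds$samples$depth_layer, sep = ":")
  rs <- mapply(function(v, e) {
    det <- ds$abundance$rpkm[v, ] > 0
    if (sum(det) < 60) return(NA_real_)
    resid <- log(ds$abundance$rpkm[v, det]) - log(ds$expected[v, det])
    cor(resid, net$host_field[e, skey[det]])
  }, net$true_links$virus_id, net$true_links$eukaryote_id)
  rs <- rs[!is.na(rs)]
  expect_gt(length(rs), 5)
  expect_gt(median(rs), 0.8)
  expect_lt(median(rs), 0.97)
  expect_gte(mean(rs > 0.8 & rs < 0.97), 0.85)
})

test_that("derived lineages are complete and nested", {
  ds <- synth_dataset(tiny_cfg(8))
  lin <- gen_lineages(ds)
  expect_setequal(lin$genome_id, ds$tree$tip.label)
  expect_false(anyNA(lin$main_group))
  # genera refine families: every genus maps into exactly one family
  expect_true(all(tapply(lin$family, lin$genus,
                         function(x) length(unique(x))) == 1))
})
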