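# Orchestration: run the full analysis (synth -> community -> niche ->
# phylo -> network -> enrichment) from one configuration, with filter
# logging and a checksummed run manifest.

#' Run the full polar-adaptation analysis
#'
#' Executes the pipeline stages in dependency order on either a
#' synthetic dataset (pass a [synth_config()]) or a list of input file
#' paths (`abundance`, `samples`, `tree`, `annotations`, `pathways`,
#' `similarity`, `euk_taxa`, and `euk` — a named vector of per-fraction
#' eukaryote matrices). Each stage's outputs are written as TSV plus a
#' JSON manifest with checksums; a rerun with the same seed is
#' byte-identical. Every filter logs its before/after counts to stderr
#' and to the returned log. When the temperature column is entirely
#' missing the niche stage runs latitude-only with a warning.
#'
#' @param x A [synth_config()] or a named list of input paths.
#' @param out_dir Output directory.
#' @param only Optional character vector of stage names to run
#'   (`community`, `niche`, `phylo`, `network`, `enrichment`).
#' @param niche_cfg A [niche_config()].
#' @param net_cfg A [network_config()].
#' @param n_perm ANOSIM permutations (default 999).
#' @param alpha Significance level for the downstream tests.
#' @return Invisibly, a list with all stage results, the `log` data
#'   frame of filter counts, and the `manifest`.
#' @export
run_all <- function(x, out_dir, only = NULL,
                    niche_cfg = niche_config(),
                    net_cfg = network_config(),
                    n_perm = 999, alpha = 0.05) {
  stages <- c("community", "niche", "phylo", "network", "enrichment")
  if (is.null(only)) only <- stages
  if (!all(only %in% stages)) stop("unknown stage in --only")
  log <- list()
  note <- function(stage, what, n_before, n_after) {
    message(sprintf("[%s] %s: %d -> %d", stage, what, n_before, n_after))
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, filter = what, n_before = n_before,
      n_after = n_after, stringsAsFactors = FALSE)
  }
  fail <- function(stage, msg) stop("stage '", stage, "': ", msg,
                                    call. = FALSE)

  # ---- inputs ----
  if (inherits(x, "synth_config")) {
    ds <- synth_dataset(x)
    lineages <- gen_lineages(ds)
    seed <- x$seed
  } else if (is.list(x)) {
    ab <- read_abundance(x$abundance)
    samples <- read_samples(x$samples)
    ds <- list(abundance = ab, samples = samples,
               tree = read_tree(x$tree),
               annotations = read_annotations(x$annotations),
               pathways = read_pathways(x$pathways),
               network = list(
                 viral_pico = NULL,
                 euk = lapply(x$euk, read_abundance),
                 similarity = read_similarity(x$similarity),
                 euk_taxa = with(utils::read.delim(x$euk_taxa),
                                 stats::setNames(taxon, eukaryote_id))))
    pico <- ds$samples$sample_id[ds$samples$size_fraction == "Pico"]
    ds$network$viral_pico <- rpkm_matrix(
      ds$abundance$rpkm[, intersect(colnames(ds$abundance$rpkm), pico),
                        drop = FALSE])
    lineages <- if (!is.null(x$lineages)) utils::read.delim(x$lineages)
      else NULL
    seed <- x$seed %||% 1
  } else stop("x must be a synth_config or a list of input paths")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(log = NULL)
  tables <- list()

  samples <- ds$samples
  has_temp <- "temperature" %in% names(samples) &&
    any(!is.na(samples$temperature))
  if (!has_temp) warning("no temperatures available: running latitude-only")
  env_t <- if (has_temp)
    samples$temperature[match(colnames(ds$abundance$rpkm),
                              samples$sample_id)] else
    rep(NA_real_, ncol(ds$abundance$rpkm))
  env_l <- abs(samples$latitude[match(colnames(ds$abundance$rpkm),
                                      samples$sample_id)])
  biome2 <- ifelse(samples$biome == "Polar", "Polar", "Nonpolar")
  partition <- stats::setNames(biome2, samples$sample_id)

  # ---- community ----
  if ("community" %in% only) {
    div <- diversity_indices(ds$abundance)
    keep <- filter_samples_for_composition(ds$abundance)
    note("community", "composition sample filter",
         ncol(ds$abundance$rpkm), length(keep))
    sub <- rpkm_matrix(ds$abundance$rpkm[, keep, drop = FALSE],
                       ds$abundance$detected[, keep, drop = FALSE])
    d <- bray_curtis(sub)
    g4 <- samples$biome[match(keep, samples$sample_id)]
    g2 <- ifelse(g4 == "Polar", "Polar", "Nonpolar")
    an4 <- if (length(unique(g4)) >= 2 && all(table(g4) >= 2))
      anosim_test(d, g4, n_perm, seed = seed) else NULL
    an2 <- if (length(unique(g2)) == 2 && all(table(g2) >= 2))
      anosim_test(d, g2, n_perm, seed = seed) else NULL
    res$community <- list(diversity = div, retained = keep,
                          anosim_biome = an4, anosim_polar = an2)
    tables$diversity <- div
    tables$anosim <- data.frame(
      grouping = c("biome4", "polar2"),
      R = c(an4$R %||% NA, an2$R %||% NA),
      p = c(an4$p %||% NA, an2$p %||% NA))
  }

  # ---- niche ----
  if ("niche" %in% only) {
    gn <- assign_binary_niche(ds$abundance, partition, alpha)
    opt_t <- if (has_temp)
      robust_optima(ds$abundance, env_t, "temperature", niche_cfg) else NULL
    opt_l <- robust_optima(ds$abundance, env_l, "abs_latitude", niche_cfg)
    si <- vapply(seq_len(nrow(ds$abundance$rpkm)), function(i)
      size_index(ds$abundance$rpkm[i, ],
                 samples$size_fraction[match(colnames(ds$abundance$rpkm),
                                             samples$sample_id)]),
      numeric(1))
    genome_niche <- data.frame(
      genome_id = gn$entity_id, label = gn$label, rule = gn$rule,
      p_bh = gn$p_bh,
      temp_q2 = if (has_temp) opt_t$q2 else NA_real_,
      lat_q2 = opt_l$q2, size_index = si, stringsAsFactors = FALSE)
    ko_niche <- family_niches(ds$annotations, ds$abundance, samples,
                              "ko_id", niche_cfg)
    note("niche", "KO eligibility (> 4 genomes)",
         nrow(ko_niche), sum(ko_niche$eligible))
    gcc_niche <- family_niches(ds$annotations, ds$abundance, samples,
                               "gcc_id", niche_cfg)
    res$niche <- list(genome = genome_niche, ko = ko_niche,
                      gcc = gcc_niche)
    tables$genome_niche <- genome_niche
    tables$ko_niche <- ko_niche
    tables$gcc_niche <- gcc_niche
  }

  # ---- phylo ----
  if ("phylo" %in% only) {
    if (is.null(res$niche)) fail("phylo", "needs the niche stage")
    labels <- stats::setNames(res$niche$genome$label,
                              res$niche$genome$genome_id)
    keep_tips <- names(labels)[labels %in% c("Polar", "Nonpolar")]
    keep_tips <- intersect(ds$tree$tip.label, keep_tips)
    note("phylo", "tips with Polar/Nonpolar labels",
         length(ds$tree$tip.label), length(keep_tips))
    if (length(keep_tips) < 3) fail("phylo", "too few labeled tips")
    tr <- ape::drop.tip(ds$tree, setdiff(ds$tree$tip.label, keep_tips))
    tr <- name_internal_nodes(tr)
    fit <- fit_er(tr, labels[keep_tips])
    trans <- count_transitions(fit)
    red <- red_values(tr)
    # per-KO phylogenetic signal (0/1 presence) and PD ratios
    ann_ko <- ds$annotations[!is.na(ds$annotations$ko_id), ]
    pres <- split(ann_ko$genome_id, ann_ko$ko_id)
    pres <- lapply(pres, unique)
    eligible <- res$niche$ko$family_id[res$niche$ko$eligible]
    lam <- lambda_signal_batch(tr, pres[intersect(names(pres), eligible)])
    pd <- do.call(rbind, lapply(names(pres), function(f) {
      memb <- intersect(pres[[f]], tr$tip.label)
      if (!length(memb)) return(NULL)
      r <- pd_ratio(tr, memb, labels)
      data.frame(family_id = f, pd_total = faith_pd(tr, memb),
                 pd_polar = r$pd_polar, pd_nonpolar = r$pd_nonpolar,
                 ratio = r$ratio, stringsAsFactors = FALSE)
    }))
    res$phylo <- list(tree = tr, fit = fit, transitions = trans,
                      red = red, lambda = lam, pd = pd)
    tables$er_fit <- data.frame(q_hat = fit$q_hat, loglik = fit$loglik,
                                n_to_p = trans$n_to_p,
                                p_to_n = trans$p_to_n)
    tables$node_states <- data.frame(node = names(fit$node_states),
                                     state = unname(fit$node_states))
    tables$transitions <- trans$events
    tables$red <- data.frame(node = names(red), red = unname(red))
    tables$lambda <- lam
    tables$pd <- pd
  }

  # ---- network ----
  if ("network" %in% only) {
    net <- ds$network
    covariate <- stats::setNames(samples$temperature, samples$sample_id)
    edge_lists <- list()
    for (f in names(net$euk)) {
      prep <- preprocess_network(net$viral_pico, net$euk[[f]], net_cfg)
      note("network", sprintf("%s: viral MAGs with >= %d observations",
                              f, net_cfg$min_observations),
           prep$n_viral_in, prep$n_viral_out)
      edge_lists[[f]] <- score_associations(prep, f, net_cfg, covariate)
    }
    pooled <- pool_best_edges(edge_lists)
    note("network", "edges pooled to one per pair",
         sum(vapply(edge_lists, nrow, 0L)), nrow(pooled))
    supp <- edge_support_test(pooled, net$similarity, net_cfg)
    pred <- tim_predict(ds$tree, pooled, net$euk_taxa, alpha)
    res$network <- list(edges = pooled, support = supp,
                        predictions = pred,
                        hosts = host_predictions(pred))
    tables$edges_pooled <- pooled
    tables$host_predictions <- as.data.frame(res$network$hosts)
    tables$edge_support <- data.frame(
      p = supp$p, median_strong = supp$median_strong,
      median_other = supp$median_other, n_strong = supp$n_strong,
      n_other = supp$n_other)
  }

  # ---- enrichment ----
  if ("enrichment" %in% only) {
    if (is.null(res$niche)) fail("enrichment", "needs the niche stage")
    labels <- stats::setNames(res$niche$genome$label,
                              res$niche$genome$genome_id)
    ann_ko <- ds$annotations[!is.na(ds$annotations$ko_id), ]
    pres <- lapply(split(ann_ko$ko_id, ann_ko$genome_id), unique)
    polar_kos <- res$niche$ko$family_id[res$niche$ko$class ==
                                          "Polar-specific"]
    line_enr <- if (!is.null(lineages))
      lineage_enrichment(labels, pres, lineages, alpha) else NULL
    ko_counts <- table(unique(ann_ko[, c("genome_id", "ko_id")])$ko_id)
    ko_counts <- stats::setNames(as.integer(ko_counts), names(ko_counts))
    pw_enr <- pathway_enrichment(polar_kos, ds$pathways, ko_counts,
                                 alpha = alpha)
    gpf <- genome_polar_fraction(ds$annotations, polar_kos, labels)
    res$enrichment <- list(lineage = line_enr, pathway = pw_enr,
                           genome_fraction = gpf)
    if (!is.null(line_enr)) tables$lineage_enrichment <- line_enr
    if (!is.null(pw_enr)) tables$pathway_enrichment <- pw_enr
    tables$genome_polar_fraction <- gpf$fractions
  }

  res$log <- do.call(rbind, log) %||% data.frame()
  tables$run_log <- res$log
  res$manifest <- write_results(tables, out_dir)
  invisible(res)
}
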