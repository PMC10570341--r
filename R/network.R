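# Virus-eukaryote co-occurrence network: preprocessing, association
# scoring (pluggable), best-edge pooling, edge-support similarity test,
# and phylogeny-guided host prediction by clade enrichment.

#' Network configuration
#'
#' @param pseudo_count Added to all cells before the log-ratio transform
#'   (default 1; must be > 0 because zero cannot be log-transformed).
#' @param min_observations Entities detected in fewer samples are removed
#'   (default 3).
#' @param alpha Significance level for association retention
#'   (default 0.01).
#' @param strong_edge_weight |weight| threshold defining a strong
#'   association (default 0.4).
#' @param scorer `"clr_pearson"` (default), `"clr_pearson_detrended"`
#'   (clr-Pearson on residuals after removing a quadratic trend in a
#'   per-sample covariate, typically temperature — a stand-in for
#'   conditional-independence inference that strips indirect edges
#'   created by a shared environmental driver), or a function
#'   `f(viral_t, euk_t)` returning a data frame with virus_id,
#'   eukaryote_id, weight in \[-1, 1\] and p_value (the plugin contract).
#' @return List of class `network_config`.
#' @export
network_config <- function(pseudo_count = 1, min_observations = 3,
                           alpha = 0.01, strong_edge_weight = 0.4,
                           scorer = "clr_pearson") {
  stopifnot(pseudo_count > 0, min_observations >= 0,
            alpha > 0, alpha < 1, strong_edge_weight >= 0)
  if (!is.function(scorer))
    scorer <- match.arg(scorer, c("clr_pearson", "clr_pearson_detrended"))
  structure(as.list(environment()), class = "network_config")
}

# centered log-ratio per sample column within one block of entities
clr_block <- function(m, pseudo) {
  lm <- log(m + pseudo)
  sweep(lm, 2, colMeans(lm))
}

#' Pair and clr-transform viral and eukaryote matrices
#'
#' Intersects the sample sets of the two matrices, removes entities
#' detected in fewer than `min_observations` of the shared samples, adds
#' the pseudo-count and applies the centered log-ratio transform per
#' sample — separately within the viral block and within the eukaryotic
#' block.
#'
#' @param viral,euk [rpkm_matrix()] objects (viral Pico fraction; one
#'   eukaryote size fraction).
#' @param cfg A [network_config()].
#' @return List: `viral_t`, `euk_t` (clr matrices over shared samples),
#'   `samples`, and the filter tallies `n_viral_in/out`, `n_euk_in/out`.
#' @export
preprocess_network <- function(viral, euk, cfg = network_config()) {
  stopifnot(inherits(viral, "rpkm_matrix"), inherits(euk, "rpkm_matrix"))
  shared <- intersect(colnames(viral$rpkm), colnames(euk$rpkm))
  if (!length(shared)) stop("empty sample intersection")
  keep_v <- rowSums(viral$detected[, shared, drop = FALSE]) >=
    cfg$min_observations
  keep_e <- rowSums(euk$detected[, shared, drop = FALSE]) >=
    cfg$min_observations
  lv <- log(viral$rpkm[keep_v, shared, drop = FALSE] + cfg$pseudo_count)
  le <- log(euk$rpkm[keep_e, shared, drop = FALSE] + cfg$pseudo_count)
  list(viral_t = sweep(lv, 2, colMeans(lv)),
       euk_t = sweep(le, 2, colMeans(le)),
       viral_mean = colMeans(lv), euk_mean = colMeans(le),
       samples = shared,
       n_viral_in = nrow(viral$rpkm), n_viral_out = sum(keep_v),
       n_euk_in = nrow(euk$rpkm), n_euk_out = sum(keep_e))
}

#' Score virus-eukaryote associations
#'
#' Default scorer: Pearson correlation between each virus-eukaryote pair
#' of clr vectors; the weight is r (in \[-1, 1\]) and pairs are kept when
#' the two-sided correlation-test p is below `alpha`. Any scorer
#' honouring the plugin contract (see [network_config()]) may be
#' substituted for the default. Pairs with fewer than 3 shared samples
#' are skipped.
#'
#' @param prep Result of [preprocess_network()].
#' @param size_fraction Label recorded on the produced edges.
#' @param cfg A [network_config()].
#' @param covariate Optional named numeric per-sample covariate
#'   (temperature) used by the detrended scorer; samples with a missing
#'   value are dropped for scoring.
#' @return Edge-list data frame: virus_id, eukaryote_id, weight,
#'   size_fraction, p_value.
#' @export
score_associations <- function(prep, size_fraction = "Piconano",
                               cfg = network_config(), covariate = NULL) {
  if (is.function(cfg$scorer)) {
    ed <- cfg$scorer(prep$viral_t, prep$euk_t)
    ed <- ed[ed$p_value < cfg$alpha, , drop = FALSE]
    if (any(abs(ed$weight) > 1)) stop("plugin scorer weight outside [-1, 1]")
    ed$size_fraction <- size_fraction
    return(ed[, c("virus_id", "eukaryote_id", "weight", "size_fraction",
                  "p_value")])
  }
  V <- prep$viral_t; E <- prep$euk_t
  df_lost <- 0
  if (identical(cfg$scorer, "clr_pearson_detrended")) {
    if (is.null(covariate)) stop("detrended scorer needs a covariate")
    cv <- covariate[colnames(V)]
    keep <- !is.na(cv)
    V <- V[, keep, drop = FALSE]; E <- E[, keep, drop = FALSE]
    # nuisance design: quadratic trend in the covariate plus the two
    # block log-means (the clr offsets, which tie together entities
    # that are jointly absent from a sample)
    X <- cbind(1, cv[keep], cv[keep]^2,
               prep$viral_mean[keep], prep$euk_mean[keep])
    Q <- qr.Q(qr(X))
    detrend <- function(M) M - (M %*% Q) %*% t(Q)
    V <- detrend(V); E <- detrend(E)
    # latent-factor adjustment: remove the leading shared-variation axes
    # of the viral residual block from both blocks, so community-wide
    # co-variation a smooth covariate trend cannot capture (e.g. the
    # detection envelope of a whole niche group) does not generate
    # indirect edges
    k <- min(5, nrow(V) - 1, ncol(V) - ncol(X) - 3)
    if (k > 0) {
      # row-standardised input so broad community axes dominate the
      # factor basis rather than a few high-variance entities
      Vz <- t(scale(t(V)))
      Vz <- Vz[!apply(Vz, 1, anyNA), , drop = FALSE]
      pcs <- svd(Vz, nu = 0, nv = k)$v
      V <- V - (V %*% pcs) %*% t(pcs)
      E <- E - (E %*% pcs) %*% t(pcs)
    } else k <- 0
    df_lost <- ncol(X) - 1 + k
  }
  if (ncol(V) < 3 + df_lost) {
    return(data.frame(virus_id = character(0), eukaryote_id = character(0),
                      weight = numeric(0), size_fraction = character(0),
                      p_value = numeric(0)))
  }
  n <- ncol(V)
  # all pairwise Pearson correlations at once
  Vs <- t(scale(t(V))); Es <- t(scale(t(E)))
  ok_v <- !apply(Vs, 1, anyNA); ok_e <- !apply(Es, 1, anyNA)
  R <- (Vs[ok_v, , drop = FALSE] %*% t(Es[ok_e, , drop = FALSE])) / (n - 1)
  R <- pmin(pmax(R, -1), 1)
  df <- n - 2 - df_lost
  tstat <- R * sqrt(df / pmax(1 - R^2, 1e-15))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  idx <- which(p < cfg$alpha, arr.ind = TRUE)
  data.frame(virus_id = rownames(R)[idx[, 1]],
             eukaryote_id = colnames(R)[idx[, 2]],
             weight = R[idx], size_fraction = size_fraction,
             p_value = p[idx], stringsAsFactors = FALSE)
}

#' Pool edges across size fractions, keeping the best per pair
#'
#' For every (virus, eukaryote) pair seen in any input list, keeps the
#' single edge with the highest absolute weight (best positive or
#' negative association); ties go to the later fraction in the input
#' order. Order-invariant in the set of input edges.
#'
#' @param edge_lists List of edge-list data frames.
#' @return One integrated edge-list data frame, one row per pair.
#' @export
pool_best_edges <- function(edge_lists) {
  stopifnot(length(edge_lists) >= 1)
  all_e <- do.call(rbind, edge_lists)
  if (!nrow(all_e)) return(all_e)
  frac_idx <- match(all_e$size_fraction, SIZE_FRACTIONS)
  key <- paste(all_e$virus_id, all_e$eukaryote_id, sep = "\r")
  ord <- order(key, -abs(all_e$weight), -frac_idx)
  all_e <- all_e[ord, , drop = FALSE]
  out <- all_e[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Do strongly associated pairs share more similar proteins?
#'
#' Two-sided Mann-Whitney (rank-sum) test comparing the maximum protein
#' identity of virus-eukaryote pairs with a strong association
#' (|weight| >= `strong_edge_weight`) against all other pairs in the
#' similarity table.
#'
#' @param edges Pooled edge-list data frame.
#' @param sims Similarity data frame (virus_id, eukaryote_id,
#'   max_protein_identity).
#' @param cfg A [network_config()].
#' @return List: `p`, `median_strong`, `median_other`, `n_strong`,
#'   `n_other`, `testable`.
#' @export
edge_support_test <- function(edges, sims, cfg = network_config()) {
  strong <- edges[abs(edges$weight) >= cfg$strong_edge_weight, ]
  key_s <- paste(strong$virus_id, strong$eukaryote_id)
  key_all <- paste(sims$virus_id, sims$eukaryote_id)
  is_strong <- key_all %in% key_s
  a <- sims$max_protein_identity[is_strong]
  b <- sims$max_protein_identity[!is_strong]
  if (length(a) < 2 || length(b) < 2) {
    return(list(p = NA_real_, median_strong = stats::median(a),
                median_other = stats::median(b), n_strong = length(a),
                n_other = length(b), testable = FALSE))
  }
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  list(p = p, median_strong = stats::median(a),
       median_other = stats::median(b), n_strong = length(a),
       n_other = length(b), testable = TRUE)
}

#' Phylogeny-guided host prediction by clade enrichment
#'
#' Maps pooled virus-eukaryote associations onto the viral tree and, for
#' every internal node and every host taxon with at least one
#' association, builds the 2x2 table over edge-bearing viral leaves —
#' (under the node vs not) x (>= 1 edge to the taxon vs none) — and runs
#' a one-sided (enrichment) Fisher's exact test. BH correction is
#' applied jointly over all (node, taxon) tests. Significant nodes are
#' pruned so only the most specific clade per taxon survives: a node is
#' dropped when one of its descendants is significant for the same taxon
#' with a smaller (or equal) p. Viral leaves without any edge carry no
#' association information and are excluded from the tables.
#'
#' @param tree Rooted viral `phylo` tree (leaves cover the edge viruses).
#' @param edges Pooled edge-list data frame.
#' @param euk_taxa Named character eukaryote_id -> taxon.
#' @param alpha Significance level on BH-corrected p (default 0.05).
#' @param min_bearing Minimum number of edge-bearing leaves under a node
#'   for it to be tested (default 5): host prediction is clade-level, and
#'   tiny leaf sets cannot support a stable enrichment call.
#' @param min_taxon_leaves Minimum number of edge-bearing leaves linked
#'   to a taxon for that taxon to be testable at all (default 5),
#'   excluding sparse taxa whose few edges cannot support an enrichment
#'   call (the same rationale as excluding rare families from
#'   enrichment analyses).
#' @return Data frame (class `host_predictions`): node, taxon, a, b, c,
#'   d (contingency counts), p_raw, p_bh, significant, pruned,
#'   member_genomes (comma-joined leaves under the node).
#' @export
tim_predict <- function(tree, edges, euk_taxa, alpha = 0.05,
                        min_bearing = 5, min_taxon_leaves = 5) {
  if (!all(edges$virus_id %in% tree$tip.label))
    stop("edges contain viruses absent from the tree")
  n_tip <- length(tree$tip.label)
  edge_taxon <- unique(data.frame(
    virus_id = edges$virus_id,
    taxon = unname(euk_taxa[edges$eukaryote_id]),
    stringsAsFactors = FALSE))
  bearing <- unique(edge_taxon$virus_id)
  taxa <- names(which(table(edge_taxon$taxon) >= min_taxon_leaves))
  if (!length(bearing) || !length(taxa)) {
    return(structure(data.frame(), class = c("host_predictions",
                                             "data.frame")))
  }
  has_taxon <- sapply(taxa, function(tx)
    bearing %in% edge_taxon$virus_id[edge_taxon$taxon == tx])
  dim(has_taxon) <- c(length(bearing), length(taxa))
  rownames(has_taxon) <- bearing; colnames(has_taxon) <- taxa
  rows <- list()
  for (i in seq_len(tree$Nnode)) {
    node_lab <- tree$node.label[i]
    under <- intersect(tips_under(tree, n_tip + i), bearing)
    if (length(under) < min_bearing || length(under) == length(bearing)) next
    in_clade <- bearing %in% under
    for (tx in taxa) {
      a <- sum(in_clade & has_taxon[, tx])
      if (a < min_taxon_leaves) next
      b <- sum(in_clade & !has_taxon[, tx])
      # a clade-level host call must describe the clade: skip taxa
      # linked to fewer than half of the clade's edge-bearing leaves
      if (a < b) next
      cc <- sum(!in_clade & has_taxon[, tx])
      d <- sum(!in_clade & !has_taxon[, tx])
      p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                              alternative = "greater")$p.value
      rows[[length(rows) + 1]] <- data.frame(
        node = node_lab, taxon = tx, a = a, b = b, c = cc, d = d,
        p_raw = p, member_genomes = paste(under, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(structure(data.frame(), class = c("host_predictions",
                                             "data.frame")))
  }
  out$p_bh <- bh_adjust(out$p_raw)
  out$significant <- out$p_bh < alpha
  # most-specific-clade pruning per taxon
  out$pruned <- FALSE
  node_idx <- match(out$node, tree$node.label) + n_tip
  desc_cache <- lapply(seq_len(tree$Nnode), function(i)
    tips_under(tree, n_tip + i))
  for (r in which(out$significant)) {
    tips_r <- desc_cache[[node_idx[r] - n_tip]]
    for (s in which(out$significant & out$taxon == out$taxon[r])) {
      if (s == r) next
      tips_s <- desc_cache[[node_idx[s] - n_tip]]
      nested <- length(tips_s) < length(tips_r) && all(tips_s %in% tips_r)
      if (nested && out$p_raw[s] <= out$p_raw[r]) out$pruned[r] <- TRUE
    }
  }
  rownames(out) <- NULL
  class(out) <- c("host_predictions", "data.frame")
  out
}

#' Significant host predictions after pruning
#' @param pred Result of [tim_predict()].
#' @return The subset of significant, unpruned rows.
#' @export
host_predictions <- function(pred) {
  if (!nrow(pred)) return(pred)
  out <- pred[pred$significant & !pred$pruned, , drop = FALSE]
  rownames(out) <- NULL
  out
}
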