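# Polar-KO lineage enrichment, pathway enrichment, and genome-level
# polar-fraction comparisons.

#' KO enrichment in Polar genomes within lineages
#'
#' For each lineage at the requested taxonomic levels (root, main group,
#' family, genus) and each KO present in it, tests enrichment of the KO
#' in the lineage's Polar versus Nonpolar genomes (one-sided Fisher's
#' exact test on the presence table), with BH correction over the whole
#' batch. Genomes labelled other than Polar/Nonpolar are excluded;
#' lineages lacking either class are skipped.
#'
#' @param niche_labels Named character genome -> label.
#' @param ko_presence Named list genome -> character vector of KOs.
#' @param lineages Data frame: genome_id, main_group, family, genus
#'   (levels may be NA). The "root" level spans all genomes.
#' @param alpha Significance level on BH-corrected p (default 0.05).
#' @return Data frame: level, lineage, ko_id, polar_with, polar_without,
#'   nonpolar_with, nonpolar_without, p_raw, p_bh, significant.
#' @export
lineage_enrichment <- function(niche_labels, ko_presence, lineages,
                               alpha = 0.05) {
  keep <- names(niche_labels)[niche_labels %in% c("Polar", "Nonpolar")]
  rows <- list()
  lineages <- lineages[lineages$genome_id %in% keep, , drop = FALSE]
  lineages$root <- "root"
  for (level in c("root", "main_group", "family", "genus")) {
    if (!level %in% names(lineages)) next
    for (lin in unique(stats::na.omit(lineages[[level]]))) {
      g <- lineages$genome_id[!is.na(lineages[[level]]) &
                                lineages[[level]] == lin]
      pol <- g[niche_labels[g] == "Polar"]
      non <- g[niche_labels[g] == "Nonpolar"]
      if (!length(pol) || !length(non)) next
      kos <- unique(unlist(ko_presence[g]))
      for (ko in kos) {
        pw <- sum(vapply(pol, function(x) ko %in% ko_presence[[x]], TRUE))
        nw <- sum(vapply(non, function(x) ko %in% ko_presence[[x]], TRUE))
        tab <- matrix(c(pw, length(pol) - pw, nw, length(non) - nw),
                      2, byrow = TRUE)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        rows[[length(rows) + 1]] <- data.frame(
          level = level, lineage = lin, ko_id = ko,
          polar_with = pw, polar_without = length(pol) - pw,
          nonpolar_with = nw, nonpolar_without = length(non) - nw,
          p_raw = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_bh <- bh_adjust(out$p_raw)
  out$significant <- out$p_bh < alpha
  out
}

#' Pathway enrichment with Polar-specific KOs
#'
#' Applies the study's filtering rules: (1) KOs observed in fewer than
#' `min_ko_genomes` genomes are dropped; (2) a pathway is a candidate if
#' at least half of its detected KOs are polar-specific; (3) a pathway is
#' displayed only if its detected KOs exceed 10% of its total KO count;
#' (4) for each candidate, a one-sided Fisher test compares the
#' polar-specific fraction of the pathway's detected KOs against all
#' other pathways' detected KOs, with BH correction.
#'
#' @param polar_kos Character vector of polar-specific KO ids.
#' @param pathways Long-format pathway map (pathway_id, name, category,
#'   ko_id).
#' @param ko_genome_counts Named integer: genomes per KO (for the rare-KO
#'   filter).
#' @param detected_kos KOs detected in the dataset at all.
#' @param min_ko_genomes Rare-KO cutoff (default 5: keep KOs observed in
#'   at least five genomes).
#' @param alpha Significance level on BH-corrected p (default 0.05).
#' @return Data frame: pathway_id, name, n_total_kos, n_detected_kos,
#'   n_polar_kos, polar_ratio, candidate, displayed, p_raw, p_bh,
#'   significant.
#' @export
pathway_enrichment <- function(polar_kos, pathways, ko_genome_counts,
                               detected_kos = names(ko_genome_counts),
                               min_ko_genomes = 5, alpha = 0.05) {
  usable <- intersect(detected_kos,
                      names(ko_genome_counts)[ko_genome_counts >=
                                                min_ko_genomes])
  pw_ids <- unique(pathways$pathway_id)
  info <- lapply(pw_ids, function(pw) {
    member <- pathways$ko_id[pathways$pathway_id == pw]
    det <- intersect(member, usable)
    pol <- intersect(det, polar_kos)
    list(pw = pw, name = pathways$name[pathways$pathway_id == pw][1],
         total = length(unique(member)), det = det, pol = pol)
  })
  info <- Filter(function(x) length(x$det) > 0, info)
  rows <- lapply(info, function(x) {
    n_det <- length(x$det); n_pol <- length(x$pol)
    other_det <- setdiff(unlist(lapply(info, `[[`, "det")), x$det)
    other_pol <- intersect(other_det, polar_kos)
    candidate <- n_pol >= n_det / 2
    p <- if (candidate) {
      tab <- matrix(c(n_pol, n_det - n_pol,
                      length(other_pol), length(other_det) - length(other_pol)),
                    2, byrow = TRUE)
      stats::fisher.test(tab, alternative = "greater")$p.value
    } else NA_real_
    data.frame(pathway_id = x$pw, name = x$name, n_total_kos = x$total,
               n_detected_kos = n_det, n_polar_kos = n_pol,
               polar_ratio = n_pol / n_det, candidate = candidate,
               displayed = n_det > 0.1 * x$total, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_bh <- NA_real_
  out$p_bh[out$candidate] <- bh_adjust(out$p_raw[out$candidate])
  out$significant <- !is.na(out$p_bh) & out$p_bh < alpha
  out
}

# Dunn's post-hoc pairwise z tests on rank sums after Kruskal-Wallis,
# with the standard tie correction.
dunn_pairwise <- function(values, groups) {
  groups <- as.character(groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  levs <- sort(unique(groups))
  mean_rk <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  out <- list()
  for (i in seq_along(levs)[-length(levs)]) {
    for (j in (i + 1):length(levs)) {
      a <- levs[i]; b <- levs[j]
      se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
      z <- (mean_rk[a] - mean_rk[b]) / se
      out[[length(out) + 1]] <- data.frame(
        group1 = a, group2 = b, z = unname(z),
        p_raw = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_bh <- bh_adjust(res$p_raw)
  res
}

#' Per-genome polar-KO fraction and its comparison across niche groups
#'
#' For every genome with at least one KO-annotated gene, the fraction of
#' those genes whose KO is polar-specific; groups (Polar, Nonpolar,
#' Unknown) are compared with a Kruskal-Wallis test followed by pairwise
#' Dunn z tests with BH correction. Flagged untestable when any group
#' has fewer than 2 genomes.
#'
#' @param annotations Annotation data frame (gene_id, genome_id, ko_id).
#' @param polar_kos Character vector of polar-specific KO ids.
#' @param niche_labels Named character genome -> label.
#' @return List: `fractions` (data frame genome_id, label, n_ko_genes,
#'   polar_fraction), `kruskal` (statistic, p), `dunn` (pairwise data
#'   frame or NULL), `testable`.
#' @export
genome_polar_fraction <- function(annotations, polar_kos, niche_labels) {
  ann <- annotations[!is.na(annotations$ko_id), , drop = FALSE]
  spl <- split(ann$ko_id, ann$genome_id)
  fr <- data.frame(
    genome_id = names(spl),
    label = unname(niche_labels[names(spl)]),
    n_ko_genes = lengths(spl),
    polar_fraction = vapply(spl, function(k) mean(k %in% polar_kos), 0),
    stringsAsFactors = FALSE)
  fr <- fr[!is.na(fr$label), , drop = FALSE]
  tab <- table(fr$label)
  testable <- length(tab) >= 2 && all(tab >= 2)
  kw <- NULL; dunn <- NULL
  if (testable) {
    k <- stats::kruskal.test(fr$polar_fraction, factor(fr$label))
    kw <- list(statistic = unname(k$statistic), p = k$p.value)
    dunn <- dunn_pairwise(fr$polar_fraction, fr$label)
  }
  list(fractions = fr, kruskal = kw, dunn = dunn, testable = testable)
}
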