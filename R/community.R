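# Community diversity and compositional-difference statistics.

#' Per-sample diversity indices
#'
#' Richness (number of detected entities), Shannon's index (nats, over
#' detected entities' relative RPKM) and Pielou's evenness
#' (Shannon / ln richness). Shannon and Pielou are NA-flagged when
#' undefined (richness 0, and richness <= 1 for Pielou).
#'
#' @param x An [rpkm_matrix()].
#' @return Data frame: sample_id, richness, shannon, pielou.
#' @export
diversity_indices <- function(x) {
  stopifnot(inherits(x, "rpkm_matrix"))
  out <- lapply(seq_len(ncol(x$rpkm)), function(j) {
    v <- x$rpkm[x$detected[, j], j]
    rich <- length(v)
    if (rich == 0) return(c(rich, NA_real_, NA_real_))
    p <- v / sum(v)
    h <- -sum(p * log(p))
    c(rich, h, if (rich > 1) h / log(rich) else NA_real_)
  })
  out <- do.call(rbind, out)
  data.frame(sample_id = colnames(x$rpkm), richness = as.integer(out[, 1]),
             shannon = out[, 2], pielou = out[, 3],
             stringsAsFactors = FALSE)
}

#' Filter samples before compositional analyses
#'
#' Keeps samples whose total RPKM is at least `min_total` and whose
#' richness is at least `min_richness` (low-signal samples produce
#' ordination outliers).
#'
#' @param x An [rpkm_matrix()].
#' @param min_total Minimum cumulative RPKM (default 10).
#' @param min_richness Minimum number of detected entities (default 5).
#' @return Character vector of retained sample ids (warns if empty).
#' @export
filter_samples_for_composition <- function(x, min_total = 10,
                                           min_richness = 5) {
  stopifnot(inherits(x, "rpkm_matrix"))
  keep <- colSums(x$rpkm) >= min_total & colSums(x$detected) >= min_richness
  if (!any(keep)) warning("no samples pass the composition filter")
  colnames(x$rpkm)[keep]
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(a, b) = sum |x - y| / sum (x + y), symmetric with zero diagonal,
#' in \[0, 1\]. A pair of all-zero samples gets distance 0.
#'
#' @param x An [rpkm_matrix()].
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "rpkm_matrix"))
  m <- t(x$rpkm)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(m[i, ] + m[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else
        sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  stats::as.dist(d)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between- versus within-group community
#' dissimilarity: R = (mean between-group rank - mean within-group rank) /
#' (M / 2), with M = n(n-1)/2 and average ranks for ties. The permutation
#' p-value uses the +1 correction, p = (1 + #\{permuted R >= observed\}) /
#' (1 + n_perm), and is deterministic under a fixed seed.
#'
#' @param d A `dist` object or symmetric distance matrix over samples.
#' @param groups Group labels, one per sample (each group needs >= 2
#'   members).
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `niche_anosim`: list with `R`, `p`, `n_perm`,
#'   `perm_R` (the permuted statistics).
#' @export
anosim_test <- function(d, groups, n_perm = 9999, seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 members")
  dv <- dm[lower.tri(dm)]
  rk <- rank(dv)            # average ranks for ties
  M <- length(dv)
  idx <- which(lower.tri(dm), arr.ind = TRUE)
  stat <- function(g) {
    within <- g[idx[, 1]] == g[idx[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  R_obs <- stat(groups)
  set.seed(seed)
  perm_R <- vapply(seq_len(n_perm), function(i) stat(sample(groups)),
                   numeric(1))
  p <- (1 + sum(perm_R >= R_obs)) / (1 + n_perm)
  structure(list(R = R_obs, p = p, n_perm = n_perm, perm_R = perm_R,
                 groups = tab), class = "niche_anosim")
}

#' @export
print.niche_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations; groups: %s)\n",
              x$R, x$p, x$n_perm,
              paste(names(x$groups), x$groups, sep = "=", collapse = ", ")))
  invisible(x)
}
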