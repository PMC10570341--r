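# Robust ecological optimum/tolerance, Polar/Nonpolar niche assignment,
# size index and polar-specific gene-family classification.

#' Niche-estimation configuration
#'
#' @param vector_size Size of the abundance-weighted environmental vector
#'   (default 10000).
#' @param min_nonNA_obs Minimum detected samples with a non-missing
#'   environmental value (default 10).
#' @param min_nonNA_fraction Minimum fraction of non-missing values among
#'   detected samples (default 0.30).
#' @param alpha Significance level for the niche rank-sum tests
#'   (default 0.05, on BH-corrected p).
#' @param polar_temp_cutoff Temperature optimum must be strictly below
#'   this for a polar-specific family (default 10 degrees C).
#' @param polar_lat_cutoff Absolute-latitude optimum must be strictly
#'   above this (default 50 degrees).
#' @return List of class `niche_config`.
#' @export
niche_config <- function(vector_size = 10000, min_nonNA_obs = 10,
                         min_nonNA_fraction = 0.30, alpha = 0.05,
                         polar_temp_cutoff = 10, polar_lat_cutoff = 50) {
  stopifnot(vector_size >= 1, min_nonNA_obs >= 0,
            min_nonNA_fraction >= 0, min_nonNA_fraction <= 1,
            alpha > 0, alpha < 1,
            polar_temp_cutoff > 0, polar_lat_cutoff > 0)
  structure(as.list(environment()), class = "niche_config")
}

#' Largest-remainder allocation of a weighted vector
#'
#' Apportions `size` slots among values proportionally to `weights`:
#' each value gets floor(weight * size) slots, and the remaining slots go
#' to the largest fractional remainders (ties broken by input order).
#' The counts always sum to `size` exactly.
#'
#' @param weights Non-negative weights summing to 1 (within 1e-9).
#' @param values Parameter values, same length as `weights`.
#' @param size Total number of slots (default 10000).
#' @return Data frame with `value` and `count`.
#' @export
allocate_weighted_vector <- function(weights, values, size = 10000) {
  if (length(weights) != length(values)) stop("length mismatch")
  if (any(weights < 0)) stop("negative weight")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  exact <- weights * size
  counts <- floor(exact)
  rem <- size - sum(counts)
  if (rem > 0) {
    frac <- exact - counts
    # order(-frac) is stable: ties resolved by input order
    top <- order(-frac)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  data.frame(value = values, count = as.integer(counts))
}

#' Robust ecological optimum and tolerance for one entity
#'
#' Computes the abundance-weighted optimum (Q2) and tolerance range
#' (Q1-Q3) of an environmental parameter: the entity's RPKM proportions
#' over detected samples with a non-missing parameter value populate a
#' fixed-size weighted vector of environmental values, whose median and
#' quartiles (linear-interpolation convention, R quantile type 7) are
#' reported. The result is flagged undefined unless at least
#' `min_nonNA_obs` detected samples have a value and they make up at
#' least `min_nonNA_fraction` of the detected samples.
#'
#' @param rpkm Numeric vector of the entity's RPKM across samples.
#' @param detected Logical vector, same length.
#' @param env Environmental parameter per sample (NA = missing).
#' @param cfg A [niche_config()].
#' @return List: `q1`, `q2`, `q3`, `defined`, `n_obs` (detected non-NA
#'   samples), `frac_nonNA`.
#' @export
robust_optimum <- function(rpkm, detected = rpkm > 0, env,
                           cfg = niche_config()) {
  stopifnot(length(rpkm) == length(env), length(detected) == length(rpkm))
  if (any(rpkm < 0)) stop("negative RPKM")
  det <- which(detected & rpkm > 0)
  usable <- det[!is.na(env[det])]
  n_obs <- length(usable)
  frac <- if (length(det)) n_obs / length(det) else 0
  defined <- n_obs >= cfg$min_nonNA_obs && frac >= cfg$min_nonNA_fraction &&
    sum(rpkm[usable]) > 0
  if (!defined) {
    return(list(q1 = NA_real_, q2 = NA_real_, q3 = NA_real_,
                defined = FALSE, n_obs = n_obs, frac_nonNA = frac))
  }
  w <- rpkm[usable] / sum(rpkm[usable])
  alloc <- allocate_weighted_vector(w, env[usable], cfg$vector_size)
  vec <- rep(alloc$value, alloc$count)
  q <- unname(stats::quantile(vec, c(0.25, 0.5, 0.75), type = 7))
  list(q1 = q[1], q2 = q[2], q3 = q[3], defined = TRUE,
       n_obs = n_obs, frac_nonNA = frac)
}

#' Robust optima for all entities of a matrix
#'
#' Vectorised driver for [robust_optimum()] over the rows of an
#' abundance matrix, for one environmental parameter.
#'
#' @param x An [rpkm_matrix()].
#' @param env Named (or matrix-ordered) parameter values per sample.
#' @param parameter Label stored in the output (e.g. "temperature").
#' @param cfg A [niche_config()].
#' @return Data frame: entity_id, parameter, q1, q2, q3, defined, n_obs.
#' @export
robust_optima <- function(x, env, parameter = "temperature",
                          cfg = niche_config()) {
  stopifnot(inherits(x, "rpkm_matrix"), length(env) == ncol(x$rpkm))
  rows <- lapply(seq_len(nrow(x$rpkm)), function(i) {
    r <- robust_optimum(x$rpkm[i, ], x$detected[i, ], env, cfg)
    data.frame(entity_id = rownames(x$rpkm)[i], parameter = parameter,
               q1 = r$q1, q2 = r$q2, q3 = r$q3, defined = r$defined,
               n_obs = r$n_obs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate a gene family's abundance profile over member genomes
#'
#' The family's per-sample RPKM is the sum of the RPKM of the genomes
#' encoding it; the family is detected wherever any member genome is.
#' Families found in four or fewer genomes are flagged ineligible for
#' niche estimation.
#'
#' @param annotations Annotation data frame (gene_id, genome_id, ko_id,
#'   gcc_id).
#' @param x Genome [rpkm_matrix()].
#' @param family KO or GCC identifier.
#' @param min_genomes A family must occur in more than this many genomes
#'   to be eligible (default 4).
#' @return List: `rpkm`, `detected` (per sample), `n_genomes`,
#'   `eligible`, `members`.
#' @export
gene_family_profile <- function(annotations, x, family, min_genomes = 4) {
  stopifnot(inherits(x, "rpkm_matrix"))
  hit <- !is.na(annotations$ko_id) & annotations$ko_id == family |
    !is.na(annotations$gcc_id) & annotations$gcc_id == family
  if (!any(hit)) stop("unknown family id: ", family)
  members <- unique(annotations$genome_id[hit])
  members <- intersect(members, rownames(x$rpkm))
  sub_r <- x$rpkm[members, , drop = FALSE]
  sub_d <- x$detected[members, , drop = FALSE]
  list(rpkm = colSums(sub_r), detected = colSums(sub_d) > 0,
       n_genomes = length(members), eligible = length(members) > min_genomes,
       members = members)
}

#' Assign binary niche labels (with zero-signal rules and rank-sum tests)
#'
#' For each entity: (1) no detected signal anywhere gives `Undetected`;
#' (2) zero signal in every sample of one class assigns the other class
#' outright; (3) otherwise a two-sided Wilcoxon rank-sum test compares the
#' entity's RPKM between the two classes (all samples of each class, zeros
#' retained), BH correction is applied across all entities reaching this
#' step, and a corrected p below `alpha` assigns the class with the
#' greater mean rank; otherwise `Unknown`.
#'
#' @param x An [rpkm_matrix()].
#' @param partition Named character vector sample_id -> class (exactly two
#'   classes, both non-empty); samples absent from it are ignored.
#' @param alpha Significance level on BH-corrected p (default 0.05).
#' @return Data frame: entity_id, label, p_raw, p_bh, rule
#'   (`undetected`, `zero_rule`, `test`).
#' @export
assign_binary_niche <- function(x, partition, alpha = 0.05) {
  stopifnot(inherits(x, "rpkm_matrix"))
  classes <- sort(unique(unname(partition)))
  if (length(classes) != 2) stop("partition must define exactly two classes")
  sA <- names(partition)[partition == classes[1]]
  sB <- names(partition)[partition == classes[2]]
  sA <- intersect(sA, colnames(x$rpkm))
  sB <- intersect(sB, colnames(x$rpkm))
  if (!length(sA) || !length(sB)) stop("partition covers no samples")
  n <- nrow(x$rpkm)
  label <- character(n); rule <- character(n)
  p_raw <- rep(NA_real_, n)
  side <- character(n)
  for (i in seq_len(n)) {
    a <- x$rpkm[i, sA]; b <- x$rpkm[i, sB]
    det_a <- any(x$detected[i, sA]); det_b <- any(x$detected[i, sB])
    if (!det_a && !det_b) {
      label[i] <- "Undetected"; rule[i] <- "undetected"
    } else if (!det_b) {
      label[i] <- classes[1]; rule[i] <- "zero_rule"
    } else if (!det_a) {
      label[i] <- classes[2]; rule[i] <- "zero_rule"
    } else {
      rule[i] <- "test"
      p_raw[i] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE)$p.value)
      rk <- rank(c(a, b))
      side[i] <- if (mean(rk[seq_along(a)]) > mean(rk[-seq_along(a)]))
        classes[1] else classes[2]
    }
  }
  p_bh <- rep(NA_real_, n)
  tested <- rule == "test"
  p_bh[tested] <- bh_adjust(p_raw[tested])
  label[tested] <- ifelse(!is.na(p_bh[tested]) & p_bh[tested] < alpha,
                          side[tested], "Unknown")
  data.frame(entity_id = rownames(x$rpkm), label = label,
             p_raw = p_raw, p_bh = p_bh, rule = rule,
             stringsAsFactors = FALSE)
}

#' Abundance-weighted size index of a genome
#'
#' Index constants per size fraction (Pico = 1, Piconano & Broad = 2,
#' Nano = 3, Micro = 4, Macro = 5; Piconano and Broad share a constant):
#' the index is sum(RPKM * constant) / sum(RPKM), an indicator of host
#' size range. Undefined (NA) when total RPKM is zero.
#'
#' @param rpkm Entity's RPKM across samples.
#' @param size_fraction Size fraction of each sample.
#' @return Numeric in \[1, 5\], or NA.
#' @export
size_index <- function(rpkm, size_fraction) {
  stopifnot(length(rpkm) == length(size_fraction))
  const <- c(Pico = 1, Piconano = 2, Broad = 2, Nano = 3, Micro = 4,
             Macro = 5)
  if (any(!size_fraction %in% names(const)))
    stop("unknown size fraction")
  tot <- sum(rpkm)
  if (tot == 0) return(NA_real_)
  sum(rpkm * const[size_fraction]) / tot
}

#' Classify a gene family as polar-specific from its optima
#'
#' Polar-specific iff both the temperature and the absolute-latitude
#' optima are defined, the temperature optimum is strictly below
#' `polar_temp_cutoff` and the latitude optimum strictly above
#' `polar_lat_cutoff`. `Ineligible` when either optimum is undefined.
#'
#' @param temp_result,lat_result Results of [robust_optimum()] for
#'   temperature and absolute latitude.
#' @param cfg A [niche_config()].
#' @return One of "Polar-specific", "Other", "Ineligible".
#' @export
classify_polar_family <- function(temp_result, lat_result,
                                  cfg = niche_config()) {
  if (!isTRUE(temp_result$defined) || !isTRUE(lat_result$defined))
    return("Ineligible")
  if (temp_result$q2 < cfg$polar_temp_cutoff &&
      lat_result$q2 > cfg$polar_lat_cutoff) "Polar-specific" else "Other"
}

#' Niche optima and polar classification for all gene families
#'
#' Builds the summed abundance profile of every KO (or GCC) family,
#' computes robust temperature and absolute-latitude optima for eligible
#' families (present in more than `min_genomes` genomes), and classifies
#' each as polar-specific or not.
#'
#' @param annotations Annotation data frame.
#' @param x Genome [rpkm_matrix()].
#' @param samples Sample table (needs `temperature`, `latitude`).
#' @param id_col `"ko_id"` or `"gcc_id"`.
#' @param cfg A [niche_config()].
#' @param min_genomes Eligibility cutoff (default 4: family must be in
#'   more than 4 genomes).
#' @return Data frame with per-family optima (temp_q1..q3, lat_q1..q3),
#'   n_genomes, eligibility and classification.
#' @export
family_niches <- function(annotations, x, samples, id_col = "ko_id",
                          cfg = niche_config(), min_genomes = 4) {
  fams <- sort(unique(stats::na.omit(annotations[[id_col]])))
  env_t <- samples$temperature[match(colnames(x$rpkm), samples$sample_id)]
  env_l <- abs(samples$latitude[match(colnames(x$rpkm), samples$sample_id)])
  rows <- lapply(fams, function(f) {
    pr <- gene_family_profile(annotations, x, f, min_genomes)
    if (!pr$eligible) {
      return(data.frame(family_id = f, n_genomes = pr$n_genomes,
                        eligible = FALSE, temp_q1 = NA, temp_q2 = NA,
                        temp_q3 = NA, lat_q1 = NA, lat_q2 = NA, lat_q3 = NA,
                        class = "Ineligible", stringsAsFactors = FALSE))
    }
    rt <- robust_optimum(pr$rpkm, pr$detected, env_t, cfg)
    rl <- robust_optimum(pr$rpkm, pr$detected, env_l, cfg)
    data.frame(family_id = f, n_genomes = pr$n_genomes, eligible = TRUE,
               temp_q1 = rt$q1, temp_q2 = rt$q2, temp_q3 = rt$q3,
               lat_q1 = rl$q1, lat_q2 = rl$q2, lat_q3 = rl$q3,
               class = classify_polar_family(rt, rl, cfg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
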