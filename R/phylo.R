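# Ancestral niche reconstruction under the two-state equal-rates Markov
# model, transition counting, relative evolutionary divergence (RED),
# Faith's phylogenetic diversity and Pagel's-lambda phylogenetic signal.

STATES <- c("Polar", "Nonpolar")

# 2-state ER transition probabilities: P(stay) = 1/2 + 1/2 exp(-2qt)
er_pmat <- function(q, t) {
  stay <- 0.5 + 0.5 * exp(-2 * q * t)
  matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2)
}

# postorder conditional likelihoods with per-node scaling.
# Returns list(frac = n_all x 2 scaled likelihoods, logscale = per node,
# loglik at the root under the stationary (1/2, 1/2) prior).
er_postorder <- function(tree, tip_states, q) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  L <- matrix(1, n_all, 2)
  logscale <- numeric(n_all)
  st <- tip_states[tree$tip.label]
  if (anyNA(st) || any(!st %in% STATES))
    stop("all tips must be labeled Polar or Nonpolar")
  # column 1 = Nonpolar, column 2 = Polar; a labeled tip has zero
  # likelihood for the state it is not in
  L[cbind(seq_len(n_tip), ifelse(st == "Polar", 1L, 2L))] <- 0
  ord <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  elen <- tree$edge.length[match(paste(ord$edge[, 1], ord$edge[, 2]), key)]
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; chi <- ord$edge[i, 2]
    P <- er_pmat(q, elen[i])
    contrib <- as.vector(P %*% L[chi, ])
    L[par, ] <- L[par, ] * contrib
    logscale[par] <- logscale[par] + logscale[chi]
    s <- sum(L[par, ])
    if (s > 0 && (s < 1e-100 || s > 1e100)) {
      L[par, ] <- L[par, ] / s
      logscale[par] <- logscale[par] + log(s)
    }
  }
  root <- n_tip + 1L
  lik <- sum(0.5 * L[root, ])
  loglik <- if (lik <= 0) -Inf else log(lik) + logscale[root]
  list(L = L, logscale = logscale, loglik = loglik, order = ord, elen = elen)
}

#' Log-likelihood of tip states under the equal-rates model
#'
#' Felsenstein pruning over a rooted, branch-lengthed tree with the
#' two-state equal-rates transition probability P(stay, t) =
#' 1/2 + 1/2 exp(-2qt) and a stationary (1/2, 1/2) root prior. Tips with
#' an Unknown niche must be pruned before calling.
#'
#' @param tree Rooted `phylo` tree.
#' @param tip_states Named character vector, tip label -> Polar/Nonpolar.
#' @param q Switching rate (>= 0) per unit branch length.
#' @return Log-likelihood (may be `-Inf`, e.g. mixed tips at q = 0).
#' @export
er_loglik <- function(tree, tip_states, q) {
  if (q < 0) stop("q must be >= 0")
  er_postorder(tree, tip_states, q)$loglik
}

#' Maximum-likelihood equal-rates fit with marginal ancestral states
#'
#' Maximises the pruning log-likelihood over the switching rate q by
#' bounded one-dimensional optimisation on \[1e-8, 100\] (tolerance 1e-8),
#' then computes marginal ancestral-state posteriors at every internal
#' node by the standard up-down (rerooting-equivalent) pass. Node states
#' are the posterior argmax; exact ties (posterior 1/2) go to Nonpolar
#' and are flagged.
#'
#' @inheritParams er_loglik
#' @param lower,upper Optimisation bounds for q.
#' @return Object of class `er_fit`: `q_hat`, `loglik`,
#'   `node_posteriors` (data frame node/P_Polar/P_Nonpolar),
#'   `node_states` (named character), `tip_states`, `tree`, `n_ties`.
#' @export
fit_er <- function(tree, tip_states, lower = 1e-8, upper = 100) {
  ll <- function(q) er_loglik(tree, tip_states, q)
  # coarse log-spaced scan to bracket the optimum (the surface can hold a
  # narrow interior maximum next to the large-q plateau), then Brent
  grid <- exp(seq(log(lower), log(upper), length.out = 40))
  lls <- vapply(grid, ll, numeric(1))
  if (all(!is.finite(lls))) stop("likelihood is -Inf over the whole range")
  best <- which.max(lls)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  q_hat <- opt$maximum
  if (lls[best] > opt$objective) {   # guard: grid point beat Brent
    q_hat <- grid[best]
    opt$objective <- lls[best]
  }
  post <- er_marginals(tree, tip_states, q_hat)
  states <- ifelse(post[, 1] > post[, 2], "Polar", "Nonpolar")
  names(states) <- rownames(post)
  structure(list(q_hat = q_hat, loglik = opt$objective,
                 node_posteriors = data.frame(
                   node = rownames(post), P_Polar = post[, 1],
                   P_Nonpolar = post[, 2], stringsAsFactors = FALSE),
                 node_states = states, tip_states = tip_states[tree$tip.label],
                 tree = tree,
                 n_ties = sum(abs(post[, 1] - 0.5) < 1e-12)),
            class = "er_fit")
}

# marginal posteriors at internal nodes: up-pass combining the outside
# likelihood G with the inside likelihood L. Order of state columns:
# (Nonpolar, Polar) internally; returned as (P_Polar, P_Nonpolar).
er_marginals <- function(tree, tip_states, q) {
  po <- er_postorder(tree, tip_states, q)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  L <- po$L
  # M[child,] = P %*% L[child,]: message from child to its parent
  Mmsg <- matrix(NA_real_, n_all, 2)
  pedge <- po$order$edge
  for (i in seq_len(nrow(pedge))) {
    Mmsg[pedge[i, 2], ] <- as.vector(er_pmat(q, po$elen[i]) %*% L[pedge[i, 2], ])
  }
  G <- matrix(NA_real_, n_all, 2)
  root <- n_tip + 1L
  G[root, ] <- c(0.5, 0.5)
  # preorder: parent before child
  for (i in rev(seq_len(nrow(pedge)))) {
    par <- pedge[i, 1]; chi <- pedge[i, 2]
    sibs_msg <- G[par, ]
    kids <- pedge[pedge[, 1] == par, 2]
    for (k in kids) if (k != chi) sibs_msg <- sibs_msg * Mmsg[k, ]
    g <- as.vector(t(er_pmat(q, po$elen[i])) %*% sibs_msg)
    s <- sum(g); if (s > 0) g <- g / s
    G[chi, ] <- g
  }
  internal <- (n_tip + 1L):n_all
  post <- G[internal, , drop = FALSE] * L[internal, , drop = FALSE]
  post <- post / rowSums(post)
  rownames(post) <- tree$node.label
  colnames(post) <- c("Nonpolar", "Polar")
  post[, c("Polar", "Nonpolar"), drop = FALSE]
}

#' @export
print.er_fit <- function(x, ...) {
  cat(sprintf("Equal-rates niche model: q = %.4g, logLik = %.4f\n",
              x$q_hat, x$loglik))
  tab <- table(x$node_states)
  cat("Ancestral states:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Count niche-transition events along branches
#'
#' One event for every branch whose parent and child states differ (tip
#' states fixed at the observations, internal states from the fit), with
#' its direction and the RED value of the child node.
#'
#' @param fit An [fit_er()] result.
#' @return Object of class `transition_summary`: `n_to_p`, `p_to_n`,
#'   `events` data frame (parent, child, direction, child_red).
#' @export
count_transitions <- function(fit) {
  stopifnot(inherits(fit, "er_fit"))
  tree <- fit$tree
  n_tip <- length(tree$tip.label)
  red <- red_values(tree)
  state_of <- function(idx) {
    if (idx <= n_tip) unname(fit$tip_states[tree$tip.label[idx]])
    else unname(fit$node_states[tree$node.label[idx - n_tip]])
  }
  rows <- list()
  for (i in seq_len(nrow(tree$edge))) {
    sp <- state_of(tree$edge[i, 1]); sc <- state_of(tree$edge[i, 2])
    if (sp != sc) {
      child_lab <- node_label_of(tree, tree$edge[i, 2])
      rows[[length(rows) + 1]] <- data.frame(
        parent = node_label_of(tree, tree$edge[i, 1]),
        child = child_lab,
        direction = paste0(substr(sp, 1, 1), "->", substr(sc, 1, 1)),
        child_red = unname(red[child_lab]),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent = character(0), child = character(0),
               direction = character(0), child_red = numeric(0))
  structure(list(n_to_p = sum(events$direction == "N->P"),
                 p_to_n = sum(events$direction == "P->N"),
                 events = events), class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("Niche transitions: %d Nonpolar->Polar, %d Polar->Nonpolar\n",
              x$n_to_p, x$p_to_n))
  invisible(x)
}

#' Relative evolutionary divergence (RED) of every node
#'
#' RED(root) = 0, tips get 1, and RED(child) = RED(parent) +
#' d / (d + u) * (1 - RED(parent)), where d is the branch length to the
#' parent and u the mean distance from the child to its descendant tips.
#' A zero-length terminal branch with u = 0 gets RED 1 by continuity.
#' RED is non-decreasing along every root-to-tip path.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @return Named numeric vector over node labels and tip labels, in
#'   \[0, 1\].
#' @export
red_values <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  elen <- tree$edge.length[match(paste(ord$edge[, 1], ord$edge[, 2]), key)]
  # mean distance to descendant tips, postorder
  ntips <- numeric(n_all); sumd <- numeric(n_all)
  ntips[seq_len(n_tip)] <- 1
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; chi <- ord$edge[i, 2]
    ntips[par] <- ntips[par] + ntips[chi]
    sumd[par] <- sumd[par] + sumd[chi] + elen[i] * ntips[chi]
  }
  ubar <- sumd / ntips
  red <- numeric(n_all)
  root <- n_tip + 1L
  red[root] <- 0
  for (i in rev(seq_len(nrow(ord$edge)))) {   # preorder
    par <- ord$edge[i, 1]; chi <- ord$edge[i, 2]
    if (chi <= n_tip) { red[chi] <- 1; next }
    d <- elen[i]; u <- ubar[chi]
    red[chi] <- if (d + u == 0) red[par] else
      red[par] + d / (d + u) * (1 - red[par])
  }
  red[seq_len(n_tip)] <- 1
  names(red) <- c(tree$tip.label, tree$node.label)
  red
}

#' Faith's phylogenetic diversity of a leaf subset
#'
#' Sum of the branch lengths of the minimal spanning subtree of the
#' subset, including the path to the root when `include_root = TRUE`
#' (the default, matching the usual implementation).
#'
#' @param tree Rooted `phylo` tree.
#' @param leaves Character vector of tip labels (non-empty subset).
#' @param include_root Include the path up to the root (default TRUE).
#' @return Total branch length (numeric).
#' @export
faith_pd <- function(tree, leaves, include_root = TRUE) {
  if (!length(leaves)) stop("empty leaf subset")
  if (!all(leaves %in% tree$tip.label)) stop("leaves not in tree")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  in_span <- logical(n_all)
  in_span[match(leaves, tree$tip.label)] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  elen <- tree$edge.length[match(paste(ord$edge[, 1], ord$edge[, 2]), key)]
  # propagate membership rootward
  for (i in seq_len(nrow(ord$edge)))
    if (in_span[ord$edge[i, 2]])
      in_span[ord$edge[i, 1]] <- TRUE
  if (include_root) {
    sum(elen[in_span[ord$edge[, 2]]])
  } else {
    # drop branches on the naked path from the root down to the MRCA
    # and count only branches with spanning nodes on both ends below MRCA
    mrca <- if (length(leaves) == 1) match(leaves, tree$tip.label) else
      ape::getMRCA(tree, leaves)
    below <- logical(n_all); below[mrca] <- TRUE
    for (i in rev(seq_len(nrow(ord$edge))))
      if (below[ord$edge[i, 1]]) below[ord$edge[i, 2]] <- TRUE
    sum(elen[in_span[ord$edge[, 2]] & below[ord$edge[, 2]] &
               ord$edge[, 2] != mrca])
  }
}

#' Polar / nonpolar phylogenetic-diversity ratio of a gene family
#'
#' Faith's PD over the family's Polar member genomes divided by PD over
#' its Nonpolar members; undefined (NA, flagged) when either side is
#' empty.
#'
#' @param tree Rooted `phylo` tree over genomes.
#' @param members Genome ids carrying the family.
#' @param niche_labels Named character genome -> Polar/Nonpolar/...
#' @param include_root Passed to [faith_pd()].
#' @return List: `pd_polar`, `pd_nonpolar`, `ratio`, `defined`.
#' @export
pd_ratio <- function(tree, members, niche_labels, include_root = TRUE) {
  members <- intersect(members, tree$tip.label)
  if (!length(members)) stop("family present in no tree leaf")
  pol <- members[niche_labels[members] %in% "Polar"]
  non <- members[niche_labels[members] %in% "Nonpolar"]
  pd_p <- if (length(pol)) faith_pd(tree, pol, include_root) else 0
  pd_n <- if (length(non)) faith_pd(tree, non, include_root) else 0
  defined <- length(pol) > 0 && length(non) > 0 && pd_n > 0
  list(pd_polar = pd_p, pd_nonpolar = pd_n,
       ratio = if (defined) pd_p / pd_n else NA_real_, defined = defined)
}

# Brownian-motion profile log-likelihood on a given covariance C:
# analytic ML over (mu, sigma2), via Cholesky.
bm_profile_loglik <- function(y, C) {
  n <- length(y)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  one <- rep(1, n)
  Ci_y <- backsolve(ch, forwardsolve(t(ch), y))
  Ci_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(Ci_y) / sum(Ci_1)
  r <- y - mu
  Ci_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Ci_r) / n
  if (s2 <= 0) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

# lambda-scaled covariance: off-diagonal entries of the shared-path
# matrix multiplied by lambda, diagonal unchanged.
lambda_cov <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Pagel's-lambda phylogenetic-signal test for one trait
#'
#' Compares the Brownian-motion model (lambda = 1, the null: trait
#' distribution explained by the species tree alone) against the lambda
#' model (0 <= lambda <= 1) by a likelihood-ratio test with a
#' chi-squared(1) reference. Under either model the tip values are
#' multivariate normal with mean mu and covariance sigma2 * C(lambda),
#' where C(lambda) multiplies the off-diagonal shared-path-length matrix
#' by lambda; (mu, sigma2) are profiled analytically and lambda fitted by
#' bounded search on \[0, 1\]. Binary presence/absence traits may be
#' supplied encoded 0/1 (a deliberate continuous-trait treatment of a
#' discrete trait; see the vignette). Constant traits are untestable and
#' flagged. Duplicate-covariance singularities are handled by a small
#' diagonal jitter (1e-8 of mean diagonal).
#'
#' @param tree Rooted `phylo` tree (>= 4 tips).
#' @param trait Named numeric vector over tips.
#' @param C Optional precomputed shared-path covariance
#'   (`ape::vcv.phylo(tree)`), to amortise batch use.
#' @return Object of class `lambda_fit`: `lambda_hat`, `loglik_lambda`,
#'   `loglik_bm`, `lrt_stat` (clipped at 0), `p_raw`, `testable`.
#' @export
pagel_lambda_test <- function(tree, trait, C = NULL) {
  if (length(tree$tip.label) < 4) stop("need >= 4 leaves")
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait missing for some tips")
  if (stats::var(y) == 0) {
    return(structure(list(lambda_hat = NA_real_, loglik_lambda = NA_real_,
                          loglik_bm = NA_real_, lrt_stat = NA_real_,
                          p_raw = NA_real_, testable = FALSE),
                     class = "lambda_fit"))
  }
  if (is.null(C)) C <- ape::vcv.phylo(tree)
  C <- C[tree$tip.label, tree$tip.label]
  ll <- function(lam) {
    v <- bm_profile_loglik(y, lambda_cov(C, lam))
    if (is.na(v)) {
      Cj <- lambda_cov(C, lam)
      diag(Cj) <- diag(Cj) + 1e-8 * mean(diag(C))
      v <- bm_profile_loglik(y, Cj)
    }
    v
  }
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  ll_bm <- ll(1)
  # the optimum may sit at the boundary lambda = 1 itself
  ll_lam <- max(opt$objective, ll_bm)
  lam_hat <- if (ll_bm >= opt$objective) 1 else opt$maximum
  lrt <- max(0, 2 * (ll_lam - ll_bm))
  structure(list(lambda_hat = lam_hat, loglik_lambda = ll_lam,
                 loglik_bm = ll_bm, lrt_stat = lrt,
                 p_raw = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 testable = TRUE), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  if (!x$testable) cat("Pagel's lambda: untestable (constant trait)\n")
  else cat(sprintf(
    "Pagel's lambda: lambda = %.4f, LRT vs BM = %.4f, p = %.4g\n",
    x$lambda_hat, x$lrt_stat, x$p_raw))
  invisible(x)
}

#' Batch lambda tests over gene families with BH correction
#'
#' Runs [pagel_lambda_test()] for the 0/1 presence trait of each family
#' and applies Benjamini-Hochberg across the testable ones.
#'
#' @param tree Rooted `phylo` tree over genomes.
#' @param presence Named list family -> character vector of member
#'   genomes (tips).
#' @return Data frame: family_id, lambda_hat, lrt_stat, p_raw, p_bh,
#'   testable.
#' @export
lambda_signal_batch <- function(tree, presence) {
  C <- ape::vcv.phylo(tree)
  rows <- lapply(names(presence), function(f) {
    tr <- stats::setNames(as.numeric(tree$tip.label %in% presence[[f]]),
                          tree$tip.label)
    r <- pagel_lambda_test(tree, tr, C)
    data.frame(family_id = f, lambda_hat = r$lambda_hat,
               lrt_stat = r$lrt_stat, p_raw = r$p_raw,
               testable = r$testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  out$p_bh[out$testable] <- bh_adjust(out$p_raw[out$testable])
  out
}
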