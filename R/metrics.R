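#' Relative connectance
#'
#' The ratio `I / S_obs` of the number of distinct plant-pollinator links
#' realised in a local network (`I`) to the number of links that the same
#' species realise anywhere across all observation sites over the whole
#' study (`S_obs`).  Unlike classical connectance (realised / all possible
#' species pairs), the denominator excludes pairs never observed to
#' interact anywhere, so the metric is not diluted by forbidden links.
#' Values lie in (0, 1]: 1 means the local network realises every link its
#' member species realise regionally.
#'
#' @param network A [bipartite_network()].
#' @param global_links A link map from [global_link_map()] computed on the
#'   pooled records of all sites.
#' @return A single number in (0, 1].
#' @export
relative_connectance <- function(network, global_links) {
  w <- network$weights
  plants <- rownames(w)
  polls <- colnames(w)
  gl_plants <- attr(global_links, "plants")
  gl_polls <- attr(global_links, "pollinators")
  if (!all(plants %in% gl_plants) || !all(polls %in% gl_polls))
    stop("network contains species absent from the global link map")
  I <- sum(w > 0)
  if (I == 0) stop("relative connectance undefined: network has no links")
  parts <- strsplit(global_links, "\x1f", fixed = TRUE)
  gp <- vapply(parts, `[`, "", 1L)
  gq <- vapply(parts, `[`, "", 2L)
  S_obs <- sum(gp %in% plants & gq %in% polls)
  I / S_obs
}

#' NODF nestedness
#'
#' Nestedness metric based on overlap and decreasing fills, computed on the
#' binarised matrix (cell > 0 is a presence).  For every pair of rows (and
#' columns) whose marginal totals strictly decrease, the paired overlap is
#' the percentage of presences of the poorer vector that coincide with
#' presences of the richer one; pairs with equal marginal totals contribute
#' zero.  NODF is the mean over all row pairs and column pairs, in [0, 100].
#' Computation is delegated to [vegan::nestednodf()].
#'
#' @param weights Non-negative matrix (weighted or binary).
#' @return NODF in [0, 100].
#' @export
nodf <- function(weights) {
  m <- as.matrix(weights) > 0
  if (!any(m)) stop("NODF undefined: all-zero matrix")
  # a single row (or column) only admits pairs that are equal-fill or have
  # an empty poorer member; every such pair contributes 0
  if (nrow(m) < 2 || ncol(m) < 2) return(0)
  res <- vegan::nestednodf(m * 1, order = TRUE, weighted = FALSE)
  unname(res$statistic["NODF"])
}

#' Barber weighted bipartite modularity of a given partition
#'
#' `Q = (1/F) * sum_ij (A_ij - k_i d_j / F) * delta(g_i, h_j)` where `F` is
#' the total matrix weight, `k_i`/`d_j` are row/column totals and the delta
#' is 1 when plant `i` and pollinator `j` share a module.
#'
#' @param weights Non-negative matrix, plants x pollinators.
#' @param plant_labels,pollinator_labels Module labels (any atomic type),
#'   one per row / column.
#' @return Q in [-1, 1].
#' @export
barber_modularity <- function(weights, plant_labels, pollinator_labels) {
  w <- as.matrix(weights)
  if (length(plant_labels) != nrow(w) || length(pollinator_labels) != ncol(w))
    stop("labels must cover every row and column")
  F_tot <- sum(w)
  if (F_tot == 0) stop("modularity undefined: total weight is zero")
  B <- w - outer(rowSums(w), colSums(w)) / F_tot
  same <- outer(as.character(plant_labels), as.character(pollinator_labels),
                "==")
  sum(B[same]) / F_tot
}

#' Maximise weighted bipartite modularity by label propagation
#'
#' A DIRTLPAwb+-style search: weighted label propagation to a local optimum
#' of Barber's Q, followed by agglomerative merging of modules while Q
#' increases, restarted from a range of initial module counts (including
#' the every-node-unique initialisation) with randomised assignment.  The
#' best partition over all restarts is returned.  Deterministic given
#' `seed`.
#'
#' @param weights Non-negative matrix with total weight > 0.
#' @param n_restarts Number of randomised restarts (default 20).
#' @param seed Integer seed for the restart randomisation.
#' @return An object of class `module_partition`: list with
#'   `plant_labels`, `pollinator_labels` (integers, renumbered
#'   consecutively) and `q`.
#' @export
optimize_modules <- function(weights, n_restarts = 20, seed = 1) {
  w <- as.matrix(weights)
  storage.mode(w) <- "double"
  if (sum(w) == 0) stop("modularity undefined: total weight is zero")
  nr <- nrow(w); nc <- ncol(w)
  F_tot <- sum(w)
  B <- w - outer(rowSums(w), colSums(w)) / F_tot  # modularity matrix

  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  max_mod <- min(nr, nc)
  init_counts <- c(max_mod,
                   sample(seq_len(max_mod), n_restarts, replace = TRUE))
  for (k in init_counts) {
    rl <- sample(seq_len(k), nr, replace = TRUE)
    cl <- sample(seq_len(k), nc, replace = TRUE)
    cand <- lpa_refine(B, rl, cl)
    cand <- merge_modules(B, cand$rl, cand$cl)
    if (is.null(best) || cand$q > best$q + 1e-12) best <- cand
  }
  # the single-module partition has Q = 0; never return worse than that
  if (best$q < 0) best <- list(rl = rep(1L, nr), cl = rep(1L, nc), q = 0)
  relab <- relabel_partition(best$rl, best$cl)
  structure(list(plant_labels = relab$rl, pollinator_labels = relab$cl,
                 q = best$q / F_tot),
            class = "module_partition")
}

# Q numerator for a labelled partition (un-normalised)
sum_q <- function(B, rl, cl) {
  s <- 0
  for (m in unique(rl)) {
    j <- cl == m
    if (any(j)) s <- s + sum(B[rl == m, j, drop = FALSE])
  }
  s
}

# alternating best-label sweeps until the (un-normalised) Q stops improving
lpa_refine <- function(B, rl, cl) {
  q <- sum_q(B, rl, cl)
  repeat {
    pool <- union(rl, cl)
    # plants adopt the label maximising their contribution given pollinators
    colsum_by_lab <- rowsum_by(t(B), cl, pool)     # pool x nrow(B)
    rl_new <- pool[max.col(t(colsum_by_lab), ties.method = "first")]
    pool <- union(rl_new, cl)
    rowsum_by_lab <- rowsum_by(B, rl_new, pool)    # pool x ncol(B)
    cl_new <- pool[max.col(t(rowsum_by_lab), ties.method = "first")]
    q_new <- sum_q(B, rl_new, cl_new)
    if (q_new <= q + 1e-12) break
    rl <- rl_new; cl <- cl_new; q <- q_new
  }
  list(rl = rl, cl = cl, q = q)
}

# rows of m summed within label groups of `by` (length nrow(m)), for each
# label in `pool`; returns length(pool) x ncol(m)
rowsum_by <- function(m, by, pool) {
  out <- matrix(0, length(pool), ncol(m))
  for (i in seq_along(pool)) {
    sel <- by == pool[i]
    if (any(sel)) out[i, ] <- colSums(m[sel, , drop = FALSE])
  }
  out
}

# greedy agglomeration: merge the module pair giving the largest Q gain,
# repeat while positive; Q kept un-normalised throughout
merge_modules <- function(B, rl, cl) {
  repeat {
    pool <- union(rl, cl)
    if (length(pool) <= 1) break
    q0 <- sum_q(B, rl, cl)
    best_gain <- 0; best_pair <- NULL
    for (a in seq_along(pool)[-length(pool)]) for (b in (a + 1):length(pool)) {
      # gain of merging modules a,b: cross terms between a-rows/b-cols
      ra <- rl == pool[a]; rb <- rl == pool[b]
      ca <- cl == pool[a]; cb <- cl == pool[b]
      gain <- sum(B[ra, cb, drop = FALSE]) + sum(B[rb, ca, drop = FALSE])
      if (gain > best_gain + 1e-12) { best_gain <- gain; best_pair <- c(a, b) }
    }
    if (is.null(best_pair)) break
    rl[rl == pool[best_pair[2]]] <- pool[best_pair[1]]
    cl[cl == pool[best_pair[2]]] <- pool[best_pair[1]]
    refined <- lpa_refine(B, rl, cl)
    rl <- refined$rl; cl <- refined$cl
  }
  list(rl = rl, cl = cl, q = sum_q(B, rl, cl))
}

relabel_partition <- function(rl, cl) {
  pool <- union(rl, cl)
  list(rl = match(rl, pool), cl = match(cl, pool))
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Bipartite module partition:",
      length(union(x$plant_labels, x$pollinator_labels)),
      "modules, Q =", format(x$q, digits = 4), "\n")
  invisible(x)
}

#' Rarity-ordered plant extinction sequence
#'
#' Plants ordered by increasing floral resource area (rarest first), the
#' assumed order of local extinction; ties broken by species name so the
#' order is deterministic.
#'
#' @param network A [bipartite_network()] with `plant_floral_area`.
#' @return Character vector of plant names, rarest first.
#' @export
extinction_order_by_rarity <- function(network) {
  fa <- network$plant_floral_area
  names(fa)[order(fa, names(fa))]
}

#' Robustness to secondary pollinator extinction
#'
#' Plants are removed sequentially in the given order; a pollinator goes
#' secondarily extinct when its last interaction partner is removed.  The
#' survival curve (fraction of pollinator species remaining vs fraction of
#' plants removed) is anchored at (0, 1) and (1, 0) and integrated by the
#' trapezoid rule; the area is the robustness, in [0, 1].
#'
#' @param network A [bipartite_network()].
#' @param order Character vector: a permutation of the network's plants
#'   (defaults to [extinction_order_by_rarity()]).
#' @return Robustness in [0, 1].
#' @export
robustness <- function(network, order = extinction_order_by_rarity(network)) {
  w <- network$weights > 0
  plants <- rownames(w)
  if (!setequal(order, plants) || length(order) != length(plants))
    stop("order must be a permutation of the network's plants")
  n_poll <- ncol(w)
  if (n_poll == 0 || length(plants) == 0)
    stop("robustness undefined: empty network")
  remaining <- rep(TRUE, length(plants))
  names(remaining) <- plants
  surv <- numeric(length(plants))
  for (i in seq_along(order)) {
    remaining[order[i]] <- FALSE
    alive <- colSums(w[remaining, , drop = FALSE]) > 0
    surv[i] <- sum(alive) / n_poll
  }
  x <- seq(0, 1, length.out = length(plants) + 1)
  y <- c(1, surv)
  y[length(y)] <- 0  # all plants gone: no pollinators remain
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Abundance-based sample coverage
#'
#' The Chao-Jost abundance-based coverage estimator:
#' `C = 1 - (f1/n) * ((n-1) f1) / ((n-1) f1 + 2 f2)` with `f1`/`f2` the
#' numbers of species observed exactly once/twice and `n` the total count.
#' Applied to species abundance vectors and, for interaction coverage, to
#' per-link visit totals.
#'
#' @param counts Non-negative integer abundance vector.
#' @return Estimated coverage in [0, 1].
#' @export
sample_coverage <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) stop("coverage undefined: no individuals")
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f1 == 0) return(1)
  1 - (f1 / n) * ((n - 1) * f1) / ((n - 1) * f1 + 2 * f2)
}

#' All four network-architecture metrics for one network
#'
#' Convenience wrapper computing relative connectance, NODF nestedness,
#' optimised modularity and rarity-ordered robustness.
#'
#' @inheritParams relative_connectance
#' @param n_restarts,seed Passed to [optimize_modules()].
#' @return A list with `relative_connectance`, `nodf`, `modularity`,
#'   `robustness`.
#' @export
network_metrics <- function(network, global_links, n_restarts = 20, seed = 1) {
  list(
    relative_connectance = relative_connectance(network, global_links),
    nodf = nodf(network$weights),
    modularity = optimize_modules(network$weights,
                                  n_restarts = n_restarts, seed = seed)$q,
    robustness = robustness(network)
  )
}
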