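# Shared fixtures and independent oracles.  Systems are generated once per
# test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

# scaled-down island system: quick enough for repeated use, mainland pool
# dense enough to dominate every island (Null model II feasibility)
test_config <- function(seed = 5) {
  generator_config(n_islands = 12, mainland_pairs = 16,
                   surveys_per_transect = 12, n_plant_species = 40,
                   n_pollinator_species = 120, area_range_ha = c(0.3, 100),
                   lambda0 = 5e-4, seed = seed)
}

test_system <- function(seed = 5) {
  key <- paste0("sys", seed)
  if (is.null(.fixtures[[key]])) {
    sim <- generate_mechanistic_system(test_config(seed))
    isl <- sim$records[!sim$records$is_mainland, , drop = FALSE]
    gl <- global_link_map(sim$records)
    .fixtures[[key]] <- list(
      records = sim$records, attributes = sim$attributes, islands = isl,
      global_links = gl,
      pool = build_reference_pool(sim$records, gl),
      networks = assemble_networks(isl))
  }
  .fixtures[[key]]
}

# full study-scale system (41 islands, defaults): used where the design
# constants themselves are under test
study_system <- function() {
  if (is.null(.fixtures$study)) {
    sim <- generate_mechanistic_system(generator_config(seed = 101))
    .fixtures$study <- sim
  }
  .fixtures$study
}

# SEM analysis table + selected model on the test system, memoised
test_sem <- function() {
  if (is.null(.fixtures$sem)) {
    sys <- test_system()
    nm <- network_metrics_table(sys$networks, sys$global_links,
                                n_restarts = 10, seed = 2)
    comm <- community_summaries(sys$islands)
    tab <- suppressMessages(prepare_design(sys$attributes, comm, nm))
    sel <- suppressWarnings(backward_select(default_path_structure(), tab))
    .fixtures$sem <- list(table = tab, fit = sel)
  }
  .fixtures$sem
}

# four-variable gaussian chain system used across the SEM tests
chain_structure <- function() {
  path_structure(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
               path_id = 1:3),
    families = c(B = "gaussian", C = "gaussian", D = "gaussian"))
}

chain_data <- function(seed, ng = 100, beta = 0.5) {
  set.seed(seed)
  n <- 2 * ng
  g <- rep(sprintf("g%03d", seq_len(ng)), each = 2)
  re <- function() rep(rnorm(ng, 0, 0.5), each = 2)
  A <- rnorm(n)
  B <- beta * A + re() + rnorm(n, 0, 0.6)
  C <- beta * B + re() + rnorm(n, 0, 0.6)
  D <- beta * C + re() + rnorm(n, 0, 0.6)
  data.frame(site_id = g, A = A, B = B, C = C, D = D,
             stringsAsFactors = FALSE)
}

# ---- independent oracles -------------------------------------------------

# pairwise NODF, coded directly from the overlap/decreasing-fill definition
nodf_brute <- function(m) {
  m <- (m > 0) * 1
  vals <- numeric(0)
  pair <- function(a, b) {          # a = richer, b = poorer (strictly)
    if (sum(b) == 0) return(0)
    100 * sum(a & b) / sum(b)
  }
  axis_terms <- function(vectors) {
    n <- length(vectors)
    out <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      si <- sum(vectors[[i]]); sj <- sum(vectors[[j]])
      out <- c(out, if (si == sj) 0
               else if (si > sj) pair(vectors[[i]], vectors[[j]])
               else pair(vectors[[j]], vectors[[i]]))
    }
    out
  }
  rows <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  cols <- lapply(seq_len(ncol(m)), function(j) m[, j])
  vals <- c(axis_terms(rows), axis_terms(cols))
  if (!length(vals)) return(0)
  mean(vals)
}

# Barber Q by literal double sum over all cells
barber_brute <- function(w, rl, cl) {
  F_tot <- sum(w)
  k <- rowSums(w); d <- colSums(w)
  s <- 0
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w)))
    if (as.character(rl[i]) == as.character(cl[j]))
      s <- s + w[i, j] - k[i] * d[j] / F_tot
  s / F_tot
}

# all set partitions of n items as restricted growth strings
set_partitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) { out[[length(out) + 1L]] <<- s; return() }
    for (k in seq_len(mx + 1L)) rec(c(s, k), max(mx, k))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum of Barber Q over every bipartite module partition
exhaustive_q <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  best <- -Inf
  for (p in set_partitions(nr + nc)) {
    q <- barber_modularity(w, p[seq_len(nr)], p[nr + seq_len(nc)])
    if (q > best) best <- q
  }
  best
}

# step-by-step removal simulation for robustness
robustness_sim <- function(w, order) {
  w <- w > 0
  n_poll <- ncol(w)
  plants <- rownames(w)
  surv <- numeric(length(order) + 1)
  surv[1] <- 1
  for (i in seq_along(order)) {
    w[order[i], ] <- FALSE
    surv[i + 1] <- if (i == length(order)) 0 else sum(colSums(w) > 0) / n_poll
  }
  x <- seq(0, 1, length.out = length(order) + 1)
  sum(diff(x) * (head(surv, -1) + tail(surv, -1)) / 2)
}

# matrix closed form for effect totals: with B[s, r] the direct
# standardized effects, total = sum_k B^k = (I - B)^{-1} - I (acyclic)
tracing_oracle <- function(coefficients, vars) {
  B <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  main <- coefficients[!grepl(":", coefficients$source, fixed = TRUE), ]
  B[cbind(main$source, main$response)] <- main$std_estimate
  total <- solve(diag(length(vars)) - B) - diag(length(vars))
  list(direct = B, total = total)
}

# brute-force relative connectance by explicit link enumeration
rc_brute <- function(network, records) {
  v <- records[records$visit_count > 0, , drop = FALSE]
  all_links <- unique(paste(v$plant_species, v$pollinator_species,
                            sep = "/"))
  plants <- rownames(network$weights)
  polls <- colnames(network$weights)
  local <- sum(network$weights > 0)
  shared <- 0
  for (l in all_links) {
    pq <- strsplit(l, "/", fixed = TRUE)[[1]]
    if (pq[1] %in% plants && pq[2] %in% polls) shared <- shared + 1
  }
  local / shared
}

# random small binary matrix with at least one link, <= 3 links per row
random_small_matrix <- function(nr, nc) {
  repeat {
    w <- matrix(rbinom(nr * nc, 1, 0.5), nr,
                dimnames = list(paste0("p", seq_len(nr)),
                                paste0("q", seq_len(nc))))
    if (sum(w) > 0 && all(rowSums(w) <= 3)) return(w)
  }
}
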