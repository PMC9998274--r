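test_that("NODF agrees with the pairwise definition", {
  # worked forms
  expect_equal(nodf(generate_structured_matrix("nested", 5, 5, fill = 1)),
               100)
  expect_equal(nodf(matrix(1, 4, 4)), 0)  # equal marginal totals
  expect_error(nodf(matrix(0, 3, 3)), "all-zero")
  # degenerate single-row/column networks: every pair contributes zero
  expect_equal(nodf(matrix(c(1, 0, 1), 1)), 0)
  expect_equal(nodf(matrix(c(1, 1, 0), ncol = 1)), 0)
  expect_equal(nodf(matrix(1, 1, 1)), 0)

  # brute-force oracle on random matrices
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6)
    if (!any(m)) next
    expect_equal(nodf(m), nodf_brute(m), tolerance = 1e-10)
  }

  # permutation invariance
  set.seed(8)
  m <- generate_structured_matrix("random", 7, 5, fill = 0.4, seed = 3)
  for (i in 1:5) {
    perm <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(nodf(perm), nodf(m), tolerance = 1e-10)
  }
})

test_that("Barber modularity matches the double-sum and is label-invariant", {
  expect_equal(barber_modularity(matrix(1, 3, 3), rep(1, 3), rep(1, 3)), 0)
  b <- generate_structured_matrix("modular", 4, 4, fill = 1)
  expect_equal(barber_modularity(b, c(1, 1, 2, 2), c(1, 1, 2, 2)), 0.5)

  set.seed(11)
  for (i in 1:10) {
    w <- matrix(rpois(20, 2), 5, 4)
    if (sum(w) == 0) next
    rl <- sample(1:3, 5, replace = TRUE)
    cl <- sample(1:3, 4, replace = TRUE)
    expect_equal(barber_modularity(w, rl, cl), barber_brute(w, rl, cl),
                 tolerance = 1e-12)
    # relabeling modules consistently leaves Q unchanged
    map <- c(7, 5, 9)
    expect_equal(barber_modularity(w, map[rl], map[cl]),
                 barber_modularity(w, rl, cl), tolerance = 1e-12)
  }
})

test_that("module search finds planted structure and the exhaustive optimum", {
  b <- generate_structured_matrix("modular", 4, 4, fill = 1)
  opt <- optimize_modules(b, n_restarts = 10, seed = 1)
  expect_equal(opt$q, 0.5, tolerance = 1e-9)
  expect_equal(length(unique(opt$plant_labels)), 2L)

  flat <- optimize_modules(matrix(1, 3, 3), n_restarts = 10, seed = 1)
  expect_lt(flat$q, 1e-9)

  # never below the single-module partition (Q = 0)
  set.seed(13)
  for (i in 1:10) {
    w <- matrix(rpois(12, 1), 4, 3)
    if (sum(w) == 0) next
    expect_gte(optimize_modules(w, n_restarts = 5, seed = i)$q, 0)
  }

  # exact agreement with exhaustive partition search on small instances
  set.seed(7)
  for (i in 1:15) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    w <- random_small_matrix(nr, nc)
    expect_equal(optimize_modules(w, n_restarts = 20, seed = i)$q,
                 exhaustive_q(w), tolerance = 1e-9)
  }

  # deterministic given the seed
  w <- random_small_matrix(4, 4)
  a <- optimize_modules(w, n_restarts = 10, seed = 99)
  b2 <- optimize_modules(w, n_restarts = 10, seed = 99)
  expect_identical(a, b2)
})

test_that("rarity ordering sorts by floral area with lexicographic ties", {
  w <- matrix(1L, 3, 2, dimnames = list(c("A", "B", "C"), c("x", "y")))
  net <- bipartite_network(w, plant_floral_area = c(A = 5, B = 1, C = 3))
  expect_equal(extinction_order_by_rarity(net), c("B", "C", "A"))

  net_tie <- bipartite_network(w, plant_floral_area = c(C = 2, A = 2, B = 2))
  expect_equal(extinction_order_by_rarity(net_tie), c("A", "B", "C"))

  set.seed(21)
  fa <- setNames(runif(10), paste0("pl", sample(10)))
  w10 <- matrix(1L, 10, 2, dimnames = list(names(fa), c("x", "y")))
  net10 <- bipartite_network(w10, plant_floral_area = fa)
  expect_equal(extinction_order_by_rarity(net10),
               names(fa)[order(fa, names(fa))])
})

test_that("robustness equals the removal simulation and closed forms", {
  one <- bipartite_network(matrix(1L, 1, 1, dimnames = list("p", "q")),
                           plant_floral_area = c(p = 1))
  expect_equal(robustness(one), 0.5)

  # fully connected: pollinators survive until the last plant goes
  w <- matrix(1L, 5, 7, dimnames = list(paste0("p", 1:5), paste0("q", 1:7)))
  full <- bipartite_network(w, plant_floral_area = setNames(1:5,
                                                            rownames(w)))
  expect_equal(robustness(full), 1 - 1 / (2 * 5))

  set.seed(17)
  for (i in 1:10) {
    w8 <- matrix(rbinom(64, 1, 0.3), 8,
                 dimnames = list(paste0("p", 1:8), paste0("q", 1:8)))
    w8 <- w8[rowSums(w8) > 0, colSums(w8) > 0, drop = FALSE]
    if (nrow(w8) < 2 || ncol(w8) < 2) next
    net <- bipartite_network(w8, plant_floral_area =
                               setNames(runif(nrow(w8)), rownames(w8)))
    ord <- extinction_order_by_rarity(net)
    expect_equal(robustness(net, ord), robustness_sim(net$weights, ord),
                 tolerance = 1e-12)
  }

  expect_error(robustness(full, order = paste0("p", c(1, 1, 2, 3, 4))),
               "permutation")
})

test_that("adding a link never lowers robustness under a fixed order", {
  set.seed(23)
  for (i in 1:15) {
    w <- matrix(rbinom(30, 1, 0.4), 6,
                dimnames = list(paste0("p", 1:6), paste0("q", 1:5)))
    if (any(rowSums(w) == 0) || any(colSums(w) == 0)) next
    fa <- setNames(runif(6), rownames(w))
    net <- bipartite_network(w, plant_floral_area = fa)
    ord <- extinction_order_by_rarity(net)
    r0 <- robustness(net, ord)
    zero <- which(w == 0, arr.ind = TRUE)
    if (!nrow(zero)) next
    add <- zero[sample.int(nrow(zero), 1), ]
    w2 <- w; w2[add[1], add[2]] <- 1L
    net2 <- bipartite_network(w2, plant_floral_area = fa)
    expect_gte(robustness(net2, ord), r0 - 1e-12)
  }
})

test_that("sample coverage follows the Chao-Jost estimator", {
  expect_equal(sample_coverage(c(5, 3, 4)), 1)            # no singletons
  expect_equal(sample_coverage(rep(1, 6)), 0)             # all singletons
  expect_equal(sample_coverage(c(1, 1, 2, 3, 3)), 0.82)   # n=10,f1=2,f2=1
  expect_error(sample_coverage(integer(0)), "no individuals")
})
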