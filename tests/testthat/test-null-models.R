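test_that("reference pool collects the mainland transects per class", {
  sys <- test_system()
  pool <- sys$pool
  expect_length(pool$edge, 16L)
  expect_length(pool$interior, 16L)

  no_int <- sys$records[!(sys$records$is_mainland &
                            sys$records$site_class == "interior"), ]
  expect_error(build_reference_pool(no_int), "interior")

  # pool link map equals the union of per-transect link sets
  per_transect <- lapply(c(pool$edge, pool$interior), function(tr) {
    v <- tr[tr$visit_count > 0, ]
    unique(paste(v$plant_species, v$pollinator_species, sep = "\x1f"))
  })
  ml <- sys$records[sys$records$is_mainland, ]
  expect_setequal(unique(unlist(per_transect)),
                  as.vector(global_link_map(ml)))
})

test_that("Null model I draws behave like transect resampling", {
  sys <- test_system()
  pool <- sys$pool

  # degenerate pool of identical transects: sums scale with n, richness
  # stays at the single-transect value
  tr <- pool$edge[[1]]
  clone_pool <- pool
  clone_pool$edge <- rep(list(tr), 4)
  clone_pool$transect_summaries <- NULL   # force re-aggregation
  clone_pool$events <- NULL
  set.seed(1)
  m <- null_draw_transects(clone_pool, 4, "edge")
  single <- community_metrics(tr)
  expect_equal(m$floral_resources, 4 * single$floral_resources)
  expect_equal(m$pollinator_abundance, 4 * single$pollinator_abundance)
  expect_equal(m$plant_richness, single$plant_richness)

  # union bound on richness
  pool_rich <- community_metrics(do.call(rbind, pool$interior))
  set.seed(2)
  for (i in 1:20) {
    d <- null_draw_transects(pool, sample(1:8, 1), "interior")
    expect_lte(d$plant_richness, pool_rich$plant_richness)
    expect_lte(d$pollinator_richness, pool_rich$pollinator_richness)
  }

  # resampling expectation: single-transect draws average to the pool mean
  per_ab <- vapply(pool$edge, function(tr) sum(tr$visit_count), 0)
  set.seed(3)
  draws <- replicate(1000,
                     null_draw_transects(pool, 1, "edge")$pollinator_abundance)
  se <- sd(per_ab) / sqrt(1000)
  expect_lt(abs(mean(draws) - mean(per_ab)), 4 * se + 1e-9)
})

test_that("Null model II meets its constraints exactly or errors", {
  sys <- test_system()
  pool <- sys$pool
  expect_error(null_draw_network(pool, 2, 3, 1, "edge"), "n_interactions")
  expect_error(null_draw_network(pool, 20000, 10000, 4, "edge"), "richness")

  set.seed(4)
  nn <- null_draw_network(pool, 10, 3, 4, "edge")
  expect_equal(sum(nn$weights), 10)
  expect_equal(nrow(nn$weights), 3L)
  expect_equal(ncol(nn$weights), 4L)
})

test_that("event sampling is proportional to pool visit counts", {
  sys <- test_system()
  pool <- sys$pool
  ev <- fragnet:::pool_events(pool, "edge")
  # control run with the constraints effectively released (targets = the
  # near-certain richness of a large draw): frequencies should follow the
  # pool weights
  set.seed(6)
  n_ev <- 4000
  idx <- sample.int(nrow(ev), n_ev, replace = TRUE,
                    prob = ev$weight / sum(ev$weight))
  counts <- tabulate(idx, nbins = nrow(ev))
  keep <- ev$weight / sum(ev$weight) * n_ev >= 5   # chi-square validity
  chi <- suppressWarnings(
    chisq.test(c(sum(counts[!keep]), counts[keep]),
               p = c(sum(ev$weight[!keep]), ev$weight[keep]) /
                 sum(ev$weight)))
  expect_gt(chi$p.value, 0.01)

  # accepted constrained draws stay reproducible from the seed
  set.seed(7)
  a <- null_draw_network(pool, 12, 4, 5, "interior")
  set.seed(7)
  b <- null_draw_network(pool, 12, 4, 5, "interior")
  expect_identical(a$weights, b$weights)
})

test_that("SES envelopes summarise null distributions correctly", {
  set.seed(9)
  null <- rnorm(1000)
  env <- ses_compare(mean(null), null)
  expect_equal(env$ses, 0, tolerance = 1e-12)
  expect_false(env$significant)

  env2 <- ses_compare(mean(null) + 2 * sd(null), null)
  expect_equal(env2$ses, 2, tolerance = 1e-12)
  expect_true(env2$significant)

  degen <- ses_compare(1, rep(1, 50))
  expect_true(degen$degenerate)
  expect_false(degen$significant)
  expect_true(is.na(degen$ses))

  # calibration: observations drawn from the null reject at ~5%
  set.seed(10)
  trials <- rnorm(1000)
  rate <- mean(vapply(trials, function(x) ses_compare(x, null)$significant,
                      TRUE))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("feeding the null through itself is self-consistent", {
  sys <- test_system()
  pool <- sys$pool
  # floral resources: continuous, so the envelope bounds are tie-free
  set.seed(12)
  null_fr <- replicate(1000,
                       null_draw_transects(pool, 3,
                                           "interior")$floral_resources)
  set.seed(13)
  obs_fr <- replicate(300,
                      null_draw_transects(pool, 3,
                                          "interior")$floral_resources)
  envs <- lapply(obs_fr, ses_compare, null_values = null_fr)
  ses <- vapply(envs, `[[`, 0, "ses")
  rej <- mean(vapply(envs, `[[`, TRUE, "significant"))
  expect_lt(abs(mean(ses)), 0.1)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("island community envelopes have coherent columns", {
  sys <- test_system()
  sub_attr <- sys$attributes[1:3, ]
  sub_rec <- sys$records[sys$records$is_mainland |
                           sys$records$site_id %in% sub_attr$site_id, ]
  out <- null_model_communities(sub_rec, sub_attr, sys$pool,
                                n_draws = 100, seed = 2)
  expect_true(all(out$ci_low <= out$null_mean + 1e-9))
  expect_true(all(out$null_mean <= out$ci_high + 1e-9))
  expect_equal(out$significant,
               out$observed < out$ci_low | out$observed > out$ci_high)
  expect_setequal(unique(out$quantity),
                  c("floral_resources", "plant_richness",
                    "pollinator_abundance", "pollinator_richness"))
})
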