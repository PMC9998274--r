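test_that("design table applies the transforms and sign conventions", {
  at <- data.frame(site_id = c("I01", "I02"), area_ha = c(1, 20),
                   distance_to_mainland_m = c(exp(6), exp(7)),
                   n_transect_pairs = c(1L, 2L), stringsAsFactors = FALSE)
  comm <- data.frame(site_id = rep(c("I01", "I02"), each = 2),
                     site_class = rep(c("edge", "interior"), 2),
                     is_mainland = FALSE,
                     floral_resources = c(10, 1, 20, 2),
                     plant_richness = c(3L, 1L, 5L, 2L),
                     pollinator_abundance = c(9L, 1L, 20L, 3L),
                     pollinator_richness = c(4L, 1L, 8L, 2L),
                     stringsAsFactors = FALSE)
  nm <- data.frame(site_id = comm$site_id, site_class = comm$site_class,
                   relative_connectance = c(0.5, 0.9, 0.4, 0.7),
                   nodf = c(40, 10, 50, 20), modularity = c(0.3, 0.6, 0.2, 0.5),
                   robustness = c(0.8, 0.5, 0.9, 0.6),
                   stringsAsFactors = FALSE)
  tab <- prepare_design(at, comm, nm)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$DA[tab$site_id == "I01"], c(0, 0))   # -ln(1) = 0
  expect_equal(tab$DA[tab$site_id == "I02"][1], -log(20))
  expect_equal(tab$DM[tab$site_id == "I01"][1], 6)
  expect_equal(tab$PE, c(1L, 0L, 1L, 0L))
  tab2 <- prepare_design(at, comm, nm, flip_area_sign = FALSE)
  expect_equal(tab2$DA, -tab$DA)
  expect_error(prepare_design(at[1, ], comm, nm), "missing island")

  # centred interaction products have mean ~ 0
  st <- default_path_structure()
  aug <- fragnet:::add_interaction_columns(
    transform(tab, FR = 1, PL = 1L, AB = 1L, PO = 1L), st)
  expect_lt(abs(mean(aug$DA_x_PE)), 1e-10)
})

test_that("path structures round-trip through YAML", {
  st <- default_path_structure()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_path_structure(st, path)
  back <- read_path_structure(path)
  expect_equal(back$paths, st$paths)
  expect_equal(back$families, st$families)
  expect_equal(back$correlated, st$correlated)
  expect_error(read_path_structure("no-such-file.yaml"), "not found")
})

test_that("component models recover known effects", {
  set.seed(30)
  ng <- 100; n <- 2 * ng
  d <- data.frame(site_id = rep(sprintf("g%03d", 1:ng), each = 2),
                  x = rnorm(n))
  d$y <- 2 * d$x + rep(rnorm(ng, 0, 0.7), each = 2) + rnorm(n, 0, 0.5)
  fit <- fit_component_model("y", "x", "gaussian", d)
  cf <- fragnet:::component_coefs(fit)
  i <- cf$term == "x"
  expect_lt(abs(cf$estimate[i] - 2), 3 * cf$se[i])

  d$z <- rpois(n, exp(1 + 0.5 * d$x))
  pfit <- fit_component_model("z", "x", "poisson", d)
  pcf <- fragnet:::component_coefs(pfit)
  j <- pcf$term == "x"
  expect_lt(abs(pcf$estimate[j] - 0.5), 3 * pcf$se[j])

  # zero island variance: fit still succeeds with a ~0 variance estimate
  d$y0 <- 1.5 * d$x + rnorm(n, 0, 0.5)
  fit0 <- fit_component_model("y0", "x", "gaussian", d)
  vc <- as.data.frame(lme4::VarCorr(fit0))
  expect_lt(vc$vcov[vc$grp == "site_id"], 0.05)

  expect_error(fit_component_model("y", character(0), "gaussian",
                                   transform(d, y = 1)), "degenerate")
  expect_error(fit_component_model("y", "w", "gaussian",
                                   transform(d, w = 1)), "zero-variance")
})

test_that("standardization is scale-invariant and matches closed forms", {
  set.seed(31)
  n <- 400
  d <- data.frame(site_id = rep(sprintf("g%03d", 1:200), each = 2),
                  x = rnorm(n))
  d$y <- 0.6 * d$x + rnorm(n, 0, 0.8)
  fit <- fit_component_model("y", "x", "gaussian", d)
  std <- standardized_coefficients(fit, "y", "gaussian", d)

  # doubling the predictor scale leaves the standardized value unchanged
  d2 <- transform(d, x = 2 * x)
  fit2 <- fit_component_model("y", "x", "gaussian", d2)
  std2 <- standardized_coefficients(fit2, "y", "gaussian", d2)
  expect_equal(unname(std2["x"]), unname(std["x"]), tolerance = 1e-6)

  # single gaussian predictor: standardized coefficient ~ Pearson r
  expect_equal(unname(std["x"]), cor(d$x, d$y), tolerance = 0.02)

  # pre-standardized data: standardized equals raw
  ds <- transform(d, x = as.numeric(scale(x)), y = as.numeric(scale(y)))
  fits <- fit_component_model("y", "x", "gaussian", ds)
  stds <- standardized_coefficients(fits, "y", "gaussian", ds)
  expect_equal(unname(stds["x"]), unname(lme4::fixef(fits)["x"]),
               tolerance = 1e-8)
})

test_that("the basis set enumerates non-adjacent pairs correctly", {
  # saturated graph: nothing to test
  sat <- path_structure(
    data.frame(source = c("A", "A", "B"), target = c("B", "C", "C"),
               path_id = 1:3),
    families = c(B = "gaussian", C = "gaussian"))
  expect_length(basis_set(sat), 0L)

  # textbook chain A -> B -> C: a single claim C _||_ A | B
  chain <- path_structure(
    data.frame(source = c("A", "B"), target = c("B", "C"), path_id = 1:2),
    families = c(B = "gaussian", C = "gaussian"))
  cl <- basis_set(chain)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$response, "C")
  expect_equal(cl[[1]]$other, "A")
  expect_equal(cl[[1]]$conditioning, "B")

  # random sparse DAGs: claim count equals direct enumeration
  set.seed(33)
  for (rep in 1:10) {
    vars <- LETTERS[1:6]
    pairs <- t(combn(6, 2))
    keep <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    if (nrow(keep) == 0) next
    paths <- data.frame(source = vars[keep[, 1]], target = vars[keep[, 2]],
                        path_id = seq_len(nrow(keep)))
    fams <- setNames(rep("gaussian", 6), vars)
    st <- path_structure(paths, fams[unique(paths$target)])
    # direct enumeration over the variables the structure mentions
    present <- st$variables
    exo <- setdiff(present, paths$target)
    pr <- t(combn(length(present), 2))
    n_expected <- sum(apply(pr, 1, function(ij) {
      a <- present[ij[1]]; b <- present[ij[2]]
      adjacent <- any((paths$source == a & paths$target == b) |
                        (paths$source == b & paths$target == a))
      !adjacent && !(a %in% exo && b %in% exo)
    }))
    expect_length(basis_set(st), n_expected)
  }

  cyc <- data.frame(source = c("A", "B"), target = c("B", "A"),
                    path_id = 1:2)
  expect_error(path_structure(cyc, c(A = "gaussian", B = "gaussian")),
               "cyclic")
})

test_that("Fisher's C combines claim p-values as stated", {
  expect_equal(combine_fisher(numeric(0)), list(C = 0, df = 0L, p = 1))
  cf <- combine_fisher(rep(0.5, 5))
  expect_equal(cf$C, -2 * 5 * log(0.5))
  expect_equal(cf$C, 6.931, tolerance = 1e-3)
  expect_equal(cf$df, 10L)

  st <- chain_structure()
  d <- chain_data(1)
  fit <- fit_psem(st, d)
  expect_equal(fit$dsep_df, 2L * nrow(fit$claims))
  expect_equal(fit$fisher_c, combine_fisher(fit$claims$p)$C)
})

test_that("SEM AIC identity holds and tracks parameter counts", {
  expect_equal(sem_aic(51.83, 45), 141.83)
  expect_equal(sem_aic(0, 3), 6)

  st <- chain_structure()
  d <- chain_data(2)
  fit <- fit_psem(st, d)
  expect_equal(fit$aic, fit$fisher_c + 2 * fit$k)

  # adding one path changes K by exactly 1
  st2 <- path_structure(
    rbind(st$paths, data.frame(source = "A", target = "C", path_id = 4L)),
    st$families)
  fit2 <- fit_psem(st2, d)
  expect_equal(fit2$k, fit$k + 1L)
  expect_equal(fit2$aic - fit$aic,
               (fit2$fisher_c - fit$fisher_c) + 2)
})

test_that("backward selection drops noise paths and is a deterministic
           fixed point", {
  d <- chain_data(3)
  set.seed(40)
  d$N <- rnorm(nrow(d))               # pure noise predictor
  st <- path_structure(
    data.frame(source = c("A", "B", "C", "N"),
               target = c("B", "C", "D", "D"), path_id = 1:4),
    families = c(B = "gaussian", C = "gaussian", D = "gaussian"))
  sel <- suppressWarnings(backward_select(st, d))
  expect_false(any(sel$coefficients$source == "N" &
                     sel$coefficients$response == "D"))

  # AIC strictly decreases along the accepted removals
  hist <- attr(sel, "selection")
  expect_true(all(diff(hist$aic) < 0))

  # selection from the already-minimal structure returns it unchanged
  sel2 <- suppressWarnings(backward_select(sel$structure, d))
  expect_equal(sel2$structure$paths, sel$structure$paths)

  # no randomness: a repeat run is identical
  sel3 <- suppressWarnings(backward_select(st, d))
  expect_equal(sel3$coefficients, sel$coefficients)
})

test_that("selected SEM on island data keeps the AIC bookkeeping coherent", {
  sem <- test_sem()
  fit <- sem$fit
  expect_s3_class(fit, "psem_fit")
  expect_equal(fit$aic, fit$fisher_c + 2 * fit$k)
  expect_gte(fit$fisher_c, 0)
  expect_true(all(diff(attr(fit, "selection")$aic) < 0))
  expect_lt(nrow(fit$coefficients), 45L)
  # print/summary/coef methods behave
  expect_output(print(fit), "Fisher's C")
  expect_named(coef(fit))
})
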