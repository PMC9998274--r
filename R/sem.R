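#' Directed path structure for a piecewise SEM
#'
#' Describes the hypothesised causal graph over the island-attribute,
#' community-structure and network-architecture variables.  Sources
#' containing `":"` (for example `"DA:PE"`) denote interaction
#' (moderation) terms: the centred product of the two named variables
#' enters the target's component model as an extra predictor.
#'
#' @param paths data.frame with columns `source`, `target`, `path_id`.
#' @param families Named character vector mapping every endogenous variable
#'   to `"gaussian"` or `"poisson"`.  Endogeneity is declared here, not
#'   inferred from the paths: a variable with a family stays endogenous
#'   (intercept-only component model, claims in the basis set) even if
#'   selection removes all of its incoming paths.
#' @param correlated Optional data.frame with columns `a`, `b`: variable
#'   pairs whose errors are allowed to covary (excluded from the
#'   independence basis set).
#' @return An object of class `path_structure`.
#' @export
path_structure <- function(paths, families, correlated = NULL) {
  stopifnot(all(c("source", "target", "path_id") %in% names(paths)))
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  if (anyDuplicated(paths$path_id)) stop("path_ids must be unique")
  if (anyDuplicated(paths[c("source", "target")]))
    stop("duplicate source->target path")
  targets <- unique(paths$target)
  if (!all(targets %in% names(families)))
    stop("families must name every endogenous variable")
  if (!all(families %in% c("gaussian", "poisson")))
    stop("families must be 'gaussian' or 'poisson'")
  comp <- strsplit(paths$source, ":", fixed = TRUE)
  vars <- unique(c(unlist(comp), paths$target, names(families)))
  # acyclicity over the edges implied by (components of) each source
  edges <- unique(do.call(rbind, Map(function(src, tgt)
    data.frame(from = src, to = tgt, stringsAsFactors = FALSE),
    comp, paths$target)))
  order <- topo_sort(vars, edges)
  structure(list(paths = paths, families = families,
                 correlated = correlated, variables = vars,
                 topo_order = order,
                 endogenous = intersect(vars, names(families)),
                 exogenous = setdiff(vars, names(families))),
            class = "path_structure")
}

topo_sort <- function(vars, edges) {
  order <- character(0)
  remaining <- vars
  repeat {
    free <- remaining[vapply(remaining, function(v)
      !any(edges$to == v & edges$from %in% remaining), TRUE)]
    if (!length(free)) {
      if (length(remaining)) stop("path structure is cyclic")
      break
    }
    order <- c(order, sort(free))
    remaining <- setdiff(remaining, free)
    if (!length(remaining)) break
  }
  order
}

#' @export
print.path_structure <- function(x, ...) {
  cat("Piecewise SEM path structure:", nrow(x$paths), "paths,",
      length(x$endogenous), "endogenous variables\n")
  invisible(x)
}

#' Default hypothesised path structure
#'
#' The shipped 45-path structure over decreased area (DA), proximity to
#' edge (PE) and distance to mainland (DM) acting on community structure
#' (FR floral resources, PL plant richness, AB pollinator abundance, PO
#' pollinator richness) and network architecture (RC relative connectance,
#' NE nestedness, MO modularity, RO robustness), with an area-by-edge
#' interaction on each community and network response and architecture
#' effects cascading into robustness.  Community responses PL/AB/PO are
#' Poisson counts; FR and the four network metrics are Gaussian.  Errors of
#' DA and DM (both island geography) may covary.
#'
#' @return A [path_structure()].
#' @export
default_path_structure <- function() {
  p <- function(source, target) data.frame(source = source, target = target,
                                           stringsAsFactors = FALSE)
  paths <- rbind(
    p(c("DA", "PE", "DM", "DA:PE"), "FR"),
    p(c("DA", "PE", "DM", "FR", "DA:PE"), "PL"),
    p(c("DA", "PE", "DM", "FR", "PL", "DA:PE"), "AB"),
    p(c("DA", "PE", "DM", "FR", "PL", "AB", "DA:PE"), "PO"),
    p(c("DA", "PE", "DM", "PL", "PO", "DA:PE"), "RC"),
    p(c("DA", "PE", "DM", "PL", "PO", "DA:PE"), "NE"),
    p(c("DA", "PE", "DM", "PL", "PO", "DA:PE"), "MO"),
    p(c("DA", "PE", "RC", "MO", "NE"), "RO"))
  paths$path_id <- seq_len(nrow(paths))
  fams <- c(FR = "gaussian", PL = "poisson", AB = "poisson", PO = "poisson",
            RC = "gaussian", NE = "gaussian", MO = "gaussian",
            RO = "gaussian")
  path_structure(paths, fams,
                 correlated = data.frame(a = "DA", b = "DM",
                                         stringsAsFactors = FALSE))
}

#' Read or write a path structure as YAML
#'
#' The on-disk format mirrors the constructor: a `paths` list of
#' `{source, target, path_id}` entries, a `families` map, and optional
#' `correlated` pairs.
#'
#' @param path YAML file path.
#' @return `read_path_structure()` returns a [path_structure()];
#'   `write_path_structure()` invisibly returns `path`.
#' @export
read_path_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$paths) || is.null(y$families))
    stop("path structure YAML needs 'paths' and 'families'")
  paths <- do.call(rbind, lapply(y$paths, function(p)
    data.frame(source = p$source, target = p$target,
               path_id = as.integer(p$path_id), stringsAsFactors = FALSE)))
  correlated <- if (length(y$correlated))
    do.call(rbind, lapply(y$correlated, function(p)
      data.frame(a = p[[1]], b = p[[2]], stringsAsFactors = FALSE)))
  path_structure(paths, unlist(y$families), correlated)
}

#' @rdname read_path_structure
#' @param structure A [path_structure()] to serialise.
#' @export
write_path_structure <- function(structure, path) {
  y <- list(
    paths = lapply(seq_len(nrow(structure$paths)), function(i)
      list(source = structure$paths$source[i],
           target = structure$paths$target[i],
           path_id = structure$paths$path_id[i])),
    families = as.list(structure$families))
  if (!is.null(structure$correlated))
    y$correlated <- lapply(seq_len(nrow(structure$correlated)), function(i)
      c(structure$correlated$a[i], structure$correlated$b[i]))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Assemble the SEM analysis table
#'
#' One row per island x habitat class.  `DA = -ln(area_ha)` by default, so
#' that a positive coefficient means an effect of *decreased* area (set
#' `flip_area_sign = FALSE` for plain `ln(area)`); `DM = ln(distance)`;
#' `PE` is the edge indicator (interior 0, edge 1).  Community and network
#' metric columns are merged in under their two-letter codes.
#'
#' @param attributes Island attribute table.
#' @param community Data.frame from [community_summaries()] (islands only).
#' @param network_metrics Data.frame with columns `site_id, site_class,
#'   relative_connectance, nodf, modularity, robustness` (see
#'   [network_metrics_table()]).
#' @param flip_area_sign Use the decreased-area sign convention (default).
#' @return The analysis data.frame with columns `site_id, site_class, DA,
#'   PE, DM, FR, PL, AB, PO, RC, NE, MO, RO`.
#' @export
prepare_design <- function(attributes, community, network_metrics,
                           flip_area_sign = TRUE) {
  if (!all(community$site_id %in% attributes$site_id))
    stop("missing island attributes for: ",
         paste(setdiff(community$site_id, attributes$site_id), collapse = ", "))
  i <- match(community$site_id, attributes$site_id)
  out <- data.frame(
    site_id = community$site_id,
    site_class = community$site_class,
    DA = (if (flip_area_sign) -1 else 1) * log(attributes$area_ha[i]),
    PE = as.integer(community$site_class == "edge"),
    DM = log(attributes$distance_to_mainland_m[i]),
    FR = community$floral_resources,
    PL = community$plant_richness,
    AB = community$pollinator_abundance,
    PO = community$pollinator_richness,
    stringsAsFactors = FALSE)
  key <- paste(out$site_id, out$site_class)
  nkey <- paste(network_metrics$site_id, network_metrics$site_class)
  j <- match(key, nkey)
  out$RC <- network_metrics$relative_connectance[j]
  out$NE <- network_metrics$nodf[j]
  out$MO <- network_metrics$modularity[j]
  out$RO <- network_metrics$robustness[j]
  drop <- is.na(out$RC)
  if (any(drop)) {
    message("dropping ", sum(drop),
            " site x class row(s) without an interaction network")
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Tabulate network metrics for a set of networks
#'
#' @param networks Named list from [assemble_networks()].
#' @param global_links Link map from [global_link_map()].
#' @param n_restarts,seed Passed to [optimize_modules()].
#' @return Data.frame `site_id, site_class, relative_connectance, nodf,
#'   modularity, robustness`.
#' @export
network_metrics_table <- function(networks, global_links,
                                  n_restarts = 20, seed = 1) {
  rows <- lapply(networks, function(net) {
    m <- network_metrics(net, global_links, n_restarts = n_restarts,
                         seed = seed)
    data.frame(site_id = net$site_id, site_class = net$site_class,
               relative_connectance = m$relative_connectance,
               nodf = m$nodf, modularity = m$modularity,
               robustness = m$robustness, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# column name used for an interaction source "A:B"
interaction_col <- function(source) gsub(":", "_x_", source, fixed = TRUE)

# add centred product columns for every interaction source in the structure
add_interaction_columns <- function(table, structure) {
  ints <- grep(":", structure$paths$source, fixed = TRUE, value = TRUE)
  for (src in unique(ints)) {
    parts <- strsplit(src, ":", fixed = TRUE)[[1]]
    col <- interaction_col(src)
    a <- table[[parts[1]]]; b <- table[[parts[2]]]
    table[[col]] <- (a - mean(a)) * (b - mean(b))
  }
  table
}

#' Fit one component mixed model
#'
#' Gaussian responses use a linear mixed model (ML, not REML, so that AICs
#' are comparable across structures) with Satterthwaite-approximated
#' p-values via \pkg{lmerTest}; Poisson responses use a log-link GLMM via
#' [lme4::glmer()] with Wald z p-values.  Every model carries a random
#' intercept for the grouping unit (island identity) to absorb the
#' non-independence of paired edge/interior observations.
#'
#' @param response Response variable name.
#' @param predictors Character vector of predictor column names (may be
#'   empty: intercept-only model).
#' @param family `"gaussian"` or `"poisson"`.
#' @param table Analysis data.frame.
#' @param group Grouping column for the random intercept.
#' @param light Fit Gaussian models with plain [lme4::lmer()] (no
#'   Satterthwaite machinery); used by resampling refits that never read
#'   p-values.
#' @return The fitted merMod object.
#' @export
fit_component_model <- function(response, predictors, family, table,
                                group = "site_id", light = FALSE) {
  if (stats::sd(table[[response]]) == 0)
    stop("degenerate response (zero variance): ", response)
  for (p in predictors)
    if (stats::sd(table[[p]]) == 0)
      stop("zero-variance predictor '", p, "' in model for ", response)
  rhs <- paste(c(if (length(predictors)) predictors else "1",
                 paste0("(1 | ", group, ")")), collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  fit <- withCallingHandlers(
    if (family == "gaussian") {
      if (light) lme4::lmer(f, data = table, REML = FALSE)
      else lmerTest::lmer(f, data = table, REML = FALSE)
    } else {
      # nAGQ = 0 (marginal Laplace) is accurate at these group sizes and
      # halves the cost of the many refits in selection and resampling
      lme4::glmer(f, data = table, family = stats::poisson(), nAGQ = 0,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE))
    },
    warning = function(w) {
      if (grepl(paste0("failed to converge|unable to evaluate scaled ",
                       "gradient|singular|unidentifiable|Rescale|Hessian|",
                       "different scales"),
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  fit
}

# coefficient table of a fitted component model: estimate, se, p per term;
# light = TRUE skips the (comparatively costly) Satterthwaite summary and
# reports no p-values -- used by resampling refits that only need estimates
component_coefs <- function(fit, light = FALSE) {
  if (light) {
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    return(data.frame(term = names(b), estimate = unname(b),
                      se = unname(se), p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  s <- stats::coef(summary(fit))
  pcol <- grep("^Pr", colnames(s))
  if (!length(pcol)) {  # lmer without lmerTest: fall back to normal Wald
    z <- s[, "Estimate"] / s[, "Std. Error"]
    p <- 2 * stats::pnorm(-abs(z))
  } else p <- s[, pcol[1]]
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"], p = as.numeric(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

# number of estimated parameters: fixed effects + variance components
component_k <- function(fit, family) {
  length(lme4::fixef(fit)) + 1L + if (family == "gaussian") 1L else 0L
}

#' Standardized coefficients of a component model
#'
#' Gaussian: `beta * sd(x) / sd(y)`.  Poisson: `beta * sd(x) / sd(r)` with
#' `r = ln(y + 0.5)`, a transparent observed-scale proxy for the latent
#' response scale of the log link.
#'
#' @param fit Fitted component model.
#' @param response Response name.
#' @param family Model family.
#' @param table The analysis table the model was fitted to.
#' @return Named numeric vector of standardized coefficients (intercept
#'   excluded).
#' @export
standardized_coefficients <- function(fit, response, family, table) {
  b <- lme4::fixef(fit)
  b <- b[names(b) != "(Intercept)"]
  if (!length(b)) return(stats::setNames(numeric(0), character(0)))
  sdy <- if (family == "gaussian") stats::sd(table[[response]])
         else stats::sd(log(table[[response]] + 0.5))
  if (sdy == 0) stop("sd(response) is zero for ", response)
  sdx <- vapply(names(b), function(v) stats::sd(table[[v]]), 0)
  b * sdx / sdy
}

#' Independence basis set of a path structure
#'
#' One conditional-independence claim per non-adjacent variable pair:
#' pairs with a directed path in either direction, pairs joined by a
#' correlated-error arc and pairs of two exogenous variables (whose joint
#' distribution the model does not restrict) are excluded.  Each claim
#' conditions on the union of both variables' parents; the claim's
#' response is the variable later in topological order, since the
#' significance test in a non-Gaussian model depends on direction.
#'
#' @param structure A [path_structure()].
#' @return A list of claims, each a list with `response`, `other`,
#'   `conditioning`.
#' @export
basis_set <- function(structure) {
  paths <- structure$paths
  main <- paths[!grepl(":", paths$source, fixed = TRUE), , drop = FALSE]
  vars <- structure$topo_order
  adjacent <- function(a, b) {
    any(main$source == a & main$target == b) ||
      any(main$source == b & main$target == a)
  }
  correlated <- function(a, b) {
    cr <- structure$correlated
    if (is.null(cr)) return(FALSE)
    any((cr$a == a & cr$b == b) | (cr$a == b & cr$b == a))
  }
  parents <- function(v) main$source[main$target == v]
  claims <- list()
  for (i in seq_along(vars)[-1]) for (j in seq_len(i - 1)) {
    later <- vars[i]; earlier <- vars[j]
    if (later %in% structure$exogenous && earlier %in% structure$exogenous)
      next
    if (adjacent(later, earlier) || correlated(later, earlier)) next
    # response must be endogenous; swap if topological order put an
    # exogenous variable later (cannot happen for targets, but be safe)
    resp <- later; other <- earlier
    if (resp %in% structure$exogenous) { resp <- earlier; other <- later }
    claims[[length(claims) + 1L]] <- list(
      response = resp, other = other,
      conditioning = setdiff(union(parents(later), parents(earlier)),
                             c(later, earlier)))
  }
  claims
}

#' Fisher's C over the basis set
#'
#' Each claim is tested by adding the putatively independent variable to
#' the response's parent model (same family, same random intercept) and
#' taking its p-value.  `C = -2 * sum(ln p_i)` is chi-squared with `2k`
#' degrees of freedom under the hypothesised structure; an empty basis set
#' gives `C = 0`, `df = 0`, `p = 1` by convention.
#'
#' @param claims Basis set from [basis_set()].
#' @param table Analysis data.frame (with interaction columns added).
#' @param families Named family vector.
#' @param group Random-intercept grouping column.
#' @param cache Optional environment memoising fitted models.
#' @return A list with `C`, `df`, `p` and a data.frame `claims` (response,
#'   other, conditioning, p).
#' @export
fishers_c <- function(claims, table, families, group = "site_id",
                      cache = NULL) {
  if (!length(claims))
    return(list(C = 0, df = 0L, p = 1,
                claims = data.frame(response = character(0),
                                    other = character(0),
                                    conditioning = character(0),
                                    p = numeric(0))))
  rows <- lapply(claims, function(cl) {
    fam <- families[[cl$response]]
    preds <- c(cl$conditioning, cl$other)
    cf <- cached_fit(cl$response, preds, fam, table, group, cache)$coefs
    p <- cf$p[cf$term == cl$other]
    if (!length(p) || is.na(p))
      stop("claim model failed for ", cl$response, " ~ ", cl$other)
    data.frame(response = cl$response, other = cl$other,
               conditioning = paste(cl$conditioning, collapse = "+"),
               p = p, stringsAsFactors = FALSE)
  })
  claims_df <- do.call(rbind, rows)
  c(combine_fisher(claims_df$p), list(claims = claims_df))
}

#' Combine independence-claim p-values into Fisher's C
#'
#' `C = -2 * sum(ln p_i)`, chi-squared with `2k` degrees of freedom.
#'
#' @param p Vector of claim p-values.
#' @return List with `C`, `df`, `p`.
#' @export
combine_fisher <- function(p) {
  if (!length(p)) return(list(C = 0, df = 0L, p = 1))
  C <- -2 * sum(log(pmax(p, 1e-300)))
  df <- 2L * length(p)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

# fit + derived tables, memoised: repeated structure evaluations (backward
# selection) reuse both the model and its (costlier) coefficient summary
cached_fit <- function(response, predictors, family, table, group, cache,
                       light = FALSE) {
  make <- function() {
    fit <- fit_component_model(response, predictors, family, table, group,
                               light = light)
    list(fit = fit, coefs = component_coefs(fit, light = light),
         k = component_k(fit, family))
  }
  if (is.null(cache)) return(make())
  key <- paste(response, family, paste(sort(predictors), collapse = ","),
               sep = "|")
  if (is.null(cache[[key]])) cache[[key]] <- make()
  cache[[key]]
}

#' SEM-level AIC
#'
#' `AIC = C + 2K` where `C` is Fisher's C and `K` is the total number of
#' estimated parameters (fixed effects plus variance components) across
#' all component models.
#'
#' @param fisher_c Fisher's C statistic.
#' @param k Total parameter count.
#' @return The SEM AIC.
#' @export
sem_aic <- function(fisher_c, k) fisher_c + 2 * k

#' Fit a piecewise structural equation model
#'
#' Fits one mixed-effects component model per endogenous variable (family
#' as declared in the structure, random intercept for the grouping unit),
#' extracts raw and standardized path coefficients, tests the directed
#' separation claims of the basis set, and assembles Fisher's C and the
#' SEM-level AIC.
#'
#' @param structure A [path_structure()].
#' @param data Analysis data.frame (see [prepare_design()]).
#' @param group Grouping column for the random intercept (island identity).
#' @param cache Optional environment for memoising component fits (used by
#'   [backward_select()]).
#' @param dsep Compute the d-separation test and SEM AIC (default).  Set
#'   `FALSE` for resampling refits that only need path coefficients.
#' @return An object of class `psem_fit` with components `structure`,
#'   `models`, `coefficients` (per-path table with standardized values),
#'   `claims`, `fisher_c`, `dsep_df`, `dsep_p`, `k`, `aic`, `r2`, `data`.
#' @export
fit_psem <- function(structure, data, group = "site_id", cache = NULL,
                     dsep = TRUE) {
  table <- add_interaction_columns(data, structure)
  responses <- intersect(structure$topo_order, structure$endogenous)
  models <- list()
  coefs <- list()
  k_total <- 0L
  r2 <- numeric(0)
  light <- isFALSE(dsep)
  for (resp in responses) {
    sub <- structure$paths[structure$paths$target == resp, , drop = FALSE]
    preds <- interaction_col(sub$source)
    fam <- structure$families[[resp]]
    entry <- cached_fit(resp, preds, fam, table, group, cache,
                        light = light)
    fit <- entry$fit
    models[[resp]] <- fit
    k_total <- k_total + entry$k
    cf <- entry$coefs
    std <- standardized_coefficients(fit, resp, fam, table)
    i <- match(preds, cf$term)
    coefs[[resp]] <- data.frame(
      path_id = sub$path_id, source = sub$source, response = resp,
      estimate = cf$estimate[i], se = cf$se[i], p = cf$p[i],
      std_estimate = unname(std[preds]), stringsAsFactors = FALSE)
    if (!light) {
      y <- table[[resp]]
      r2[resp] <- stats::cor(stats::fitted(fit), y)^2
    }
  }
  if (dsep) {
    claims <- basis_set(structure)
    dsep <- fishers_c(claims, table, structure$families, group, cache)
  } else {
    dsep <- list(C = NA_real_, df = NA_integer_, p = NA_real_,
                 claims = NULL)
  }
  coefficients <- do.call(rbind, coefs)
  rownames(coefficients) <- NULL
  structure(list(structure = structure, models = models,
                 coefficients = coefficients, claims = dsep$claims,
                 fisher_c = dsep$C, dsep_df = dsep$df, dsep_p = dsep$p,
                 k = k_total, aic = sem_aic(dsep$C, k_total), r2 = r2,
                 data = table, group = group),
            class = "psem_fit")
}

#' @export
print.psem_fit <- function(x, ...) {
  cat("Piecewise SEM:", nrow(x$coefficients), "paths,",
      length(x$models), "component models\n")
  cat(sprintf("  Fisher's C = %.2f, df = %d, P = %.3f;  AIC = %.2f (K = %d)\n",
              x$fisher_c, x$dsep_df, x$dsep_p, x$aic, x$k))
  invisible(x)
}

#' @export
summary.psem_fit <- function(object, ...) {
  cat("Piecewise structural equation model\n")
  cat(sprintf("Fisher's C = %.2f on %d df (P = %.3f)%s\n", object$fisher_c,
              object$dsep_df, object$dsep_p,
              if (object$dsep_p <= 0.05) "  [structure rejected]" else ""))
  cat(sprintf("SEM AIC = %.2f with K = %d estimated parameters\n\n",
              object$aic, object$k))
  cf <- object$coefficients
  cf$sig <- ifelse(cf$p < 0.001, "***", ifelse(cf$p < 0.01, "**",
            ifelse(cf$p < 0.05, "*", "")))
  print(cf, digits = 3, row.names = FALSE)
  cat("\nR-squared (fitted vs observed):\n")
  print(round(object$r2, 3))
  invisible(object)
}

#' @export
coef.psem_fit <- function(object, standardized = TRUE, ...) {
  cf <- object$coefficients
  stats::setNames(if (standardized) cf$std_estimate else cf$estimate,
                  paste(cf$source, cf$response, sep = "->"))
}

#' @export
AIC.psem_fit <- function(object, ...) object$aic

#' Backward path selection by SEM AIC
#'
#' Greedy backward elimination: at each step every currently removable
#' direct path is dropped in turn, the SEM refitted, and the removal
#' giving the lowest SEM AIC is accepted; selection stops when no removal
#' lowers the AIC.  A main-effect path is not removable while an
#' interaction involving it remains on the same response.  Warns if the
#' selected model's d-separation test rejects (global P <= 0.05);
#' non-significant paths may be retained when their removal does not
#' improve AIC.  Deterministic: no randomness is involved.
#'
#' @param structure Initial [path_structure()].
#' @param data Analysis data.frame.
#' @param group Random-intercept grouping column.
#' @param trace Print progress.
#' @return The final `psem_fit`, with the removal history in attribute
#'   `"selection"`.
#' @export
backward_select <- function(structure, data, group = "site_id",
                            trace = FALSE) {
  cache <- new.env(parent = emptyenv())
  current <- fit_psem(structure, data, group, cache)
  history <- data.frame(step = 0L, removed_path = NA_integer_,
                        aic = current$aic)
  step <- 0L
  repeat {
    paths <- current$structure$paths
    if (nrow(paths) <= 1) break
    removable <- vapply(seq_len(nrow(paths)), function(i) {
      src <- paths$source[i]
      if (grepl(":", src, fixed = TRUE)) return(TRUE)
      ints <- paths$source[paths$target == paths$target[i] &
                           grepl(":", paths$source, fixed = TRUE)]
      !any(vapply(strsplit(ints, ":", fixed = TRUE),
                  function(pp) src %in% pp, TRUE))
    }, TRUE)
    cand_aic <- rep(Inf, nrow(paths))
    fits <- vector("list", nrow(paths))
    for (i in which(removable)) {
      reduced <- drop_path(current$structure, paths$path_id[i])
      fits[i] <- list(tryCatch(fit_psem(reduced, data, group, cache),
                               error = function(e) NULL))
      if (!is.null(fits[[i]])) cand_aic[i] <- fits[[i]]$aic
    }
    best <- which.min(cand_aic)
    if (!length(best) || cand_aic[best] >= current$aic - 1e-9) break
    step <- step + 1L
    if (trace)
      cat(sprintf("step %d: drop path %d (%s -> %s), AIC %.2f -> %.2f\n",
                  step, paths$path_id[best], paths$source[best],
                  paths$target[best], current$aic, cand_aic[best]))
    current <- fits[[best]]
    history <- rbind(history, data.frame(step = step,
                                         removed_path = paths$path_id[best],
                                         aic = current$aic))
  }
  if (current$dsep_p <= 0.05)
    warning("selected model's d-separation test rejects (P = ",
            format(current$dsep_p, digits = 3), ")")
  attr(current, "selection") <- history
  current
}

# remove one directed path (by id) from a structure
drop_path <- function(structure, path_id) {
  paths <- structure$paths[structure$paths$path_id != path_id, , drop = FALSE]
  if (!nrow(paths)) stop("cannot remove the last path")
  path_structure(paths, structure$families, structure$correlated)
}
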