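#' Build the mainland reference pool
#'
#' Collects the mainland ("unfragmented" reference) transects into per-class
#' pools used by the two constrained null models: Null model I resamples
#' whole transects, Null model II resamples individual visitation events.
#' The pool also carries the mainland per-plant floral totals (used to order
#' plant extinctions in null networks) and the all-sites global link map.
#'
#' @param records A validated survey-record data.frame covering mainland
#'   (and usually island) sites; mainland rows must have
#'   `is_mainland = TRUE`.
#' @param global_links Optional link map for relative connectance; defaults
#'   to [global_link_map()] over all of `records`.
#' @return An object of class `reference_pool`.
#' @export
build_reference_pool <- function(records, global_links = global_link_map(records)) {
  ml <- records[records$is_mainland, , drop = FALSE]
  pool <- list()
  for (cls in c("edge", "interior")) {
    sub <- ml[ml$site_class == cls, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("reference pool has no mainland records for class: ", cls)
    pool[[cls]] <- split(sub, sub$transect_id, drop = TRUE)
  }
  fa <- tapply(ml$floral_area, ml$plant_species, sum)
  # per-transect summaries and pooled event tables, precomputed so the
  # thousands of null draws never re-aggregate raw records
  summarise_tr <- function(tr) {
    v <- tr$visit_count > 0
    list(fr = sum(tr$floral_area), ab = sum(tr$visit_count),
         plants = unique(tr$plant_species),
         polls = unique(tr$pollinator_species[v]))
  }
  structure(
    list(edge = pool$edge, interior = pool$interior,
         global_links = global_links,
         species_floral_area = stats::setNames(as.numeric(fa), names(fa)),
         transect_summaries = list(
           edge = lapply(pool$edge, summarise_tr),
           interior = lapply(pool$interior, summarise_tr)),
         events = list(edge = aggregate_events(pool$edge),
                       interior = aggregate_events(pool$interior))),
    class = "reference_pool")
}

aggregate_events <- function(transects) {
  recs <- do.call(rbind, transects)
  v <- recs[recs$visit_count > 0, , drop = FALSE]
  if (nrow(v) == 0)
    return(data.frame(plant = character(0), pollinator = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  agg <- stats::aggregate(visit_count ~ plant_species + pollinator_species,
                          data = v, FUN = sum)
  data.frame(plant = agg$plant_species, pollinator = agg$pollinator_species,
             weight = agg$visit_count, stringsAsFactors = FALSE)
}

#' @export
print.reference_pool <- function(x, ...) {
  cat("Mainland reference pool:", length(x$edge), "edge and",
      length(x$interior), "interior transects;",
      length(x$global_links), "global links\n")
  invisible(x)
}

#' Null model I: transect-count-constrained community draw
#'
#' Draws `n_transects` whole transects with replacement from the matching
#' mainland class pool, pools their records (duplicated draws count twice
#' towards sums; richness is over the union of species) and returns the
#' community metrics of the null assemblage.  This constrains sampling
#' effort to that of the focal island so that observed-vs-null differences
#' cannot be explained by a passive sampling effect.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param pool A [build_reference_pool()] object.
#' @param n_transects Number of transects to draw (the island's own count).
#' @param site_class `"edge"` or `"interior"`.
#' @return A list as from [community_metrics()].
#' @export
null_draw_transects <- function(pool, n_transects, site_class) {
  site_class <- match.arg(site_class, c("edge", "interior"))
  if (n_transects < 1) stop("n_transects must be >= 1")
  sm <- pool$transect_summaries[[site_class]]
  if (is.null(sm)) {                 # pool built by hand: aggregate now
    tr <- pool[[site_class]]
    idx <- sample.int(length(tr), n_transects, replace = TRUE)
    return(community_metrics(do.call(rbind, tr[idx])))
  }
  idx <- sample.int(length(sm), n_transects, replace = TRUE)
  drawn <- sm[idx]
  list(
    floral_resources = sum(vapply(drawn, `[[`, 0, "fr")),
    plant_richness = length(unique(unlist(lapply(drawn, `[[`, "plants")))),
    pollinator_abundance = sum(vapply(drawn, `[[`, 0, "ab")),
    pollinator_richness = length(unique(unlist(lapply(drawn, `[[`,
                                                      "polls"))))
  )
}

#' Null model II: interaction- and richness-constrained network draw
#'
#' Draws `n_interactions` individual visitation events with replacement
#' from the pooled mainland class events (each event sampled with
#' probability proportional to its link's total visit count), accepting the
#' draw only when the resulting network contains exactly `n_plants` plant
#' and `n_pollinators` pollinator species -- the focal island's network
#' size.  After `max_tries` rejections a documented repair step swaps
#' events between links to hit the species-count targets exactly; a network
#' that underwent repair carries attribute `repaired = TRUE`.  Plant floral
#' areas of the null network are the mainland per-species totals.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param pool A [build_reference_pool()] object.
#' @param n_interactions Total visitation events to draw (the network's
#'   total weight); must be at least `max(n_plants, n_pollinators)`.
#' @param n_plants,n_pollinators Target species richness of the null
#'   network.
#' @param site_class `"edge"` or `"interior"`.
#' @param max_tries Rejection-sampling cap before repair (default 10000).
#' @param repair If `FALSE`, exhausting `max_tries` is an error.
#' @return A [bipartite_network()] (site_id `"null"`).
#' @export
null_draw_network <- function(pool, n_interactions, n_plants, n_pollinators,
                              site_class, max_tries = 10000, repair = TRUE) {
  site_class <- match.arg(site_class, c("edge", "interior"))
  if (n_interactions < max(n_plants, n_pollinators))
    stop("n_interactions must be >= max(n_plants, n_pollinators)")
  ev <- pool_events(pool, site_class)
  pool_np <- length(unique(ev$plant)); pool_nq <- length(unique(ev$pollinator))
  if (n_plants > pool_np || n_pollinators > pool_nq)
    stop("requested richness exceeds the reference pool's richness")
  if (n_plants < 1 || n_pollinators < 1)
    stop("targets must be >= 1")

  prob <- ev$weight / sum(ev$weight)
  repaired <- FALSE
  draw <- NULL
  for (try in seq_len(max_tries)) {
    idx <- sample.int(nrow(ev), n_interactions, replace = TRUE, prob = prob)
    if (length(unique(ev$plant[idx])) == n_plants &&
        length(unique(ev$pollinator[idx])) == n_pollinators) {
      draw <- idx
      break
    }
    if (try == max_tries) draw_last <- idx
  }
  if (is.null(draw)) {
    if (!repair)
      stop("null network draw: max_tries exhausted without meeting the ",
           "richness constraints")
    draw <- repair_draw(ev, draw_last, n_plants, n_pollinators, prob)
    repaired <- TRUE
  }
  net <- events_to_network(ev, draw, pool, site_class)
  attr(net, "repaired") <- repaired
  net
}

# pooled event (link) table for one class: one row per realised link with
# its total visit count across the class's mainland transects
pool_events <- function(pool, site_class) {
  if (!is.null(pool$events[[site_class]])) return(pool$events[[site_class]])
  aggregate_events(pool[[site_class]])
}

# constructive repair when rejection sampling cannot hit the targets:
# choose the species sets first (probability proportional to marginal
# visit totals), cover every chosen species with one event on a link
# internal to the chosen sets, then fill the remaining events from those
# internal links proportionally to their weights -- the constraints then
# hold by construction
repair_draw <- function(ev, idx, n_plants, n_pollinators, prob) {
  n_interactions <- length(idx)
  pw <- tapply(ev$weight, ev$plant, sum)
  qw <- tapply(ev$weight, ev$pollinator, sum)
  for (attempt in 1:200) {
    # draw one side first, then the other side from its realised partners,
    # so the chosen sets are always mutually coverable; alternate which
    # side leads between attempts
    if (attempt %% 2L == 1L) {
      P <- sample(names(pw), n_plants, prob = pw)
      subP <- which(ev$plant %in% P)
      partners <- tapply(ev$weight[subP], ev$pollinator[subP], sum)
      if (length(partners) < n_pollinators) next
      Q <- sample(names(partners), n_pollinators, prob = partners)
    } else {
      Q <- sample(names(qw), n_pollinators, prob = qw)
      subQ <- which(ev$pollinator %in% Q)
      partners <- tapply(ev$weight[subQ], ev$plant[subQ], sum)
      if (length(partners) < n_plants) next
      P <- sample(names(partners), n_plants, prob = partners)
    }
    sub <- which(ev$plant %in% P & ev$pollinator %in% Q)
    if (!all(P %in% ev$plant[sub]) || !all(Q %in% ev$pollinator[sub])) next
    cover <- integer(0)
    for (p in P) {
      cand <- sub[ev$plant[sub] == p]
      cover <- c(cover, cand[sample.int(length(cand), 1)])
    }
    for (q in setdiff(Q, ev$pollinator[cover])) {
      cand <- sub[ev$pollinator[sub] == q]
      cover <- c(cover, cand[sample.int(length(cand), 1)])
    }
    if (length(cover) > n_interactions) next
    fill <- sample(sub, n_interactions - length(cover), replace = TRUE,
                   prob = prob[sub])
    return(c(cover, fill))
  }
  stop("null network draw: repair failed to satisfy the richness constraints")
}

events_to_network <- function(ev, idx, pool, site_class) {
  plants <- sort(unique(ev$plant[idx]))
  polls <- sort(unique(ev$pollinator[idx]))
  w <- matrix(0L, length(plants), length(polls),
              dimnames = list(plants, polls))
  tab <- table(factor(ev$plant[idx], plants),
               factor(ev$pollinator[idx], polls))
  w[] <- as.integer(tab)
  fa <- pool$species_floral_area[plants]
  fa[is.na(fa)] <- 0
  names(fa) <- plants
  bipartite_network(w, site_id = "null", site_class = site_class,
                    plant_floral_area = fa)
}

#' Standardized effect size against a null distribution
#'
#' `SES = (obs - mean(null)) / sd(null)`; the observed value is flagged
#' significant (two-tailed, 5% level) when it falls outside the empirical
#' 2.5-97.5 percentile interval of the null values.  A degenerate null
#' (zero s.d.) yields `ses = NA` and significance decided by exact
#' inequality with the constant null value.
#'
#' @param observed Observed value.
#' @param null_values Numeric vector of null draws (length >= 2).
#' @param quantity Optional name carried in the output.
#' @return An object of class `null_envelope`: list with `quantity`,
#'   `observed`, `null_mean`, `null_sd`, `ci_low`, `ci_high`, `ses`,
#'   `significant`, `n_draws`, `degenerate`.
#' @export
ses_compare <- function(observed, null_values, quantity = "quantity") {
  null_values <- null_values[is.finite(null_values)]
  if (length(null_values) < 2) stop("need at least 2 null values")
  m <- mean(null_values); s <- stats::sd(null_values)
  ci <- unname(stats::quantile(null_values, c(0.025, 0.975), type = 7))
  degenerate <- s == 0
  structure(
    list(quantity = quantity, observed = observed, null_mean = m,
         null_sd = s, ci_low = ci[1], ci_high = ci[2],
         ses = if (degenerate) NA_real_ else (observed - m) / s,
         significant = if (degenerate) observed != m
                       else (observed < ci[1] || observed > ci[2]),
         n_draws = length(null_values), degenerate = degenerate),
    class = "null_envelope")
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf("%s: obs %.4g, null %.4g +/- %.4g [%.4g, %.4g], SES %.3g%s\n",
              x$quantity, x$observed, x$null_mean, x$null_sd,
              x$ci_low, x$ci_high,
              if (is.na(x$ses)) NA else x$ses,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Null-model envelopes for island community metrics
#'
#' For every island x habitat class, compares the observed community metrics
#' (FR, PL, AB, PO) with `n_draws` Null model I draws matched to the
#' island's own transect count in that class.
#'
#' @param records Validated survey records (islands + mainland).
#' @param attributes Island attribute table (supplies `n_transect_pairs`).
#' @param pool A [build_reference_pool()] object.
#' @param n_draws Null draws per island x class (study scale: 1000).
#' @param seed Integer seed.
#' @return A data.frame, one row per island x class x quantity, with
#'   envelope columns
#'   `site_id,site_class,quantity,observed,null_mean,null_sd,ci_low,ci_high,ses,significant,n_draws,seed`.
#' @export
null_model_communities <- function(records, attributes, pool,
                                   n_draws = 1000, seed = 1) {
  isl <- records[!records$is_mainland, , drop = FALSE]
  obs <- community_summaries(isl)
  quantities <- c("floral_resources", "plant_richness",
                  "pollinator_abundance", "pollinator_richness")
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(obs))) {
    sid <- obs$site_id[i]; cls <- obs$site_class[i]
    ntr <- attributes$n_transect_pairs[match(sid, attributes$site_id)]
    if (is.na(ntr)) stop("no attributes for island: ", sid)
    draws <- replicate(n_draws,
                       unlist(null_draw_transects(pool, ntr, cls)))
    for (q in quantities) {
      env <- ses_compare(obs[[q]][i], draws[q, ], quantity = q)
      out[[length(out) + 1L]] <- data.frame(
        site_id = sid, site_class = cls, quantity = q,
        observed = env$observed, null_mean = env$null_mean,
        null_sd = env$null_sd, ci_low = env$ci_low, ci_high = env$ci_high,
        ses = env$ses, significant = env$significant,
        n_draws = env$n_draws, seed = seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Null-model envelopes for island network metrics
#'
#' For every island x habitat class network, compares the observed
#' architecture metrics (RC, NODF, modularity, robustness) with `n_draws`
#' Null model II networks matched to the observed network's total
#' interactions and species counts.
#'
#' @param networks Named list from [assemble_networks()] (islands only).
#' @param pool A [build_reference_pool()] object.
#' @param n_draws Null draws per network.
#' @param seed Integer seed.
#' @param n_restarts Modularity restarts used inside each null draw
#'   (smaller than the observed-network default for tractability).
#' @return A data.frame as in [null_model_communities()].
#' @export
null_model_networks <- function(networks, pool, n_draws = 1000, seed = 1,
                                n_restarts = 5) {
  set.seed(seed)
  quantities <- c("relative_connectance", "nodf", "modularity", "robustness")
  out <- list()
  for (net in networks) {
    obs <- network_metrics(net, pool$global_links)
    draws <- replicate(n_draws, {
      nn <- null_draw_network(pool,
                              n_interactions = sum(net$weights),
                              n_plants = nrow(net$weights),
                              n_pollinators = ncol(net$weights),
                              site_class = net$site_class)
      unlist(network_metrics(nn, pool$global_links,
                             n_restarts = n_restarts,
                             seed = sample.int(1e6, 1)))
    })
    for (q in quantities) {
      env <- ses_compare(obs[[q]], draws[q, ], quantity = q)
      out[[length(out) + 1L]] <- data.frame(
        site_id = net$site_id, site_class = net$site_class, quantity = q,
        observed = env$observed, null_mean = env$null_mean,
        null_sd = env$null_sd, ci_low = env$ci_low, ci_high = env$ci_high,
        ses = env$ses, significant = env$significant,
        n_draws = env$n_draws, seed = seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
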