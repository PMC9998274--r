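#' Construct a bipartite plant-pollinator network
#'
#' A weighted plant x pollinator interaction matrix for one habitat class
#' (forest edge or interior) at one site, together with per-plant floral
#' resource totals.  Cell weights are pooled visit counts.
#'
#' @param weights Non-negative integer matrix, plants in rows, pollinators
#'   in columns, with dimnames.
#' @param site_id Site identifier.
#' @param site_class `"edge"` or `"interior"`.
#' @param plant_floral_area Named non-negative numeric vector of summed
#'   floral resource area per plant; must cover every plant row.
#' @return An object of class `bipartite_network`.
#' @export
bipartite_network <- function(weights, site_id = "site", site_class = "edge",
                              plant_floral_area = NULL) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)))
    rownames(weights) <- paste0("plant_", seq_len(nrow(weights)))
  if (is.null(colnames(weights)))
    colnames(weights) <- paste0("poll_", seq_len(ncol(weights)))
  if (any(weights < 0)) stop("interaction weights must be non-negative")
  storage.mode(weights) <- "integer"
  if (is.null(plant_floral_area)) {
    plant_floral_area <- stats::setNames(rep(0, nrow(weights)),
                                         rownames(weights))
  }
  if (!all(rownames(weights) %in% names(plant_floral_area)))
    stop("plant_floral_area must name every plant in the matrix")
  structure(
    list(site_id = site_id,
         site_class = match.arg(site_class, c("edge", "interior")),
         weights = weights,
         plant_floral_area = plant_floral_area[rownames(weights)]),
    class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("Bipartite plant-pollinator network:", x$site_id,
      paste0("(", x$site_class, ")\n"))
  cat("  ", nrow(x$weights), "plants x", ncol(x$weights), "pollinators;",
      sum(x$weights), "visits over", sum(x$weights > 0), "links\n")
  invisible(x)
}

#' Assemble per-site, per-habitat-class interaction networks
#'
#' Pools all survey rounds and transects of each habitat class at each site
#' (the multi-year pooling step of the study design) and builds one weighted
#' network per `(site_id, site_class)` group that contains at least one
#' record.  Cell weights are summed visit counts; `plant_floral_area` is the
#' summed floral resource area per plant in the group.  Plants with floral
#' records but no visits do not enter the matrix (they still count towards
#' community summaries, see [community_summaries()]).
#'
#' @param records A validated survey-record data.frame.
#' @return A named list of [bipartite_network()] objects; names are
#'   `"<site_id>.<site_class>"`.
#' @export
assemble_networks <- function(records) {
  groups <- split(records,
                  list(site_id = records$site_id,
                       site_class = records$site_class),
                  drop = TRUE, sep = "\r")
  out <- lapply(groups, function(g) {
    fa <- tapply(g$floral_area, g$plant_species, sum)
    v <- g[g$visit_count > 0, , drop = FALSE]
    if (nrow(v) == 0) return(NULL)  # no realised interactions: no network
    plants <- sort(unique(v$plant_species))
    polls <- sort(unique(v$pollinator_species))
    w <- matrix(0L, length(plants), length(polls),
                dimnames = list(plants, polls))
    if (nrow(v)) {
      agg <- stats::aggregate(visit_count ~ plant_species + pollinator_species,
                              data = v, FUN = sum)
      w[cbind(agg$plant_species, agg$pollinator_species)] <-
        as.integer(agg$visit_count)
    }
    fa_full <- stats::setNames(rep(0, length(plants)), plants)
    hit <- intersect(plants, names(fa))
    fa_full[hit] <- fa[hit]
    bipartite_network(w, site_id = g$site_id[1], site_class = g$site_class[1],
                      plant_floral_area = fa_full)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  names(out) <- vapply(out, function(n) paste(n$site_id, n$site_class,
                                              sep = "."), "")
  out
}

#' Community-structure summaries per site and habitat class
#'
#' Computes, for each `(site_id, site_class)` group: floral resources
#' (summed floral area, FR), plant richness (distinct flowering plant
#' species, PL), pollinator abundance (summed visit counts, AB) and
#' pollinator richness (distinct visiting species, PO).
#'
#' @param records A validated survey-record data.frame.
#' @return A data.frame with columns `site_id, site_class, is_mainland,
#'   floral_resources, plant_richness, pollinator_abundance,
#'   pollinator_richness`.
#' @export
community_summaries <- function(records) {
  groups <- split(records,
                  list(records$site_id, records$site_class),
                  drop = TRUE, sep = "\r")
  rows <- lapply(groups, function(g)
    cbind(data.frame(site_id = g$site_id[1], site_class = g$site_class[1],
                     is_mainland = g$is_mainland[1],
                     stringsAsFactors = FALSE),
          as.data.frame(community_metrics(g))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site_id, out$site_class), , drop = FALSE]
}

#' Community metrics of one record group
#'
#' @param records Survey records of a single `(site, class)` group (or any
#'   pooled collection to summarise as one community).
#' @return A list with `floral_resources`, `plant_richness`,
#'   `pollinator_abundance`, `pollinator_richness`.
#' @export
community_metrics <- function(records) {
  visited <- records$visit_count > 0
  list(
    floral_resources = sum(records$floral_area),
    plant_richness = length(unique(records$plant_species)),
    pollinator_abundance = sum(records$visit_count),
    pollinator_richness = length(unique(records$pollinator_species[visited]))
  )
}

#' Global link map across all sites and years
#'
#' Enumerates every distinct plant-pollinator link realised anywhere in the
#' pooled records (all sites, all rounds).  This is the reference universe
#' used by [relative_connectance()].
#'
#' @param records A validated survey-record data.frame (all sites pooled).
#' @return A character vector of link keys `"plantpollinator"`, plus
#'   attributes `plants` and `pollinators` listing the species universe.
#' @export
global_link_map <- function(records) {
  v <- records[records$visit_count > 0, , drop = FALSE]
  keys <- unique(link_key(v$plant_species, v$pollinator_species))
  structure(keys,
            plants = sort(unique(v$plant_species)),
            pollinators = sort(unique(v$pollinator_species)))
}

link_key <- function(plant, pollinator) paste(plant, pollinator, sep = "\x1f")
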