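#' Read transect survey records
#'
#' Reads the long-format visitation table: one row per observation of a
#' pollinator species on a flowering plant species on one transect in one
#' survey round.  Rows with `visit_count = 0` are flowering-plant-only
#' observations (the plant was surveyed in flower but received no visit);
#' they contribute to floral resources and plant richness but not to the
#' interaction network.
#'
#' Expected columns:
#' `site_id, transect_id, site_class, is_mainland, survey_round,
#'  plant_species, pollinator_species, visit_count, floral_area`.
#'
#' @param path Path to a UTF-8 comma-separated file with a header row.
#' @param strict If `TRUE` (default) any invalid row (negative
#'   `visit_count` or `floral_area`, bad `site_class`) is an error naming
#'   the offending row; if `FALSE` such rows are dropped with a warning.
#' @return A validated `data.frame` of survey records, in file order.
#' @seealso [read_island_attributes()], [assemble_networks()]
#' @export
read_survey_records <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_survey_records(df, strict = strict)
}

#' Validate a survey-record table
#'
#' Checks the schema and row-level invariants of a survey-record table and
#' normalises species names (whitespace trimmed, internal runs collapsed).
#'
#' @param df A data.frame shaped like the output of [read_survey_records()].
#' @inheritParams read_survey_records
#' @return The validated, normalised data.frame.
#' @export
validate_survey_records <- function(df, strict = TRUE) {
  required <- c("site_id", "transect_id", "site_class", "is_mainland",
                "survey_round", "plant_species", "pollinator_species",
                "visit_count", "floral_area")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("survey records are missing required column(s): ",
         paste(missing, collapse = ", "))

  squeeze <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))
  df$plant_species <- squeeze(df$plant_species)
  df$pollinator_species <- squeeze(df$pollinator_species)
  df$site_class <- squeeze(df$site_class)
  df$site_id <- squeeze(df$site_id)
  df$transect_id <- squeeze(df$transect_id)
  df$is_mainland <- as.logical(df$is_mainland)
  df$visit_count <- as.numeric(df$visit_count)
  df$floral_area <- as.numeric(df$floral_area)
  df$survey_round <- as.integer(df$survey_round)

  bad <- which(
    is.na(df$visit_count) | df$visit_count < 0 |
    df$visit_count != floor(df$visit_count) |
    is.na(df$floral_area) | df$floral_area < 0 |
    !(df$site_class %in% c("edge", "interior")) |
    is.na(df$survey_round) | df$survey_round < 1 |
    is.na(df$is_mainland)
  )
  if (length(bad)) {
    if (strict)
      stop("invalid survey record(s) at row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "")
    warning("dropping ", length(bad), " invalid survey record(s)")
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df$visit_count <- as.integer(df$visit_count)
  df
}

#' Write survey records to CSV
#'
#' @param records A validated survey-record data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_survey_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the island attribute table
#'
#' Expected columns:
#' `site_id, area_ha, distance_to_mainland_m, n_transect_pairs`.
#' Duplicate `site_id`s and non-positive areas are rejected.
#'
#' @param path Path to a comma-separated file with a header row.
#' @return A data.frame with one row per island.
#' @export
read_island_attributes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_island_attributes(df)
}

#' Validate an island attribute table
#'
#' @param df A data.frame shaped like the output of
#'   [read_island_attributes()].
#' @return The validated data.frame.
#' @export
validate_island_attributes <- function(df) {
  required <- c("site_id", "area_ha", "distance_to_mainland_m",
                "n_transect_pairs")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("island attributes are missing required column(s): ",
         paste(missing, collapse = ", "))
  df$site_id <- trimws(as.character(df$site_id))
  dup <- df$site_id[duplicated(df$site_id)]
  if (length(dup))
    stop("duplicated site_id in island attributes: ",
         paste(unique(dup), collapse = ", "))
  if (any(is.na(df$area_ha) | df$area_ha <= 0))
    stop("area_ha must be positive for every island")
  if (any(is.na(df$distance_to_mainland_m) | df$distance_to_mainland_m <= 0))
    stop("distance_to_mainland_m must be positive for every island")
  if (any(is.na(df$n_transect_pairs) | df$n_transect_pairs < 1))
    stop("n_transect_pairs must be >= 1 for every island")
  df$n_transect_pairs <- as.integer(df$n_transect_pairs)
  df
}

#' Write an island attribute table to CSV
#'
#' @param attributes A validated island-attribute data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_island_attributes <- function(attributes, path) {
  utils::write.csv(attributes, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an interaction matrix to CSV
#'
#' Plant rows by pollinator columns; the first column holds the plant name.
#' Reading the file back with [read_interaction_matrix()] reproduces the
#' matrix exactly (integer weights).
#'
#' @param network A [bipartite_network()] object, or a plain numeric matrix
#'   with dimnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_interaction_matrix <- function(network, path) {
  w <- if (inherits(network, "bipartite_network")) network$weights else network
  rn <- if (is.null(rownames(w))) character(nrow(w)) else rownames(w)
  df <- data.frame(plant = rn, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(w) > 0) df <- cbind(df, as.data.frame(w, check.names = FALSE))
  if (nrow(w) == 0) df <- df[0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an interaction matrix from CSV
#'
#' @param path Path to a matrix CSV written by [write_interaction_matrix()].
#' @return An integer matrix (plants x pollinators) with dimnames.
#' @export
read_interaction_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        encoding = "UTF-8")
  if (!"plant" %in% names(df)) stop("matrix file lacks the 'plant' column")
  m <- as.matrix(df[, setdiff(names(df), "plant"), drop = FALSE])
  rownames(m) <- df$plant
  storage.mode(m) <- "integer"
  m
}
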