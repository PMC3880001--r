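# Columnar text serialisation of populations, frames and configs.
#
# Documented headers:
#   meshblocks.tsv: mb_id, au_id, stratum_id, census_persons,
#     census_dwellings, dwellings_current (optional), dens_maori,
#     dens_pacific, dens_asian, dens_maori_au, dens_pacific_au,
#     dens_asian_au, roll_addresses
#   households.tsv: household_id, mb_id, au_id, stratum_id, n_persons,
#     n_adults, n_children, eth_maori, eth_pacific, eth_asian, roll_flag
#   persons.tsv: person_id, household_id, mb_id, au_id, stratum_id,
#     is_adult, eth_maori, eth_pacific, eth_asian, on_roll_maori_descent,
#     <one column per outcome>

#' Write a population to a directory of TSV files
#'
#' @param population A `df_population`.
#' @param dir Target directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "df_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    meshblocks = file.path(dir, "meshblocks.tsv"),
    households = file.path(dir, "households.tsv"),
    persons = file.path(dir, "persons.tsv"),
    strata = file.path(dir, "strata.tsv")
  )
  readr::write_tsv(population$meshblocks, paths[["meshblocks"]])
  readr::write_tsv(population$households, paths[["households"]])
  readr::write_tsv(population$persons, paths[["persons"]])
  readr::write_tsv(population$strata, paths[["strata"]])
  invisible(paths)
}

#' Read a population written by [write_population()]
#'
#' Rebuilds the `df_population` object, including the fast selection
#' indexes. Tables must preserve the generation ordering (households by
#' meshblock, persons by household, ids equal to row numbers).
#'
#' @param dir Directory containing the TSV files.
#' @param config Optional [population_config()] to re-attach.
#' @return A `df_population`.
#' @export
read_population <- function(dir, config = NULL) {
  rd <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  pop <- structure(
    list(strata = rd("strata.tsv"), meshblocks = rd("meshblocks.tsv"),
         households = rd("households.tsv"), persons = rd("persons.tsv"),
         config = config),
    class = "df_population"
  )
  for (tb in c("households", "persons")) {
    for (col in intersect(names(pop[[tb]]),
                          c("is_adult", "eth_maori", "eth_pacific", "eth_asian",
                            "on_roll_maori_descent", "roll_flag"))) {
      pop[[tb]][[col]] <- as.logical(pop[[tb]][[col]])
    }
  }
  if (!identical(pop$households$household_id, seq_len(nrow(pop$households))) ||
      !identical(pop$persons$person_id, seq_len(nrow(pop$persons)))) {
    # ids as row numbers are what the selection indexes assume
    pop$households$household_id <- seq_len(nrow(pop$households))
    pop$persons$person_id <- seq_len(nrow(pop$persons))
  }
  pop$index <- build_selection_index(pop)
  pop
}

#' Read a user-supplied meshblock frame
#'
#' Accepts any columnar text file with the documented meshblock headers
#' (`mb_id`, `stratum_id`, `census_persons`, `census_dwellings`, the six
#' density columns, `roll_addresses`; `au_id` and `dwellings_current`
#' default sensibly when absent).
#'
#' @param path TSV/CSV file path.
#' @return A `df_frame` tibble.
#' @export
read_frame <- function(path) {
  frame <- if (grepl("\\.csv$", path)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("mb_id", "stratum_id", "census_persons", "census_dwellings",
            "dens_maori", "dens_pacific", "dens_asian",
            "dens_maori_au", "dens_pacific_au", "dens_asian_au",
            "roll_addresses")
  missing <- setdiff(need, names(frame))
  if (length(missing)) {
    abort(paste("frame is missing required column(s):",
                paste(missing, collapse = ", ")))
  }
  if (!"au_id" %in% names(frame)) frame$au_id <- frame$mb_id
  if (!"dwellings_current" %in% names(frame)) {
    frame$dwellings_current <- frame$census_dwellings
  }
  class(frame) <- c("df_frame", class(tibble()))
  frame
}

#' Write / read a design configuration as YAML
#'
#' @param design A [design_config()].
#' @param path YAML file path.
#' @return `write_design_config` returns the path invisibly;
#'   `read_design_config` returns a `df_design`.
#' @export
write_design_config <- function(design, path) {
  stopifnot(inherits(design, "df_design"))
  x <- unclass(design)
  x$targeting_coefficients <- as.list(x$targeting_coefficients)
  x$response_prob <- as.list(x$response_prob)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$targeting_coefficients <- unlist(x$targeting_coefficients)
  x$response_prob <- unlist(x$response_prob)
  do.call(design_config, x)
}
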