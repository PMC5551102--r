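#' precocity: size at onset of flowering and its phylogenetic correlates
#'
#' Tools to estimate the relative plant size at which 50% of individuals in a
#' population flower (S0.5) from individual flowering records, to build a
#' calibrated taxonomy-based phylogeny, to test for phylogenetic signal
#' (Blomberg's K, Pagel's lambda), and to fit phylogenetic linear regressions
#' under the lambda covariance model with all-subsets AIC selection.
#'
#' @keywords internal
#' @aliases precocity-package
"_PACKAGE"

.sex_levels   <- c("dioecious", "cosexual")
.leaf_levels  <- c("deciduous", "evergreen")
.fruit_levels <- c("fleshy", "dry")

#' Read an individual-level observation table
#'
#' Reads a CSV of individual flowering records: one row per surveyed plant,
#' with its species, stem diameter (cm) and whether it bore flowers.
#'
#' @param path Path to a CSV file with header columns \code{species},
#'   \code{diameter_cm}, \code{flowered} (0/1 or true/false) and optionally
#'   \code{sex} (\code{male}, \code{female} or \code{unknown}).
#' @return A data frame with columns \code{species} (character),
#'   \code{diameter_cm} (numeric), \code{flowered} (logical) and \code{sex}
#'   (character, \code{"unknown"} where absent), row order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(species = "A", diameter_cm = c(2, 9),
#'                      flowered = c(0, 1)), f, row.names = FALSE)
#' read_observations(f)
read_observations <- function(path) {
  d <- read_csv_checked(path, "observation table")
  need <- c("species", "diameter_cm", "flowered")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$species <- as.character(d$species)
  if (any(!nzchar(d$species) | is.na(d$species)))
    stop("empty species identifier in row(s) ",
         paste(which(!nzchar(d$species) | is.na(d$species)), collapse = ", "),
         call. = FALSE)
  d$diameter_cm <- as.numeric(d$diameter_cm)
  bad <- which(!is.finite(d$diameter_cm) | d$diameter_cm <= 0)
  if (length(bad) > 0L)
    stop("non-positive or non-numeric diameter_cm in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  d$flowered <- parse_logical(d$flowered, "flowered")
  if ("sex" %in% names(d)) {
    d$sex <- as.character(d$sex)
    d$sex[is.na(d$sex) | !nzchar(d$sex)] <- "unknown"
    bad <- !d$sex %in% c("male", "female", "unknown")
    if (any(bad))
      stop("invalid sex value(s): ", paste(unique(d$sex[bad]), collapse = ", "),
           call. = FALSE)
  } else {
    d$sex <- "unknown"
  }
  d[, c("species", "diameter_cm", "flowered", "sex")]
}

#' Write an observation table to CSV
#'
#' @param obs A data frame as returned by [read_observations()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_observations <- function(obs, path) {
  out <- obs
  out$flowered <- as.integer(out$flowered)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, what) {
  tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
           error = function(e)
             stop(what, " at '", path, "' is empty or malformed: ",
                  conditionMessage(e), call. = FALSE))
}

# tolerate the common boolean encodings {0,1,true,false,TRUE,FALSE}
parse_logical <- function(x, what) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true")] <- TRUE
  out[s %in% c("0", "false")] <- FALSE
  if (anyNA(out))
    stop("column '", what, "' must be 0/1 or true/false; offending row(s): ",
         paste(which(is.na(out)), collapse = ", "), call. = FALSE)
  as.logical(out)
}

#' Read a species-trait table
#'
#' Reads a CSV with one row per species: family, relative size at 50%
#' flowering (\code{s50}, may be empty), sex expression, leaf habit, fruit
#' type, 95th-percentile stem diameter and number of observed individuals.
#' A \code{genus} column is derived as the first token of the species name.
#'
#' @param path Path to a CSV file with header columns \code{species},
#'   \code{family}, \code{s50}, \code{sex_expression}, \code{leaf_habit},
#'   \code{fruit_type}, \code{dbh95_cm}, \code{n_obs}.
#' @return A validated data frame with the columns above plus \code{genus}.
#' @export
read_trait_table <- function(path) {
  d <- read_csv_checked(path, "trait table")
  need <- c("species", "family", "s50", "sex_expression", "leaf_habit",
            "fruit_type", "dbh95_cm", "n_obs")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d) == 0L) stop("trait table has no rows", call. = FALSE)
  d$species <- as.character(d$species)
  if (anyDuplicated(d$species))
    stop("duplicate species: ",
         paste(unique(d$species[duplicated(d$species)]), collapse = ", "),
         call. = FALSE)
  d$genus <- vapply(strsplit(d$species, "[ _]"), `[`, "", 1L)
  check_levels <- function(col, levels) {
    v <- as.character(d[[col]])
    bad <- !v %in% levels
    if (any(bad))
      stop("invalid ", col, " value(s): ",
           paste(unique(v[bad]), collapse = ", "),
           " (allowed: ", paste(levels, collapse = ", "), ")", call. = FALSE)
    v
  }
  d$sex_expression <- check_levels("sex_expression", .sex_levels)
  d$leaf_habit     <- check_levels("leaf_habit", .leaf_levels)
  d$fruit_type     <- check_levels("fruit_type", .fruit_levels)
  d$s50 <- suppressWarnings(as.numeric(d$s50))  # empty -> NA (not yet fitted)
  if (any(!is.na(d$s50) & d$s50 <= 0))
    stop("s50 must be positive where present", call. = FALSE)
  d$dbh95_cm <- as.numeric(d$dbh95_cm)
  if (any(!is.finite(d$dbh95_cm) | d$dbh95_cm <= 0))
    stop("dbh95_cm must be positive", call. = FALSE)
  d$n_obs <- as.integer(d$n_obs)
  if (any(is.na(d$n_obs) | d$n_obs < 1L))
    stop("n_obs must be a positive integer", call. = FALSE)
  d[, c("species", "family", "genus", "s50", "sex_expression", "leaf_habit",
        "fruit_type", "dbh95_cm", "n_obs")]
}

#' Write a species-trait table to CSV
#'
#' @param traits A data frame as returned by [read_trait_table()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  out <- traits[, setdiff(names(traits), "genus")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the bundled 30-species study table
#'
#' Species-level characteristics of 30 woody species (11 dioecious, 19
#' cosexual; 26 genera in 18 families) surveyed in a temperate evergreen
#' broad-leaved forest: relative size at 50% flowering (S0.5), sex
#' expression, leaf habit, fruit type, 95th-percentile stem diameter (cm)
#' and the number of individuals observed.
#'
#' @return A species-trait data frame of 30 rows (see [read_trait_table()]).
#' @export
#' @examples
#' tab <- load_study_table()
#' table(tab$sex_expression)
load_study_table <- function() {
  read_trait_table(system.file("extdata", "table1_species.csv",
                               package = "precocity", mustWork = TRUE))
}
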