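#' Morpho-species grouping for Bombus queens
#'
#' Queens of several *Bombus* species cannot be told apart reliably in the
#' field without a stereomicroscope, so captures are analysed at the level of
#' eight morpho-species groups. The default map pools *B. borealis* with
#' *B. fervidus*, *B. bimaculatus* with *B. griseocollis*, and *B. vagans*
#' with *B. perplexus* and *B. sandersoni*; the remaining five species are
#' field-identifiable and map to themselves. *B. griseocollis* is
#' morphologically compatible with both the *B. bimaculatus* and *B. vagans*
#' groups; the default assigns it to the *B. bimaculatus* group.
#'
#' @return Named character vector mapping full species names to one of the
#'   eight analysis group labels.
#' @export
#' @examples
#' map <- default_morphospecies_map()
#' map[["Bombus fervidus"]]
default_morphospecies_map <- function() {
  c(
    "Bombus borealis"     = "B. borealis group",
    "Bombus fervidus"     = "B. borealis group",
    "Bombus bimaculatus"  = "B. bimaculatus group",
    "Bombus griseocollis" = "B. bimaculatus group",
    "Bombus vagans"       = "B. vagans group",
    "Bombus perplexus"    = "B. vagans group",
    "Bombus sandersoni"   = "B. vagans group",
    "Bombus citrinus"     = "B. citrinus",
    "Bombus impatiens"    = "B. impatiens",
    "Bombus rufocinctus"  = "B. rufocinctus",
    "Bombus ternarius"    = "B. ternarius",
    "Bombus terricola"    = "B. terricola"
  )
}

#' Group labels of the default morpho-species map
#' @return Character vector of the eight analysis labels, in fixed order.
#' @export
morphospecies_groups <- function(map = default_morphospecies_map()) {
  unique(unname(map))
}

#' Map species names to morpho-species groups
#'
#' @param taxon Character vector of species names (e.g. `"Bombus impatiens"`;
#'   the abbreviated form `"B. impatiens"` is also accepted).
#' @param map Named character vector, species name -> group label.
#' @return Character vector of group labels.
#' @export
#' @examples
#' map_morphospecies("Bombus vagans")
map_morphospecies <- function(taxon, map = default_morphospecies_map()) {
  if (!is.character(taxon) || anyNA(taxon))
    stop_input("'taxon' must be a character vector without NA")
  full <- sub("^B\\. ", "Bombus ", taxon)
  hit <- match(full, names(map))
  if (anyNA(hit)) {
    bad <- unique(taxon[is.na(hit)])
    stop_input("unrecognized taxon: ", paste(shQuote(bad), collapse = ", "))
  }
  unname(map[hit])
}

#' Total survey effort per orchard
#'
#' Effort bookkeeping for the repeated-visit design: each season an orchard
#' receives a number of visits, each covered by several teams of several
#' observers searching for a fixed duration.
#'
#' @param visits,teams,observers_per_team Positive integers.
#' @param hours_per_observer Positive number of search hours per observer.
#' @return Total person-hours of sampling effort.
#' @export
#' @examples
#' compute_effort(3, 2, 2, 1)  # 12 h per orchard per season
compute_effort <- function(visits, teams, observers_per_team, hours_per_observer) {
  visits <- assert_count(visits, "visits")
  teams <- assert_count(teams, "teams")
  observers_per_team <- assert_count(observers_per_team, "observers_per_team")
  hours_per_observer <- assert_number(hours_per_observer, "hours_per_observer")
  if (hours_per_observer <= 0)
    stop_input("'hours_per_observer' must be positive")
  visits * teams * observers_per_team * hours_per_observer
}

## ---------------------------------------------------------------------------
## detection_dataset: the binary detection array plus covariates that the
## community occupancy model consumes. Sampling unit = orchard x season, with
## closure assumed within a season; a site index ties units from the same
## orchard for the site random effect.
## ---------------------------------------------------------------------------

#' Construct a detection dataset
#'
#' Low-level constructor used by [build_detection_history()], the synthetic
#' generator and the CSV reader. Validates shapes and standardizes the visit
#' covariates (z-scores over all observed visits), keeping the constants for
#' back-transformation.
#'
#' @param y Binary array, species x units x max visits; `NA` marks visits that
#'   did not take place (ragged designs).
#' @param species Character vector of species/group labels (rows of `y`).
#' @param units Data frame with one row per sampling unit and columns
#'   `site_id`, `season_id`, `season_fall` (0 spring / 1 fall), `enhancement`
#'   (0/1), `pesticide_high` (0/1).
#' @param air,time Numeric matrices, units x max visits, on their natural
#'   scales (degrees Celsius; hours after sunrise). `NA` where `y` is `NA`.
#' @param standardize Standardize `air`/`time`? Set `FALSE` when the matrices
#'   are already standardized (constants must then be supplied via `scaling`).
#' @param scaling Optional list with `air_mean`, `air_sd`, `time_mean`,
#'   `time_sd` when `standardize = FALSE`.
#' @param flags Character vector of data-quality flags (e.g. visits whose
#'   covariates were missing and imputed at the covariate mean).
#' @return Object of class `detection_dataset`.
#' @export
detection_dataset <- function(y, species, units, air, time,
                              standardize = TRUE, scaling = NULL,
                              flags = character()) {
  if (length(dim(y)) != 3L) stop_input("'y' must be a 3-d array (species x units x visits)")
  storage.mode(y) <- "double"
  n <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  if (length(species) != n) stop_input("length(species) must match nrow of 'y'")
  if (nrow(units) != J) stop_input("'units' must have one row per unit")
  need <- c("site_id", "season_id", "season_fall", "enhancement", "pesticide_high")
  miss <- setdiff(need, names(units))
  if (length(miss)) stop_input("'units' is missing columns: ", paste(miss, collapse = ", "))
  if (!all(dim(air) == c(J, K)) || !all(dim(time) == c(J, K)))
    stop_input("'air' and 'time' must be units x visits matrices matching 'y'")
  yv <- y[!is.na(y)]
  if (length(yv) == 0L && J > 0L) stop_input("'y' contains no observed visits")
  if (length(yv) && !all(yv %in% c(0, 1))) stop_input("'y' must be binary (0/1 or NA)")
  for (v in c("season_fall", "enhancement", "pesticide_high"))
    if (!all(units[[v]] %in% c(0, 1))) stop_input(sprintf("units$%s must be 0/1", v))

  obs <- !is.na(matrix(y[1, , ], J, K))  # visit-occurrence mask (shared across species)
  # every species row must share the same missingness pattern
  for (i in seq_len(n))
    if (!identical(is.na(matrix(y[i, , ], J, K)), !obs))
      stop_input("missing-visit pattern must be identical across species")
  if (J > 0L && any(rowSums(obs) < 1)) stop_input("every unit needs at least one visit")

  fl <- as.character(flags)
  if (J > 0L) {
    na_cov <- (is.na(air) | is.na(time)) & obs
    if (any(na_cov)) {
      idx <- which(na_cov, arr.ind = TRUE)
      fl <- c(fl, sprintf("missing covariate imputed at mean: unit %d visit %d",
                          idx[, 1], idx[, 2]))
    }
  }
  if (standardize) {
    sc <- list(air_mean = mean(air[obs], na.rm = TRUE), air_sd = stats::sd(air[obs], na.rm = TRUE),
               time_mean = mean(time[obs], na.rm = TRUE), time_sd = stats::sd(time[obs], na.rm = TRUE))
    if (!is.finite(sc$air_sd) || sc$air_sd == 0) sc$air_sd <- 1
    if (!is.finite(sc$time_sd) || sc$time_sd == 0) sc$time_sd <- 1
    if (!is.finite(sc$air_mean)) sc$air_mean <- 0
    if (!is.finite(sc$time_mean)) sc$time_mean <- 0
    air_s <- (air - sc$air_mean) / sc$air_sd
    time_s <- (time - sc$time_mean) / sc$time_sd
  } else {
    sc <- scaling %||% list(air_mean = 0, air_sd = 1, time_mean = 0, time_sd = 1)
    air_s <- air; time_s <- time
  }
  air_s[obs & is.na(air_s)] <- 0   # imputed at the covariate mean
  time_s[obs & is.na(time_s)] <- 0
  air_s[!obs] <- NA; time_s[!obs] <- NA

  units$site_index <- as.integer(factor(units$site_id, levels = unique(units$site_id)))
  structure(list(
    y = y, species = as.character(species), units = units,
    air = air_s, time = time_s, obs = obs,
    scaling = sc, flags = fl
  ), class = "detection_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.detection_dataset <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf("<detection_dataset> %d species x %d units (%d sites x %d seasons) x up to %d visits\n",
              d[1], d[2], length(unique(x$units$site_id)),
              length(unique(x$units$season_id)), d[3]))
  cat(sprintf("  naive detection rate: %.3f; flags: %d\n",
              mean(x$y[!is.na(x$y)]), length(x$flags)))
  invisible(x)
}

#' Build detection histories from capture records
#'
#' Collapses capture counts to binary detection, groups species into
#' morpho-species, and assembles the species x unit x visit detection array
#' together with the visit and unit covariates. Units are orchard x season
#' combinations. Duplicate records of the same (group, unit, visit) are
#' merged; any positive count yields a detection.
#'
#' @param records Data frame of capture records with columns `site_id`,
#'   `season_id`, `visit`, `taxon`, `count`, matching the design declared by
#'   `visits`. Rows with `count = 0` are allowed and ignored.
#' @param visits Data frame declaring every visit that took place: `site_id`,
#'   `season_id`, `visit`, `air_temp` (deg C) and either `time_of_day` (hours
#'   after sunrise) or both `clock_time` and `sunrise` (decimal hours, from
#'   which time after sunrise is computed).
#' @param site_covariates Data frame with `site_id`, `enhancement` (0/1) and
#'   either `pesticide_high` (0/1) or `pesticide_index` (classified at
#'   `threshold`).
#' @param map Morpho-species map, see [default_morphospecies_map()].
#' @param species Optional fixed vector of group labels defining the row order
#'   of `y` (defaults to all groups of `map`).
#' @param fall_pattern Regular expression identifying fall seasons in
#'   `season_id`.
#' @param threshold Pesticide-intensity split used when `site_covariates`
#'   carries a raw `pesticide_index`.
#' @return A [detection_dataset()].
#' @export
build_detection_history <- function(records, visits, site_covariates,
                                    map = default_morphospecies_map(),
                                    species = morphospecies_groups(map),
                                    fall_pattern = "fall",
                                    threshold = 48.5) {
  for (col in c("site_id", "season_id", "visit", "taxon", "count"))
    if (is.null(records[[col]])) stop_input("records lack column '", col, "'")
  if (any(records$count < 0)) stop_input("capture counts must be non-negative")
  if (is.null(visits$time_of_day)) {
    if (is.null(visits$clock_time) || is.null(visits$sunrise))
      stop_input("visits need 'time_of_day' or both 'clock_time' and 'sunrise'")
    visits$time_of_day <- visits$clock_time - visits$sunrise
  }

  unit_key <- function(s, ss) paste(s, ss, sep = "\r")
  vkeys <- unique(unit_key(visits$site_id, visits$season_id))
  J <- length(vkeys)
  uidx <- match(unit_key(visits$site_id, visits$season_id), vkeys)
  K <- max(visits$visit)
  if (any(visits$visit < 1 | visits$visit != round(visits$visit)))
    stop_input("visit indices must be positive integers")

  n <- length(species)
  y <- array(NA_real_, c(n, J, K))
  air <- matrix(NA_real_, J, K); tod <- matrix(NA_real_, J, K)
  for (r in seq_len(nrow(visits))) {
    j <- uidx[r]; k <- visits$visit[r]
    y[, j, k] <- 0
    air[j, k] <- visits$air_temp[r]
    tod[j, k] <- visits$time_of_day[r]
  }

  if (nrow(records)) {
    grp <- map_morphospecies(records$taxon, map)
    gi <- match(grp, species)
    if (anyNA(gi)) stop_input("record taxon maps outside the declared species set")
    ju <- match(unit_key(records$site_id, records$season_id), vkeys)
    if (anyNA(ju)) stop_input("records reference undeclared site/season combinations")
    for (r in seq_len(nrow(records))) {
      k <- records$visit[r]
      if (k < 1 || k > K || is.na(y[gi[r], ju[r], k]))
        stop_input("record references an undeclared visit (site ",
                   records$site_id[r], ", ", records$season_id[r], ", visit ", k, ")")
      if (records$count[r] >= 1) y[gi[r], ju[r], k] <- 1
    }
  }

  first <- match(vkeys, unit_key(visits$site_id, visits$season_id))
  units <- data.frame(
    site_id = visits$site_id[first],
    season_id = visits$season_id[first],
    stringsAsFactors = FALSE
  )
  units$season_fall <- as.integer(grepl(fall_pattern, units$season_id, ignore.case = TRUE))
  sc <- site_covariates
  m <- match(units$site_id, sc$site_id)
  if (anyNA(m)) stop_input("site covariates missing for some sites")
  units$enhancement <- as.integer(sc$enhancement[m])
  if (!is.null(sc$pesticide_high)) {
    units$pesticide_high <- as.integer(sc$pesticide_high[m])
  } else if (!is.null(sc$pesticide_index)) {
    units$pesticide_high <- as.integer(classify_intensity(sc$pesticide_index[m],
                                                          threshold = threshold) == "high")
  } else stop_input("site covariates need 'pesticide_high' or 'pesticide_index'")

  detection_dataset(y, species, units, air, tod)
}

#' Write / read a detection dataset as CSV plus a JSON sidecar
#'
#' The long CSV holds one row per (species, unit, visit) cell with the binary
#' outcome; the sidecar carries unit covariates, standardized visit
#' covariates, standardization constants and flags, so that a round trip
#' reproduces the dataset exactly.
#'
#' @param data A [detection_dataset()].
#' @param csv,sidecar File paths.
#' @return `write_detection_data()` returns the paths invisibly;
#'   `read_detection_data()` returns a [detection_dataset()].
#' @export
write_detection_data <- function(data, csv, sidecar) {
  d <- dim(data$y)
  idx <- which(!is.na(data$y), arr.ind = TRUE)
  long <- data.frame(species = data$species[idx[, 1]],
                     unit = idx[, 2], visit = idx[, 3],
                     y = data$y[idx])
  long <- long[order(long$unit, long$visit, match(long$species, data$species)), ]
  utils::write.csv(long, csv, row.names = FALSE)
  side <- list(
    species = data$species,
    units = data$units,
    air = apply(data$air, 1, function(r) r, simplify = FALSE),
    time = apply(data$time, 1, function(r) r, simplify = FALSE),
    max_visits = d[3],
    scaling = data$scaling,
    flags = data$flags
  )
  # digits = I(17): full double precision, so a round trip is bit-exact
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(c(csv = csv, sidecar = sidecar))
}

#' @rdname write_detection_data
#' @export
read_detection_data <- function(csv, sidecar) {
  long <- utils::read.csv(csv, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  species <- side$species
  units <- as.data.frame(side$units, stringsAsFactors = FALSE)
  J <- nrow(units); K <- side$max_visits; n <- length(species)
  y <- array(NA_real_, c(n, J, K))
  i <- match(long$species, species)
  y[cbind(i, long$unit, long$visit)] <- long$y
  tomat <- function(lst) {
    if (is.matrix(lst)) return(matrix(as.numeric(lst), nrow(lst), ncol(lst)))
    m <- do.call(rbind, lapply(lst, function(r) {
      r <- unlist(r); length(r) <- K; as.numeric(r)
    }))
    if (is.null(m)) matrix(NA_real_, 0, K) else m
  }
  detection_dataset(y, species, units, tomat(side$air), tomat(side$time),
                    standardize = FALSE, scaling = side$scaling,
                    flags = side$flags %||% character())
}
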