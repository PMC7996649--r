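#' @keywords internal
"_PACKAGE"

#' @useDynLib referralnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats glm.fit binomial plogis qlogis quantile rnbinom runif
#'   sd var setNames optim cov
#' @importFrom utils read.csv write.csv head modifyList
NULL

## Closed vocabularies used throughout.
TIERS <- c("dispensary", "health_centre", "hospital")
OWNERSHIPS <- c("public", "faith_based", "private")
DOMAINS <- c("childcare", "ncd")

FACILITY_COLUMNS <- c(
  "facility_id", "name", "district", "tier", "ownership", "surveyed",
  "lon", "lat", "delivery_beds", "patient_beds", "rooms", "motorcycles",
  "ambulances", "catchment_population", "facility_deliveries_3m",
  "outpatient_visits_3m", "rch_visits_3m"
)
REFERRAL_COLUMNS <- c(
  "sender_id", "receiver_id", "condition_category", "domain", "n_referrals"
)

## Count covariates that must be present (>= 0) for every facility, surveyed
## or not: they enter the ERGMs.
COUNT_COVARIATES <- c(
  "delivery_beds", "patient_beds", "rooms", "motorcycles", "ambulances",
  "facility_deliveries_3m"
)

data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("referralnet_data_error", "error")))
}

usage_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("referralnet_usage_error", "error")))
}

parse_boolean <- function(x, what) {
  out <- rep(NA, length(x))
  low <- tolower(trimws(as.character(x)))
  out[low %in% c("1", "true")] <- TRUE
  out[low %in% c("0", "false")] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    data_error("%s: cannot parse '%s' as boolean (row %d); expected 0/1/true/false",
               what, x[bad], bad)
  }
  out
}

#' Read and validate a facility roster table
#'
#' Reads the `facilities.csv` dialect: comma-separated, UTF-8, mandatory
#' header with columns `facility_id, name, district, tier, ownership,
#' surveyed, lon, lat, delivery_beds, patient_beds, rooms, motorcycles,
#' ambulances, catchment_population, facility_deliveries_3m,
#' outpatient_visits_3m, rch_visits_3m`.  Tier and ownership come from the
#' closed vocabularies `dispensary/health_centre/hospital` and
#' `public/faith_based/private`.  Visit volumes may be blank for facilities
#' that were not surveyed (referral destinations outside the study), but the
#' count covariates used in the models must be present for every row.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` (one row per facility, input order preserved) with
#'   typed columns.
#' @export
read_facility_table <- function(path) {
  if (!file.exists(path)) data_error("facility table not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(FACILITY_COLUMNS, names(raw))
  if (length(missing) > 0) {
    data_error("facility table %s is missing columns: %s", path,
               paste(missing, collapse = ", "))
  }
  raw <- raw[FACILITY_COLUMNS]
  if (nrow(raw) == 0) {
    return(empty_roster())
  }
  validate_roster(type_roster(raw), where = path)
}

type_roster <- function(raw) {
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  int_or_na <- function(col) {
    x <- trimws(raw[[col]])
    out <- suppressWarnings(as.integer(x))
    out[x == ""] <- NA_integer_
    out
  }
  data.frame(
    facility_id = trimws(raw$facility_id),
    name = raw$name,
    district = trimws(raw$district),
    tier = trimws(raw$tier),
    ownership = trimws(raw$ownership),
    surveyed = parse_boolean(raw$surveyed, "surveyed"),
    lon = num("lon"),
    lat = num("lat"),
    delivery_beds = int_or_na("delivery_beds"),
    patient_beds = int_or_na("patient_beds"),
    rooms = int_or_na("rooms"),
    motorcycles = int_or_na("motorcycles"),
    ambulances = int_or_na("ambulances"),
    catchment_population = int_or_na("catchment_population"),
    facility_deliveries_3m = int_or_na("facility_deliveries_3m"),
    outpatient_visits_3m = int_or_na("outpatient_visits_3m"),
    rch_visits_3m = int_or_na("rch_visits_3m"),
    stringsAsFactors = FALSE
  )
}

empty_roster <- function() {
  r <- type_roster(as.data.frame(
    setNames(rep(list(character(0)), length(FACILITY_COLUMNS)),
             FACILITY_COLUMNS),
    stringsAsFactors = FALSE))
  r
}

#' Validate a facility roster
#'
#' Enforces the roster invariants: unique non-empty `facility_id`, tier and
#' ownership drawn from the closed vocabularies, non-negative count
#' covariates present for every facility, `catchment_population >= 1`.
#'
#' @param roster a roster `data.frame` as returned by [read_facility_table()].
#' @param where label used in error messages.
#' @return the roster, invisibly usable (returned unchanged).
#' @export
validate_roster <- function(roster, where = "roster") {
  id <- roster$facility_id
  if (any(id == "" | is.na(id))) {
    data_error("%s: empty facility_id in row(s) %s", where,
               paste(which(id == "" | is.na(id)), collapse = ", "))
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    data_error("%s: duplicated facility_id: %s", where,
               paste(dup, collapse = ", "))
  }
  bad_tier <- setdiff(unique(roster$tier), TIERS)
  if (length(bad_tier) > 0) {
    data_error("%s: unknown tier token(s): %s (allowed: %s)", where,
               paste(bad_tier, collapse = ", "), paste(TIERS, collapse = ", "))
  }
  bad_own <- setdiff(unique(roster$ownership), OWNERSHIPS)
  if (length(bad_own) > 0) {
    data_error("%s: unknown ownership token(s): %s (allowed: %s)", where,
               paste(bad_own, collapse = ", "),
               paste(OWNERSHIPS, collapse = ", "))
  }
  for (col in COUNT_COVARIATES) {
    x <- roster[[col]]
    if (anyNA(x)) {
      data_error("%s: missing %s for facility %s", where, col,
                 paste(id[is.na(x)], collapse = ", "))
    }
    if (any(x < 0)) {
      data_error("%s: negative %s for facility %s", where, col,
                 paste(id[x < 0], collapse = ", "))
    }
  }
  pop <- roster$catchment_population
  if (anyNA(pop) || any(pop < 1)) {
    bad <- is.na(pop) | pop < 1
    data_error("%s: catchment_population must be >= 1 (facility %s)", where,
               paste(id[bad], collapse = ", "))
  }
  opt <- c("outpatient_visits_3m", "rch_visits_3m")
  for (col in opt) {
    x <- roster[[col]]
    if (any(!is.na(x) & x < 0)) {
      data_error("%s: negative %s for facility %s", where, col,
                 paste(id[!is.na(x) & x < 0], collapse = ", "))
    }
  }
  roster
}

#' Read and validate referral records
#'
#' Reads the `referrals.csv` dialect with header `sender_id, receiver_id,
#' condition_category, domain, n_referrals`.  `domain` must be `childcare`
#' or `ncd`; a blank `n_referrals` defaults to 1; self-referrals are
#' rejected.  When a roster is supplied, every sender and receiver must
#' resolve against it.
#'
#' @param path path to a CSV file.
#' @param roster optional roster to resolve facility keys against.
#' @return a `data.frame` of validated referral records, input order
#'   preserved.
#' @export
read_referral_records <- function(path, roster = NULL) {
  if (!file.exists(path)) data_error("referral table not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(REFERRAL_COLUMNS, names(raw))
  if (length(missing) > 0) {
    data_error("referral table %s is missing columns: %s", path,
               paste(missing, collapse = ", "))
  }
  n_ref <- trimws(raw$n_referrals)
  n_int <- suppressWarnings(as.integer(n_ref))
  n_int[n_ref == ""] <- 1L
  rec <- data.frame(
    sender_id = trimws(raw$sender_id),
    receiver_id = trimws(raw$receiver_id),
    condition_category = trimws(raw$condition_category),
    domain = trimws(raw$domain),
    n_referrals = n_int,
    stringsAsFactors = FALSE
  )
  validate_records(rec, roster = roster, where = path)
}

#' Validate referral records
#'
#' @param records a records `data.frame`.
#' @param roster optional roster for key resolution.
#' @param where label for error messages.
#' @return the validated records.
#' @export
validate_records <- function(records, roster = NULL, where = "records") {
  if (nrow(records) == 0) return(records)
  loops <- records$sender_id == records$receiver_id
  if (any(loops)) {
    data_error("%s: self-referral (sender == receiver == %s) in row(s) %s",
               where, paste(unique(records$sender_id[loops]), collapse = ", "),
               paste(which(loops), collapse = ", "))
  }
  bad_dom <- setdiff(unique(records$domain), DOMAINS)
  if (length(bad_dom) > 0) {
    data_error("%s: unknown domain token(s): %s (allowed: %s)", where,
               paste(bad_dom, collapse = ", "),
               paste(DOMAINS, collapse = ", "))
  }
  if (anyNA(records$n_referrals) || any(records$n_referrals < 1)) {
    bad <- is.na(records$n_referrals) | records$n_referrals < 1
    data_error("%s: n_referrals must be a positive integer (row %s)", where,
               paste(which(bad), collapse = ", "))
  }
  if (!is.null(roster)) {
    keys <- unique(c(records$sender_id, records$receiver_id))
    unresolved <- setdiff(keys, roster$facility_id)
    if (length(unresolved) > 0) {
      data_error("%s: facility key(s) not in roster: %s", where,
                 paste(unresolved, collapse = ", "))
    }
  }
  records
}

#' Read a pairwise road-distance matrix
#'
#' Reads the `distances.csv` dialect: first column `facility_id`, remaining
#' columns keyed by facility_id, entries in kilometres.  The matrix must
#' cover every roster facility, have a zero diagonal, non-negative entries,
#' and be symmetric within an absolute tolerance of 1e-6 km; it is then
#' symmetrized by averaging and reordered to roster order.
#'
#' @param path path to a CSV file.
#' @param roster the facility roster defining the node order.
#' @param tol symmetry tolerance in km.
#' @return a symmetric numeric matrix with dimnames equal to
#'   `roster$facility_id`.
#' @export
read_distance_matrix <- function(path, roster, tol = 1e-6) {
  if (!file.exists(path)) data_error("distance matrix not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
  if (names(raw)[1] != "facility_id") {
    data_error("distance matrix %s: first column must be 'facility_id'", path)
  }
  ids <- trimws(as.character(raw[[1]]))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  colnames(mat) <- trimws(colnames(mat))
  if (!identical(sort(rownames(mat)), sort(colnames(mat)))) {
    data_error("distance matrix %s: row and column keys differ", path)
  }
  mat <- mat[, rownames(mat), drop = FALSE]
  missing <- setdiff(roster$facility_id, ids)
  if (length(missing) > 0) {
    data_error("distance matrix %s: missing facility id(s): %s", path,
               paste(missing, collapse = ", "))
  }
  validate_distance_matrix(mat, roster, tol = tol, where = path)
}

#' Validate and symmetrize a distance matrix
#'
#' @param mat square numeric matrix with facility ids as dimnames.
#' @param roster roster giving the target node order.
#' @param tol symmetry tolerance in km.
#' @param where label for error messages.
#' @return the symmetrized matrix in roster order.
#' @export
validate_distance_matrix <- function(mat, roster, tol = 1e-6,
                                     where = "distances") {
  mat <- mat[roster$facility_id, roster$facility_id, drop = FALSE]
  if (anyNA(mat)) data_error("%s: missing distance entries", where)
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    data_error("%s: negative distance for pair (%s, %s)", where,
               rownames(mat)[bad[1]], colnames(mat)[bad[2]])
  }
  if (any(abs(diag(mat)) > tol)) {
    data_error("%s: nonzero diagonal for facility %s", where,
               paste(rownames(mat)[abs(diag(mat)) > tol], collapse = ", "))
  }
  asym <- abs(mat - t(mat))
  if (any(asym > tol)) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    data_error("%s: asymmetric by %.6g km for pair (%s, %s)", where,
               max(asym), rownames(mat)[bad[1]], colnames(mat)[bad[2]])
  }
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  mat
}

#' Write a facility roster, referral records or distance matrix as CSV
#'
#' Writers for the same CSV dialects the readers accept, so that generated
#' data round-trips through the package's own I/O.
#'
#' @param roster,records a roster / records `data.frame`.
#' @param mat a distance matrix with facility-id dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_facility_table <- function(roster, path) {
  out <- roster
  out$surveyed <- as.integer(out$surveyed)
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' @rdname write_facility_table
#' @export
write_referral_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_facility_table
#' @export
write_distance_matrix <- function(mat, path) {
  out <- data.frame(facility_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
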