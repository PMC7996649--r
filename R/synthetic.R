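## Covariate generation parameters: per tier, a mean count and the marginal
## [min, max] range the draw is truncated to.  Shapes follow the two-district
## facility profile: dispensaries are small (a few rooms, no vehicles),
## health centres intermediate, hospitals large with busy maternity wards.
default_covariate_params <- function() {
  list(
    rooms = list(mu = c(3.5, 10, 25), range = c(1, 36), size = 2),
    patient_beds = list(mu = c(2, 25, 180), range = c(0, 366), size = 1.5),
    delivery_beds = list(mu = c(1, 4, 10), range = c(0, 17), size = 2),
    motorcycles = list(mu = c(0.2, 0.5, 1), range = c(0, 2), size = 1),
    ambulances = list(mu = c(0.1, 0.6, 1.5), range = c(0, 5), size = 1),
    facility_deliveries_3m = list(mu = c(10, 90, 600), range = c(1, 1892),
                                  size = 1.2),
    catchment_population = list(log_range = rbind(c(1200, 2e4),
                                                  c(5e3, 1e5),
                                                  c(1e5, 1.535e6)))
  )
}

#' Configuration for a synthetic district referral system
#'
#' Describes the facility mix, spatial layout and covariate distributions of
#' one simulated district.  `kilolo_config()` and `msalala_config()` preset
#' the tier mixes of the two study-like districts (46 = 40/3/3 and
#' 31 = 25/4/2 facilities); `recovery_config()` is the parameter-recovery
#' scenario: 40 facilities (34/3/3) in a compact area sized so that the
#' ground-truth coefficients produce sparse networks (density around 0.02).
#'
#' @param district district label.
#' @param n_dispensary,n_health_centre,n_hospital tier counts (at least one
#'   facility overall, and at least one health centre or hospital so the
#'   network has a receiver-capable facility).
#' @param n_surveyed number of facilities flagged as surveyed, filled in
#'   roster order (the remainder emulate unsurveyed referral destinations).
#' @param extent_km side of the square area facilities are scattered over.
#' @param road_factor multiplier (>= 1) applied to straight-line distances
#'   to emulate road distances.
#' @param hospital_placement `"central"` (hospital near the district centre,
#'   town-like) or `"peripheral"` (distant hospital at the district edge).
#' @param covariates covariate distribution parameters; see
#'   `default_covariate_params()`.
#' @param origin lon/lat of the area's south-west corner, decimal degrees.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(district = "district_a", n_dispensary = 40,
                       n_health_centre = 3, n_hospital = 3,
                       n_surveyed = NULL, extent_km = 40, road_factor = 1.3,
                       hospital_placement = c("central", "peripheral"),
                       covariates = default_covariate_params(),
                       origin = c(35.0, -8.0)) {
  hospital_placement <- match.arg(hospital_placement)
  n <- n_dispensary + n_health_centre + n_hospital
  if (n < 1) usage_error("configuration has zero facilities")
  if (n_health_centre + n_hospital < 1) {
    usage_error("need at least one receiver-capable facility (health centre or hospital)")
  }
  if (road_factor < 1) usage_error("road_factor must be >= 1")
  structure(list(
    district = district, n_dispensary = n_dispensary,
    n_health_centre = n_health_centre, n_hospital = n_hospital,
    n_surveyed = n_surveyed %||% n, extent_km = extent_km,
    road_factor = road_factor, hospital_placement = hospital_placement,
    covariates = covariates, origin = origin
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
kilolo_config <- function() {
  sim_config(district = "kilolo", n_dispensary = 40, n_health_centre = 3,
             n_hospital = 3, n_surveyed = 42, extent_km = 60,
             hospital_placement = "central")
}

#' @rdname sim_config
#' @export
msalala_config <- function() {
  cov <- default_covariate_params()
  cov$rooms$range <- c(1, 26)
  cov$patient_beds$range <- c(0, 300)
  cov$delivery_beds$range <- c(0, 8)
  cov$ambulances$range <- c(0, 3)
  sim_config(district = "msalala", n_dispensary = 25, n_health_centre = 4,
             n_hospital = 2, n_surveyed = 27, extent_km = 50,
             hospital_placement = "peripheral",
             covariates = cov, origin = c(32.5, -3.6))
}

#' @rdname sim_config
#' @export
recovery_config <- function() {
  sim_config(district = "synthetic", n_dispensary = 34, n_health_centre = 3,
             n_hospital = 3, extent_km = 2, hospital_placement = "central")
}

KM_PER_DEGREE <- 111.32

draw_count <- function(n, mu, range, size) {
  lo <- range[1]; hi <- range[2]
  x <- lo + rnbinom(n, mu = max(mu - lo, 0.01), size = size)
  pmin(x, hi)
}

#' Generate a synthetic facility roster
#'
#' Draws a deterministic (seeded) roster with the configured tier mix.
#' Count covariates are truncated negative-binomial draws within the
#' configured marginal ranges, with tier-specific means; catchment
#' population is log-uniform within a tier-specific range.  Dispensaries
#' and health centres are scattered uniformly over the square area;
#' hospitals sit near the centre (`"central"`) or at the area's edge
#' (`"peripheral"`).
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory: generation is a pure function of
#'   config and seed).
#' @return a validated roster `data.frame`.
#' @export
generate_roster <- function(config, seed) {
  if (missing(seed) || is.null(seed)) usage_error("seed is mandatory")
  set.seed(seed)
  nd <- config$n_dispensary; nh <- config$n_health_centre
  nH <- config$n_hospital
  n <- nd + nh + nH
  if (n < 1) usage_error("configuration has zero facilities")
  tier <- rep(TIERS, c(nd, nh, nH))
  tier_idx <- match(tier, TIERS)
  ext_deg <- config$extent_km / KM_PER_DEGREE
  lon <- config$origin[1] + runif(n) * ext_deg
  lat <- config$origin[2] + runif(n) * ext_deg
  hosp <- which(tier == "hospital")
  if (length(hosp) > 0) {
    if (config$hospital_placement == "central") {
      lon[hosp] <- config$origin[1] + ext_deg * (0.5 + runif(length(hosp), -0.1, 0.1))
      lat[hosp] <- config$origin[2] + ext_deg * (0.5 + runif(length(hosp), -0.1, 0.1))
    } else {
      lon[hosp] <- config$origin[1] + ext_deg * (0.95 + runif(length(hosp), -0.04, 0.04))
      lat[hosp] <- config$origin[2] + ext_deg * runif(length(hosp))
    }
  }
  cv <- config$covariates
  draw_by_tier <- function(par) {
    draw_count(n, par$mu[tier_idx], par$range, par$size)
  }
  pop_range <- cv$catchment_population$log_range[tier_idx, , drop = FALSE]
  pop <- round(exp(runif(n, log(pop_range[, 1]), log(pop_range[, 2]))))
  surveyed <- seq_len(n) <= config$n_surveyed |
    rep(FALSE, n)  # surveyed flag fills roster order
  ## surveyed facilities carry visit volumes; external destinations omit them
  opd <- ifelse(surveyed, 300 + draw_count(n, 900, c(0, 20000), 1.2), NA)
  rch <- ifelse(surveyed, 100 + draw_count(n, 350, c(0, 8000), 1.2), NA)
  roster <- data.frame(
    facility_id = sprintf("%s_%03d", toupper(substr(config$district, 1, 3)),
                          seq_len(n)),
    name = sprintf("%s facility %d", config$district, seq_len(n)),
    district = config$district,
    tier = tier,
    ownership = "public",
    surveyed = surveyed,
    lon = lon, lat = lat,
    delivery_beds = as.integer(draw_by_tier(cv$delivery_beds)),
    patient_beds = as.integer(draw_by_tier(cv$patient_beds)),
    rooms = as.integer(draw_by_tier(cv$rooms)),
    motorcycles = as.integer(draw_by_tier(cv$motorcycles)),
    ambulances = as.integer(draw_by_tier(cv$ambulances)),
    catchment_population = as.integer(pop),
    facility_deliveries_3m = as.integer(draw_by_tier(cv$facility_deliveries_3m)),
    outpatient_visits_3m = as.integer(opd),
    rch_visits_3m = as.integer(rch),
    stringsAsFactors = FALSE
  )
  validate_roster(roster, where = "generated roster")
}

#' Generate a road-distance matrix from facility coordinates
#'
#' Straight-line (equirectangular) distance in km between facility
#' coordinates, multiplied by the configured road factor.  Symmetric with a
#' zero diagonal by construction.
#'
#' @param roster a roster with `lon`/`lat`.
#' @param config a [sim_config()] supplying `road_factor`.
#' @return a symmetric distance matrix in km, facility ids as dimnames.
#' @export
generate_distances <- function(roster, config) {
  lat0 <- cos(mean(roster$lat) * pi / 180)
  dx <- outer(roster$lon, roster$lon, "-") * KM_PER_DEGREE * lat0
  dy <- outer(roster$lat, roster$lat, "-") * KM_PER_DEGREE
  d <- sqrt(dx^2 + dy^2) * config$road_factor
  dimnames(d) <- list(roster$facility_id, roster$facility_id)
  d
}

#' Draw one referral network from a ground-truth ERGM
#'
#' Runs the tie/no-tie sampler at the ground-truth coefficients after a long
#' burn-in and returns a single network.  Ten spaced draws are inspected:
#' if more than 90 percent are empty or complete the ground truth is
#' declared degenerate and an error advises re-tuning.
#'
#' @param roster facility roster (node set and covariates).
#' @param distances dyadic distance matrix in km.
#' @param theta ground-truth coefficient vector (finite).
#' @param terms `ergm_terms` specification matching `theta`.
#' @param domain care domain label for the generated network.
#' @param burnin sampler burn-in (proposals).
#' @param interval spacing between the inspected draws.
#' @param seed integer seed (mandatory).
#' @return a `referral_network` (the last inspected draw).
#' @export
generate_network <- function(roster, distances, theta, terms,
                             domain = "childcare", burnin = 1e5,
                             interval = 2e3, seed) {
  if (missing(seed) || is.null(seed)) usage_error("seed is mandatory")
  if (any(!is.finite(theta))) usage_error("ground-truth theta must be finite")
  n <- nrow(roster)
  shell <- referral_network(matrix(0L, n, n), roster,
                           district = roster$district[1], domain = domain)
  draws <- simulate_networks(shell, terms, theta,
                             dyadcov = list(distance = distances),
                             nsamples = 10, burnin = burnin,
                             interval = interval, seed = seed,
                             init = "empty")
  edges <- vapply(draws, network_edge_count, numeric(1))
  degen <- mean(edges == 0 | edges == n * (n - 1))
  if (degen > 0.9) {
    degeneracy_error(paste0(
      "ground-truth coefficients are degenerate: more than 90% of draws are ",
      "empty or complete; re-tune theta"),
      payload = list(theta = theta, edges = edges))
  }
  draws[[length(draws)]]
}

## ------------------------------------------------------------------------
## Deterministic study-like fixtures reproducing the printed tier-to-tier
## referral breakdowns.

table4_flows <- function(district, domain) {
  key <- paste(district, domain, sep = ".")
  flows <- list(
    kilolo.childcare = list(
      c("dispensary", "health_centre", 5),
      c("dispensary", "hospital", 22),
      c("health_centre", "dispensary", 1),
      c("health_centre", "hospital", 2),
      c("hospital", "hospital", 3)
    ),
    kilolo.ncd = list(
      c("dispensary", "health_centre", 2),
      c("dispensary", "hospital", 25),
      c("health_centre", "hospital", 1),
      c("hospital", "hospital", 5)
    ),
    msalala.childcare = list(
      c("dispensary", "dispensary", 3),
      c("dispensary", "health_centre", 10),
      c("dispensary", "hospital", 16),
      c("health_centre", "health_centre", 1),
      c("health_centre", "hospital", 2)
    ),
    msalala.ncd = list(
      c("dispensary", "dispensary", 2),
      c("dispensary", "health_centre", 6),
      c("dispensary", "hospital", 8),
      c("health_centre", "hospital", 3)
    )
  )
  flows[[key]]
}

fixture_roster <- function(district) {
  if (district == "kilolo") {
    n <- 46; nd <- 40; nh <- 3; nH <- 3
    ids <- sprintf("KIL_%03d", seq_len(n))
    surveyed <- c(rep(TRUE, 40), TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
    ownership <- rep("public", n)
    ownership[c(42, 43, 45)] <- "faith_based"   # 3 faith-based facilities
    distr <- rep("kilolo", n)
    distr[46] <- "iringa_urban"                 # regional referral hospital
    origin <- c(35.0, -8.0); extent <- 60
  } else if (district == "msalala") {
    n <- 31; nd <- 25; nh <- 4; nH <- 2
    ids <- sprintf("MSA_%03d", seq_len(n))
    surveyed <- c(rep(TRUE, 24), FALSE, rep(TRUE, 3), FALSE, FALSE, FALSE)
    ownership <- rep("public", n)
    ownership[25] <- "private"                  # 1 private receiver
    ownership[29] <- "faith_based"              # 1 faith-based receiver
    distr <- rep("msalala", n)
    distr[30] <- "kahama_urban"                 # district hospital next door
    distr[31] <- "shinyanga_urban"
    origin <- c(32.5, -3.6); extent <- 50
  } else {
    usage_error("unknown fixture district '%s'", district)
  }
  tier <- rep(TIERS, c(nd, nh, nH))
  i <- seq_len(n)
  ext_deg <- extent / KM_PER_DEGREE
  ## deterministic low-discrepancy layout on the square
  lon <- origin[1] + ((i * 0.6180339887) %% 1) * ext_deg
  lat <- origin[2] + ((i * 0.7548776662) %% 1) * ext_deg
  tier_idx <- match(tier, TIERS)
  roster <- data.frame(
    facility_id = ids,
    name = sprintf("%s facility %d", district, i),
    district = distr,
    tier = tier,
    ownership = ownership,
    surveyed = surveyed,
    lon = lon, lat = lat,
    delivery_beds = c(1L, 4L, 10L)[tier_idx],
    patient_beds = c(2L, 24L, 180L)[tier_idx] + (i %% 3L),
    rooms = c(3L, 12L, 26L)[tier_idx] + (i %% 4L),
    motorcycles = ifelse(tier == "dispensary", i %% 2L, 1L),
    ambulances = c(0L, 1L, 2L)[tier_idx],
    catchment_population = c(3300L, 25000L, 400000L)[tier_idx] + 37L * i,
    facility_deliveries_3m = c(9L, 90L, 700L)[tier_idx] + (i %% 7L),
    outpatient_visits_3m = ifelse(surveyed, 900L + 25L * i, NA_integer_),
    rch_visits_3m = ifelse(surveyed, 300L + 10L * i, NA_integer_),
    stringsAsFactors = FALSE
  )
  validate_roster(roster, where = sprintf("%s fixture roster", district))
}

#' Deterministic two-district fixtures from the printed flow tables
#'
#' Builds a roster with the published tier mix (Kilolo 46 = 40/3/3,
#' Msalala 31 = 25/4/2) and a referral record set that reproduces the
#' printed tier-to-tier referral breakdown exactly.  The published tables
#' constrain only the tier-pair counts, not which facilities connect, so
#' edges are assigned to distinct dyads by round-robin over the facilities
#' of each tier in roster order.  Everything is deterministic: no RNG.
#'
#' @param district `"kilolo"` or `"msalala"`.
#' @param domain `"childcare"` or `"ncd"`.
#' @return a list with `roster`, `records` and a `distances` matrix
#'   (straight-line km x 1.3).
#' @export
fixture_from_table4 <- function(district = c("kilolo", "msalala"),
                                domain = c("childcare", "ncd")) {
  district <- match.arg(district)
  domain <- match.arg(domain)
  roster <- fixture_roster(district)
  flows <- table4_flows(district, domain)
  categories <- if (domain == "childcare") {
    c("fever_malaria", "cough_pneumonia", "diarrhoea")
  } else {
    c("hypertension", "diabetes", "chronic_respiratory")
  }
  members <- split(roster$facility_id, roster$tier)
  rec <- list()
  for (fl in flows) {
    from <- fl[1]; to <- fl[2]; count <- as.integer(fl[3])
    a <- members[[from]]; b <- members[[to]]
    if (from == to) {
      pairs <- expand.grid(s = seq_along(a), r = seq_along(b))
      pairs <- pairs[pairs$s != pairs$r, , drop = FALSE]
      pairs <- pairs[order(pairs$s, pairs$r), , drop = FALSE]
      s <- a[pairs$s[seq_len(count)]]
      r <- b[pairs$r[seq_len(count)]]
    } else {
      t <- seq_len(count)
      s <- a[(t - 1) %% length(a) + 1]
      r <- b[(t - 1) %% length(b) + 1]
    }
    rec[[length(rec) + 1]] <- data.frame(
      sender_id = s, receiver_id = r,
      condition_category = categories[(seq_len(count) - 1) %% 3 + 1],
      domain = domain, n_referrals = 1L, stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  cfg <- if (district == "kilolo") kilolo_config() else msalala_config()
  list(roster = roster,
       records = validate_records(records, roster, "table fixture"),
       distances = generate_distances(roster, cfg))
}
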