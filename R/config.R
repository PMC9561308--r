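#' Base-case model configuration
#'
#' Returns the packaged base-case configuration of the
#' partitioned-survival model as a nested list: log-logistic OS/PFS
#' parameters per arm, per-mg drug prices, dosing rules, grade >= 3
#' adverse-event incidences, costs and disutilities, health-state
#' utilities, body surface area, discounting, the willingness-to-pay
#' threshold, treatment durations, and the one-way/probabilistic
#' sensitivity ranges and distribution families for every varied
#' parameter.
#'
#' All monetary values are US dollars; survival time is in months;
#' the model cycle is 21 days.
#'
#' @return A nested list of class `psm_config`.
#' @examples
#' cfg <- base_config()
#' cfg$prices_per_mg$pembrolizumab
#' @export
base_config <- function() {
  cfg <- list(
    model = list(
      cycle_days = 21,
      horizon_years = 10,
      month_days = 30.4375,
      discount_rate = 0.05,
      wtp_per_qaly = 37663.26,
      bsa_m2 = 1.64,
      half_cycle_correction = FALSE
    ),
    survival = list(
      lp_os     = list(family = "loglogistic", shape = 1.5396, scale = 0.01375),
      lp_pfs    = list(family = "loglogistic", shape = 1.6294, scale = 0.04528),
      chemo_os  = list(family = "loglogistic", shape = 1.8582, scale = 0.01024),
      chemo_pfs = list(family = "loglogistic", shape = 1.941,  scale = 0.06522)
    ),
    prices_per_mg = list(
      lenvatinib = 4.255,
      pembrolizumab = 25.98,
      doxorubicin = 0.3220,
      paclitaxel = 0.1138
    ),
    dosing = list(
      lenvatinib_mg_per_day = 20,
      pembrolizumab_mg_per_cycle = 200,
      doxorubicin_mg_per_m2 = 60,
      paclitaxel_mg_per_m2 = 80,
      # 80 mg/m2 weekly, 3 weeks on / 1 off: 3 doses per 28 days,
      # i.e. 2.25 administrations per 21-day model cycle
      paclitaxel_admin_per_cycle = 2.25
    ),
    costs = list(
      followup_per_cycle = 337.50,
      bsc_per_cycle = 55.6,
      ae = list(hypertension = 12.9, anemia = 73.68, neutropenia = 461.5)
    ),
    utilities = list(
      pfd = 0.817,
      pd = 0.779,
      ae_disutility = list(hypertension = 0.1, anemia = 0.074,
                           neutropenia = 0.2)
    ),
    ae_incidence = list(
      lp    = list(hypertension = 0.379, anemia = 0.062, neutropenia = 0.017),
      chemo = list(hypertension = 0.023, anemia = 0.147, neutropenia = 0.258)
    ),
    treatment = list(
      # ceil(median treatment duration / 21 days): 231 d -> 11 cycles,
      # 104.5 d -> 5 cycles
      lp_duration_cycles = 11,
      chemo_duration_cycles = 5,
      chemo_doxorubicin_weight = 0.5
    ),
    sensitivity = list(
      list(path = "prices_per_mg.lenvatinib",    low = 2.7575, high = 4.255,  dist = "gamma"),
      list(path = "prices_per_mg.pembrolizumab", low = 12.99,  high = 25.98,  dist = "gamma"),
      list(path = "prices_per_mg.doxorubicin",   low = 0.1958, high = 0.4482, dist = "gamma"),
      list(path = "prices_per_mg.paclitaxel",    low = 0.0692, high = 0.1584, dist = "gamma"),
      list(path = "costs.ae.hypertension",       low = 11.6,   high = 14.2,   dist = "gamma"),
      list(path = "costs.ae.anemia",             low = 55.27,  high = 92.11,  dist = "gamma"),
      list(path = "costs.ae.neutropenia",        low = 415.4,  high = 507.7,  dist = "gamma"),
      list(path = "costs.bsc_per_cycle",         low = 27.8,   high = 83.4,   dist = "gamma"),
      list(path = "costs.followup_per_cycle",    low = 168.75, high = 506.25, dist = "gamma"),
      list(path = "utilities.pfd",               low = 0.797,  high = 0.836,  dist = "beta"),
      list(path = "utilities.pd",                low = 0.699,  high = 0.859,  dist = "beta"),
      list(path = "utilities.ae_disutility.hypertension", low = 0.1,   high = 0.15, dist = "beta"),
      list(path = "utilities.ae_disutility.anemia",       low = 0.037, high = 0.11, dist = "beta"),
      list(path = "utilities.ae_disutility.neutropenia",  low = 0.15,  high = 0.25, dist = "beta"),
      list(path = "model.bsa_m2",                low = 1.288,  high = 1.96,   dist = "beta"),
      list(path = "model.discount_rate",         low = 0,      high = 0.08,   dist = "beta"),
      # DSA-only parameters (no distribution assigned): +/- 25%
      list(path = "treatment.lp_duration_cycles",       low = 8,     high = 14,    dist = NA),
      list(path = "treatment.chemo_doxorubicin_weight", low = 0.375, high = 0.625, dist = NA)
    )
  )
  structure(cfg, class = c("psm_config", "list"))
}

#' Read and write model configurations
#'
#' Configurations are plain YAML (or JSON) mirroring the structure of
#' [base_config()].
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `load_config()` returns a `psm_config` list.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  validate_config(structure(cfg, class = c("psm_config", "list")))
}

#' @rdname load_config
#' @param cfg A `psm_config` list.
#' @export
save_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Get or set a configuration value by dot-path
#'
#' `cfg_get(cfg, "prices_per_mg.pembrolizumab")` retrieves a nested
#' value; `cfg_set()` replaces it (the path must already exist --
#' misspelled parameter names are an error, not a silent insertion).
#'
#' @param cfg A `psm_config`.
#' @param path Dot-separated path into the nested list.
#' @param value Replacement value.
#' @return The value, or the modified configuration.
#' @export
cfg_get <- function(cfg, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- cfg
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stop("no such configuration entry: '", path, "'")
    node <- node[[k]]
  }
  node
}

#' @rdname cfg_get
#' @export
cfg_set <- function(cfg, path, value) {
  cfg_get(cfg, path)  # errors if absent
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  cfg[[keys]] <- value
  cfg
}

#' Apply `key=value` override strings to a configuration
#'
#' Used by the command line (`--set path=value`); values are parsed as
#' numeric when possible, else kept as strings.
#'
#' @param cfg A `psm_config`.
#' @param overrides Character vector of `"dot.path=value"` strings.
#' @return The modified configuration.
#' @export
apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([^=]+)=(.*)$", ov))[[1L]]
    if (length(m) != 3L) stop("malformed override (need key=value): '", ov, "'")
    val <- suppressWarnings(as.numeric(m[3L]))
    if (is.na(val)) val <- m[3L]
    cfg <- cfg_set(cfg, trimws(m[2L]), val)
  }
  cfg
}

validate_config <- function(cfg) {
  need <- c("model", "survival", "prices_per_mg", "dosing", "costs",
            "utilities", "ae_incidence", "treatment")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("configuration is missing section(s): ", paste(miss, collapse = ", "))
  if (any(unlist(cfg$prices_per_mg) < 0)) stop("drug prices must be >= 0")
  u <- cfg$utilities
  # pfd >= pd holds for the base-case values; independent sensitivity
  # draws may cross, so only the range is a hard error here
  if (u$pfd < 0 || u$pfd > 1 || u$pd < 0 || u$pd > 1)
    stop("utilities must lie in [0,1]")
  inc <- unlist(cfg$ae_incidence)
  if (any(inc < 0 | inc > 1)) stop("adverse-event incidences must be in [0,1]")
  r <- cfg$model$discount_rate
  if (r < 0 || r > 1) stop("discount_rate must be in [0,1]")
  cfg
}
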