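# Reading, validating, serializing and overriding model configurations.
# The bundled base-case file (inst/extdata/base_case.yaml) encodes the full
# published parameter table so the base case needs zero user input.

req <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop("missing required key: ", where, ".", key, call. = FALSE)
  }
  x[[key]]
}

as_ranged <- function(x, field) {
  if (is.numeric(x) && length(x) == 1L) return(ranged_value(x))
  if (!is.list(x) || is.null(x$mean)) {
    stop("field '", field, "' must be a number or a {mean, low, high, ",
         "distribution} map", call. = FALSE)
  }
  tryCatch(
    ranged_value(x$mean,
                 low = if (is.null(x$low)) x$mean else x$low,
                 high = if (is.null(x$high)) x$mean else x$high,
                 distribution = if (is.null(x$distribution)) "fixed" else x$distribution),
    error = function(e) stop("field '", field, "': ", conditionMessage(e),
                             call. = FALSE))
}

as_endpoint <- function(x, field) {
  if (!is.null(x$theta)) {
    return(loglogistic_params(req(x, "theta", field), req(x, "kappa", field)))
  }
  if (!is.null(x$reference)) {
    hr <- req(x, "hr", field)
    return(hr_reference(x$reference, req(x, "endpoint", field),
                        hazard_ratio(req(hr, "mean", paste0(field, ".hr")),
                                     req(hr, "ci_low", paste0(field, ".hr")),
                                     req(hr, "ci_high", paste0(field, ".hr")))))
  }
  stop("field '", field, "' must give {theta, kappa} or an hr reference",
       call. = FALSE)
}

as_dosing <- function(x, field) {
  dosing_rule(unit_price = as_ranged(req(x, "unit_price", field),
                                     paste0(field, ".unit_price")),
              unit_size = req(x, "unit_size", field),
              dose_kind = req(x, "dose_kind", field),
              dose_value = req(x, "dose_value", field),
              administrations_per_cycle = req(x, "administrations_per_cycle", field))
}

#' Load and validate a model configuration file
#'
#' Reads the YAML parameter file, validates every field against its
#' invariants and returns a typed `cea_config`. Missing required keys raise a
#' schema error naming the key; violated invariants raise a validation error
#' naming field and bound.
#'
#' @param path Path to a YAML model-config file.
#' @return A `cea_config` (see [model_config()]).
#' @seealso [base_case_config()] for the bundled base-case parameter set.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  st <- req(raw, "settings", "config")
  utilities <- req(st, "utilities", "settings")
  care <- req(st, "care_costs", "settings")
  anl <- req(st, "anlotinib", "settings")
  settings <- model_settings(
    cycle_length_days = req(st, "cycle_length_days", "settings"),
    horizon_years = req(st, "horizon_years", "settings"),
    discount_rate_annual = as_ranged(req(st, "discount_rate_annual", "settings"),
                                     "settings.discount_rate_annual"),
    wtp_per_qaly = req(st, "wtp_per_qaly", "settings"),
    body_weight_kg = as_ranged(req(st, "body_weight_kg", "settings"),
                               "settings.body_weight_kg"),
    body_surface_m2 = as_ranged(req(st, "body_surface_m2", "settings"),
                                "settings.body_surface_m2"),
    utilities = list(
      pfs = as_ranged(req(utilities, "pfs", "settings.utilities"), "utilities.pfs"),
      pd = as_ranged(req(utilities, "pd", "settings.utilities"), "utilities.pd"),
      end_stage = as_ranged(req(utilities, "end_stage", "settings.utilities"),
                            "utilities.end_stage")),
    care_costs = list(
      followup = as_ranged(req(care, "followup", "settings.care_costs"),
                           "care_costs.followup"),
      bsc = as_ranged(req(care, "bsc", "settings.care_costs"), "care_costs.bsc"),
      palliative = as_ranged(req(care, "palliative", "settings.care_costs"),
                             "care_costs.palliative")),
    anlotinib = list(
      os = as_endpoint(req(anl, "os", "settings.anlotinib"), "anlotinib.os"),
      pfs = as_endpoint(req(anl, "pfs", "settings.anlotinib"), "anlotinib.pfs"),
      dosing = as_dosing(req(anl, "dosing", "settings.anlotinib"),
                         "anlotinib.dosing")),
    half_cycle_correction = isTRUE(st$half_cycle_correction),
    end_stage_mortality_mode = st$end_stage_mortality_mode %||% "anlotinib_os_clock",
    end_stage_fixed_prob = st$end_stage_fixed_prob,
    palliative_cost_mode = st$palliative_cost_mode %||% "one_time_death",
    pd_clock_mode = st$pd_clock_mode %||% "state_entry",
    hr_application = st$hr_application %||% "ph")
  strategies <- lapply(req(raw, "strategies", "config"), function(s) {
    nm <- req(s, "name", "strategies[]")
    strategy_spec(
      name = nm,
      os = as_endpoint(req(s, "os", nm), paste0(nm, ".os")),
      pfs = as_endpoint(req(s, "pfs", nm), paste0(nm, ".pfs")),
      discontinuation_prob_per_cycle =
        as_ranged(req(s, "discontinuation_prob_per_cycle", nm),
                  paste0(nm, ".discontinuation_prob_per_cycle")),
      dosing = as_dosing(req(s, "dosing", nm), paste0(nm, ".dosing")),
      ae_cost = as_ranged(req(s, "ae_cost", nm), paste0(nm, ".ae_cost")),
      ae_disutility = as_ranged(req(s, "ae_disutility", nm),
                                paste0(nm, ".ae_disutility")),
      subsequent_therapy_proportion =
        as_ranged(req(s, "subsequent_therapy_proportion", nm),
                  paste0(nm, ".subsequent_therapy_proportion")))
  })
  model_config(settings, strategies)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the bundled base-case parameter file
#' @return File path within the installed package.
#' @export
base_case_path <- function() {
  system.file("extdata", "base_case.yaml", package = "nsclcCEA", mustWork = TRUE)
}

#' Load the bundled base-case configuration
#'
#' The shipped file encodes the published parameter table verbatim: the
#' log-logistic theta/kappa pairs for each survival endpoint, the nivolumab
#' hazard ratios, per-cycle discontinuation probabilities, unit drug prices,
#' per-cycle care costs, adverse-event aggregates, state utilities, the 5\%
#' annual discount rate and the $35,663/QALY willingness-to-pay threshold.
#'
#' @return A `cea_config`.
#' @export
base_case_config <- function() load_model_config(base_case_path())

ranged_to_list <- function(v) {
  list(mean = v$mean, low = v$low, high = v$high, distribution = v$distribution)
}

endpoint_to_list <- function(e) {
  if (inherits(e, "loglogistic_params")) {
    list(theta = e$theta, kappa = e$kappa)
  } else {
    list(reference = e$reference, endpoint = e$endpoint,
         hr = list(mean = e$hr$mean, ci_low = e$hr$ci_low, ci_high = e$hr$ci_high))
  }
}

dosing_to_list <- function(d) {
  list(unit_price = ranged_to_list(d$unit_price), unit_size = d$unit_size,
       dose_kind = d$dose_kind, dose_value = d$dose_value,
       administrations_per_cycle = d$administrations_per_cycle)
}

config_to_list <- function(config) {
  st <- config$settings
  list(
    settings = list(
      cycle_length_days = st$cycle_length_days,
      horizon_years = st$horizon_years,
      discount_rate_annual = ranged_to_list(st$discount_rate_annual),
      wtp_per_qaly = st$wtp_per_qaly,
      body_weight_kg = ranged_to_list(st$body_weight_kg),
      body_surface_m2 = ranged_to_list(st$body_surface_m2),
      utilities = lapply(st$utilities, ranged_to_list),
      care_costs = lapply(st$care_costs, ranged_to_list),
      anlotinib = list(os = endpoint_to_list(st$anlotinib$os),
                       pfs = endpoint_to_list(st$anlotinib$pfs),
                       dosing = dosing_to_list(st$anlotinib$dosing)),
      half_cycle_correction = st$half_cycle_correction,
      end_stage_mortality_mode = st$end_stage_mortality_mode,
      end_stage_fixed_prob = st$end_stage_fixed_prob,
      palliative_cost_mode = st$palliative_cost_mode,
      pd_clock_mode = st$pd_clock_mode,
      hr_application = st$hr_application),
    strategies = lapply(unname(config$strategies), function(s) {
      list(name = s$name,
           os = endpoint_to_list(s$os),
           pfs = endpoint_to_list(s$pfs),
           discontinuation_prob_per_cycle =
             ranged_to_list(s$discontinuation_prob_per_cycle),
           dosing = dosing_to_list(s$dosing),
           ae_cost = ranged_to_list(s$ae_cost),
           ae_disutility = ranged_to_list(s$ae_disutility),
           subsequent_therapy_proportion =
             ranged_to_list(s$subsequent_therapy_proportion))
    }))
}

#' Serialize a configuration back to YAML
#'
#' `load_model_config(write_model_config(cfg, f))` reproduces `cfg`
#' field-by-field (round-trip property).
#'
#' @param config A `cea_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15L)
  invisible(path)
}

#' Dump a normalized configuration as JSON (provenance logging)
#'
#' @param config A `cea_config`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
config_as_json <- function(config, path = NULL) {
  js <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

config_get <- function(config, path) {
  x <- config
  for (p in path) x <- x[[p]]
  x
}

config_set <- function(config, path, value) {
  if (length(path) == 1L) {
    config[[path]] <- value
    return(config)
  }
  config[[path[1L]]] <- config_set(config[[path[1L]]], path[-1L], value)
  config
}

# One row per sweepable/sampleable parameter: id, access path, kind.
param_registry <- function(config) {
  entries <- list(
    list(id = "discount_rate", path = c("settings", "discount_rate_annual"), kind = "ranged"),
    list(id = "body_weight", path = c("settings", "body_weight_kg"), kind = "ranged"),
    list(id = "body_surface_area", path = c("settings", "body_surface_m2"), kind = "ranged"),
    list(id = "utility_pfs", path = c("settings", "utilities", "pfs"), kind = "ranged"),
    list(id = "utility_pd", path = c("settings", "utilities", "pd"), kind = "ranged"),
    list(id = "utility_end_stage", path = c("settings", "utilities", "end_stage"), kind = "ranged"),
    list(id = "cost_followup", path = c("settings", "care_costs", "followup"), kind = "ranged"),
    list(id = "cost_bsc", path = c("settings", "care_costs", "bsc"), kind = "ranged"),
    list(id = "cost_palliative", path = c("settings", "care_costs", "palliative"), kind = "ranged"),
    list(id = "price_anlotinib", path = c("settings", "anlotinib", "dosing", "unit_price"), kind = "ranged"))
  for (nm in names(config$strategies)) {
    s <- config$strategies[[nm]]
    entries <- c(entries, list(
      list(id = paste0("disc_prob_", nm),
           path = c("strategies", nm, "discontinuation_prob_per_cycle"), kind = "ranged"),
      list(id = paste0("price_", nm),
           path = c("strategies", nm, "dosing", "unit_price"), kind = "ranged"),
      list(id = paste0("ae_cost_", nm),
           path = c("strategies", nm, "ae_cost"), kind = "ranged"),
      list(id = paste0("ae_disutility_", nm),
           path = c("strategies", nm, "ae_disutility"), kind = "ranged"),
      list(id = paste0("subsequent_therapy_", nm),
           path = c("strategies", nm, "subsequent_therapy_proportion"), kind = "ranged")))
    for (ep in c("os", "pfs")) {
      if (inherits(s[[ep]], "hr_reference")) {
        entries <- c(entries, list(
          list(id = paste0("hr_", ep, "_", nm),
               path = c("strategies", nm, ep, "hr"), kind = "hazard_ratio")))
      }
    }
  }
  entries
}

#' Table of sweepable model parameters
#'
#' Lists every parameter exposed to deterministic and probabilistic
#' sensitivity analysis, with its baseline, range and distribution tag. The
#' fitted log-logistic theta/kappa pairs are deliberately absent: they are
#' held fixed in both analyses.
#'
#' @param config A `cea_config`.
#' @return A data frame with columns `id`, `mean`, `low`, `high`,
#'   `distribution`.
#' @export
param_table <- function(config) {
  entries <- param_registry(config)
  do.call(rbind, lapply(entries, function(e) {
    v <- config_get(config, e$path)
    if (e$kind == "hazard_ratio") {
      data.frame(id = e$id, mean = v$mean, low = v$ci_low, high = v$ci_high,
                 distribution = "normal")
    } else {
      data.frame(id = e$id, mean = v$mean, low = v$low, high = v$high,
                 distribution = v$distribution)
    }
  }))
}

#' Override one named parameter
#'
#' Returns a new configuration differing only in the named parameter's point
#' value (the DSA range and distribution tag are untouched); the input is
#' unchanged. Overrides of different parameters commute.
#'
#' @param config A `cea_config`.
#' @param id Parameter id as listed by [param_table()].
#' @param value New point value.
#' @return The overridden `cea_config`.
#' @export
apply_override <- function(config, id, value) {
  entries <- param_registry(config)
  ids <- vapply(entries, `[[`, character(1), "id")
  i <- match(id, ids)
  if (is.na(i)) {
    stop("unknown parameter '", id, "'; valid names: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  e <- entries[[i]]
  v <- config_get(config, e$path)
  v$mean <- value
  config_set(config, e$path, v)
}
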