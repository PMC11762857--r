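# Full model parameter set: risk equation, age trends, event/mortality
# parameters, costs, utilities, engine options.

#' Assemble a complete model parameter set
#'
#' Bundles everything one simulation run needs: the risk-equation
#' coefficients, risk-factor age trends, event and mortality parameters,
#' cost and utility parameters, and engine options. The discount rate lives
#' in [utility_parameters()] and applies identically to costs and QALYs.
#'
#' @param coefficients a [risk_coefficients()] object.
#' @param trends an [age_trend_model()].
#' @param events an [event_parameters()] object.
#' @param costs a [cost_parameters()] object.
#' @param utilities a [utility_parameters()] object.
#' @param max_age simulation age cap (individuals are censored after the
#'   cycle in which they are this old).
#' @param allow_recurrence if `TRUE`, post-event survivors face the same
#'   annual ASCVD hazard again (recurrent events, decrements not stacked);
#'   default `FALSE` (first-event model).
#' @param floors lower bounds for continuous risk factors during projection.
#' @return an object of class `parameter_set`.
#' @export
parameter_set <- function(coefficients = default_risk_coefficients(),
                          trends = default_age_trends(),
                          events = event_parameters(),
                          costs = cost_parameters(),
                          utilities = utility_parameters(),
                          max_age = 89,
                          allow_recurrence = FALSE,
                          floors = c(sbp = 80, tc = 2.0, hdl = 0.3,
                                     ldl = 0.5, wc = 50)) {
  stopifnot(inherits(coefficients, "risk_coefficients"),
            inherits(trends, "age_trend_model"),
            inherits(events, "event_parameters"),
            inherits(costs, "cost_parameters"),
            inherits(utilities, "utility_parameters"),
            max_age >= 40, max_age <= 89)
  structure(list(coefficients = coefficients, trends = trends,
                 events = events, costs = costs, utilities = utilities,
                 max_age = max_age, allow_recurrence = allow_recurrence,
                 floors = floors),
            class = "parameter_set")
}

# addressable parameters for sensitivity analysis: short name -> list path
param_registry <- function() {
  list(
    or_chd             = c("events", "or_chd"),
    or_stroke          = c("events", "or_stroke"),
    or_diabetes        = c("events", "or_diabetes"),
    chd_share          = c("events", "chd_share"),
    post_event_mortality_multiplier =
      c("events", "post_event_mortality_multiplier"),
    statin_cost        = c("costs", "statin_annual"),
    hosp_chd           = c("costs", "hosp_chd"),
    hosp_stroke        = c("costs", "hosp_stroke"),
    first_year_chd     = c("costs", "first_year_chd"),
    first_year_stroke  = c("costs", "first_year_stroke"),
    office_chd         = c("costs", "office_chd"),
    office_stroke      = c("costs", "office_stroke"),
    diabetes_cost      = c("costs", "diabetes_annual"),
    acute_chd          = c("utilities", "acute_chd"),
    acute_stroke       = c("utilities", "acute_stroke"),
    longterm_chd       = c("utilities", "longterm_chd"),
    longterm_stroke    = c("utilities", "longterm_stroke"),
    diabetes_disutility = c("utilities", "diabetes"),
    discount_rate      = c("utilities", "discount_rate")
  )
}

#' Set a named model parameter
#'
#' Addresses scalar parameters by the short names used in sensitivity
#' analysis (e.g. `"statin_cost"`, `"or_chd"`, `"acute_stroke"`).
#'
#' @param params a [parameter_set()].
#' @param name parameter name; see `names(statinsim:::param_registry())`.
#' @param value new value.
#' @return the modified `parameter_set`.
#' @export
set_parameter <- function(params, name, value) {
  stopifnot(inherits(params, "parameter_set"))
  reg <- param_registry()
  if (!name %in% names(reg)) {
    stop("unknown parameter '", name, "'; known parameters: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  path <- reg[[name]]
  params[[path[1]]][[path[2]]] <- value
  params
}

#' Get a named model parameter
#'
#' @inheritParams set_parameter
#' @return the parameter's current value.
#' @export
get_parameter <- function(params, name) {
  reg <- param_registry()
  if (!name %in% names(reg)) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  path <- reg[[name]]
  params[[path[1]]][[path[2]]]
}
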