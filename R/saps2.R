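# SAPS-II severity score -------------------------------------------------

# Physiologic admissibility bounds used for input validation (generator
# bounds in cohort_config() are a subset of these).
.saps2_bounds <- list(
  age             = c(0, 130),
  heart_rate      = c(0, 350),
  systolic_bp     = c(0, 400),
  temperature     = c(25, 45),
  pao2_fio2_ratio = c(0, 800),
  urine_output    = c(0, 20000),
  bun             = c(0, 400),
  sodium          = c(90, 200),
  potassium       = c(0.5, 12),
  bicarbonate     = c(1, 60),
  bilirubin       = c(0, 80),
  wbc             = c(0, 300),
  gcs             = c(3, 15)
)

.saps2_env <- new.env(parent = emptyenv())

#' SAPS-II point table
#'
#' Returns the category point assignments used by [saps2_score()], read from
#' the versioned JSON table shipped with the package. Interval components
#' carry `breaks` (right-open interval edges) and per-interval `points`;
#' categorical components carry a named point map. The PaO2/FiO2 component
#' is scored only for mechanically ventilated patients.
#'
#' @return A list with elements `table_version` and `components`.
#' @export
saps2_point_table <- function() {
  if (is.null(.saps2_env$table)) {
    .saps2_env$table <- jsonlite::read_json(
      icusurv_extdata("saps2_points.json"), simplifyVector = TRUE
    )
  }
  .saps2_env$table
}

.saps2_factor_fields <- c(
  "age", "heart_rate", "systolic_bp", "temperature", "pao2_fio2_ratio",
  "urine_output", "bun", "sodium", "potassium", "bicarbonate", "bilirubin",
  "wbc", "gcs", "chronic_disease", "admission_type"
)

.chronic_levels <- c("none", "metastatic_cancer", "hematologic_malignancy", "aids")
.admission_levels <- c("scheduled_surgical", "medical", "unscheduled_surgical")

validate_risk_factors <- function(factors) {
  if (is.list(factors) && !is.data.frame(factors)) {
    factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(factors)) {
    stop_input("`factors` must be a data.frame or named list of risk factors")
  }
  missing <- setdiff(.saps2_factor_fields, names(factors))
  if (length(missing)) {
    stop_input("missing risk factor field(s): %s", paste(missing, collapse = ", "))
  }
  if (!"ventilated" %in% names(factors)) {
    # conservative default: not ventilated, PaO2/FiO2 component scores 0
    factors$ventilated <- FALSE
  }
  for (f in names(.saps2_bounds)) {
    x <- factors[[f]]
    if (!is.numeric(x) || anyNA(x)) {
      stop_input("risk factor '%s' must be numeric with no missing values", f)
    }
    b <- .saps2_bounds[[f]]
    if (any(x < b[1] | x > b[2])) {
      stop_input("risk factor '%s' outside admissible range [%g, %g]", f, b[1], b[2])
    }
  }
  if (any(factors$gcs != round(factors$gcs))) {
    stop_input("risk factor 'gcs' must be an integer in [3, 15]")
  }
  if (!all(factors$chronic_disease %in% .chronic_levels)) {
    stop_input("risk factor 'chronic_disease' must be one of: %s",
               paste(.chronic_levels, collapse = ", "))
  }
  if (!all(factors$admission_type %in% .admission_levels)) {
    stop_input("risk factor 'admission_type' must be one of: %s",
               paste(.admission_levels, collapse = ", "))
  }
  if (!is.logical(factors$ventilated) || anyNA(factors$ventilated)) {
    stop_input("risk factor 'ventilated' must be logical with no missing values")
  }
  factors
}

interval_points <- function(x, breaks, points) {
  points[findInterval(x, breaks) + 1L]
}

#' Compute the SAPS-II severity score
#'
#' Sums category points over the 15 SAPS-II components (13 physiological
#' measurements plus chronic disease and admission type), yielding an
#' integer score between 0 and 163. The PaO2/FiO2 component is scored only
#' when `ventilated` is `TRUE` (mechanical ventilation or CPAP); otherwise
#' it contributes 0 points, as in the original score definition.
#'
#' @param factors A data.frame (one row per patient) or named list with the
#'   fields `age`, `heart_rate`, `systolic_bp`, `temperature`,
#'   `pao2_fio2_ratio`, `urine_output` (mL/day), `bun` (mg/dL), `sodium`,
#'   `potassium`, `bicarbonate`, `bilirubin` (mg/dL), `wbc` (10^3/uL),
#'   `gcs` (integer 3-15), `chronic_disease` (one of `none`,
#'   `metastatic_cancer`, `hematologic_malignancy`, `aids`),
#'   `admission_type` (one of `scheduled_surgical`, `medical`,
#'   `unscheduled_surgical`), and optionally `ventilated` (logical,
#'   default `FALSE`).
#' @return Integer vector of scores, one per row of `factors`.
#' @examples
#' healthy <- list(
#'   age = 30, heart_rate = 80, systolic_bp = 120, temperature = 37,
#'   pao2_fio2_ratio = 450, urine_output = 1500, bun = 15, sodium = 140,
#'   potassium = 4.2, bicarbonate = 24, bilirubin = 0.7, wbc = 8, gcs = 15,
#'   chronic_disease = "none", admission_type = "scheduled_surgical"
#' )
#' saps2_score(healthy)  # 0
#' @export
saps2_score <- function(factors) {
  factors <- validate_risk_factors(factors)
  tab <- saps2_point_table()$components
  total <- integer(nrow(factors))
  for (f in .saps2_factor_fields) {
    comp <- tab[[f]]
    if (identical(comp$type, "interval")) {
      pts <- interval_points(factors[[f]], comp$breaks, comp$points)
      if (isTRUE(comp$requires_ventilation)) {
        pts[!factors$ventilated] <- comp$not_ventilated_points
      }
    } else {
      pts <- unlist(comp$points)[factors[[f]]]
    }
    total <- total + as.integer(pts)
  }
  unname(total)
}
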