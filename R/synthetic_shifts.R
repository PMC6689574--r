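# Phenotype simulation with the structure of the two experiments:
#  - social context: 2 selfing lines (DAN, R); per line 8 control fish plus 9
#    test fish each observed under both a single-fish and a group context
#    (34 unique fish, 52 fish x context units)
#  - infection: 80 fish (40 per line), 20 infected / 20 control per line
# Each unit is photographed at 0, 24 and 48 h, giving three shift intervals
# (0-24, 0-48, 24-48) per unit.

.INTERVALS <- data.frame(
  interval = factor(c("0-24", "0-48", "24-48"),
                    levels = c("0-24", "0-48", "24-48")),
  time_h   = c(24, 48, 48),      # interval-end hour
  from_h   = c(0, 0, 24),
  to_h     = c(24, 48, 48)
)

#' Experiment design tables
#'
#' Builds the unit table of one of the two study designs. A "unit" is one
#' fish under one treatment; in the social design the 9 test fish per line
#' appear under both the single and the group context (with the same
#' `individual_id`), while controls appear once.
#'
#' @param experiment `"social"` or `"infection"`.
#' @return Data frame with columns `unit_id`, `individual_id`, `line`
#'   (factor DAN/R) and `treatment` (factor; control/single/group or
#'   control/infected).
#' @export
experiment_design <- function(experiment = c("social", "infection")) {
  experiment <- match.arg(experiment)
  if (experiment == "infection") {
    d <- expand.grid(i = 1:40, line = c("DAN", "R"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$individual_id <- sprintf("%s_%02d", d$line, d$i)
    d$treatment <- ifelse(d$i <= 20, "infected", "control")
    d$unit_id <- d$individual_id
    d$treatment <- factor(d$treatment, levels = c("control", "infected"))
  } else {
    per_line <- function(line) {
      ctrl <- data.frame(individual_id = sprintf("%s_c%02d", line, 1:8),
                         line = line, treatment = "control")
      test <- sprintf("%s_t%02d", line, 1:9)
      rbind(ctrl,
            data.frame(individual_id = test, line = line, treatment = "single"),
            data.frame(individual_id = test, line = line, treatment = "group"))
    }
    d <- rbind(per_line("DAN"), per_line("R"))
    d$unit_id <- paste(d$individual_id, d$treatment, sep = ".")
    d$treatment <- factor(d$treatment, levels = c("control", "single", "group"))
  }
  d$line <- factor(d$line, levels = c("DAN", "R"))
  rownames(d) <- NULL
  d[, c("unit_id", "individual_id", "line", "treatment")]
}

#' Generating model for simulated colour shifts
#'
#' Defines the linear mixed-effects model the simulator draws from:
#' `delta = X beta + u_individual + eps`, with a Gaussian random intercept
#' per fish and Gaussian residuals. `beta` is named after design-matrix
#' columns under treatment contrasts (e.g. `"(Intercept)"`,
#' `"treatmentinfected"`, `"lineR"`, `"time_h"`,
#' `"lineR:treatmentinfected"`); unnamed columns contribute zero.
#'
#' @param attribute Response label, one of `"L"`, `"h"`, `"C"` (free text
#'   allowed).
#' @param beta Named numeric vector of fixed-effect coefficients.
#' @param sd_individual Random-intercept standard deviation (>= 0).
#' @param sd_resid Residual standard deviation (>= 0).
#' @param time_coding `"hours"` codes time as the interval-end hour
#'   (`time_h`: 24 or 48); `"categorical"` codes the interval factor.
#' @return Object of class `effect_model`.
#' @export
effect_model <- function(attribute = "L",
                         beta = c("(Intercept)" = 0),
                         sd_individual = 1,
                         sd_resid = 1,
                         time_coding = c("hours", "categorical")) {
  stopifnot(sd_individual >= 0, sd_resid >= 0, !is.null(names(beta)))
  structure(list(attribute = attribute, beta = beta,
                 sd_individual = sd_individual, sd_resid = sd_resid,
                 time_coding = match.arg(time_coding)),
            class = "effect_model")
}

# design matrix columns referenced by a model's beta, in beta's order
.sim_design_matrix <- function(data, model) {
  covs <- if (model$time_coding == "hours") {
    stats::reformulate(c("line", "treatment", "time_h", "interval"))
  } else {
    stats::reformulate(c("line", "treatment", "interval"))
  }
  # build a saturated column dictionary incl. all interactions among the
  # main columns so any named beta can be resolved
  mm_main <- stats::model.matrix(covs, data)
  cols <- colnames(mm_main)
  X <- matrix(0, nrow(data), length(model$beta),
              dimnames = list(NULL, names(model$beta)))
  for (nm in names(model$beta)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% c(cols, "(Intercept)"))) {
      stop("effect_model beta names unresolvable column: ", nm)
    }
    col <- rep(1, nrow(data))
    for (p in parts) if (p != "(Intercept)") col <- col * mm_main[, p]
    X[, nm] <- col
  }
  X
}

#' Simulate a shift dataset for a design
#'
#' One record per unit x interval (three intervals per unit). The response
#' is drawn from the model's LMM: fixed effects from `beta`, a shared
#' random intercept per `individual_id`, independent Gaussian residuals.
#' Deterministic given `seed`.
#'
#' @param design Data frame from [experiment_design()].
#' @param model An [effect_model()].
#' @param seed Integer seed.
#' @return Data frame of shift records: `unit_id`, `individual_id`, `line`,
#'   `treatment`, `interval`, `time_h`, `attribute`, `delta`.
#' @export
generate_shift_dataset <- function(design, model, seed = 1L) {
  stopifnot(inherits(model, "effect_model"))
  data <- merge(design, .INTERVALS[, c("interval", "time_h")], by = NULL)
  data <- data[order(data$unit_id, data$interval), ]
  rownames(data) <- NULL
  X <- .sim_design_matrix(data, model)
  mu <- as.vector(X %*% model$beta)
  ids <- sort(unique(design$individual_id))
  .with_seed(seed, {
    u <- stats::rnorm(length(ids), 0, model$sd_individual)
    names(u) <- ids
    eps <- stats::rnorm(nrow(data), 0, model$sd_resid)
    data$delta <- mu + u[data$individual_id] + eps
  })
  data$attribute <- model$attribute
  data[, c("unit_id", "individual_id", "line", "treatment",
           "interval", "time_h", "attribute", "delta")]
}

#' Simulate raw attribute trajectories instead of shifts
#'
#' Alternative pathway for testing [compute_shifts()]: per-unit attribute
#' values at 0, 24 and 48 h with a per-hour drift, an individual baseline
#' and measurement noise. Differencing these records reproduces the shift
#' structure the direct simulator draws from.
#'
#' @param design Data frame from [experiment_design()].
#' @param baseline Population baseline of the attribute at 0 h.
#' @param drift_per_h Named numeric: per-hour drift coefficients named after
#'   design-matrix columns (as in [effect_model()]), e.g.
#'   `c("(Intercept)" = 0.1, "treatmentinfected" = 0.05)`.
#' @param sd_individual SD of the per-fish baseline deviation.
#' @param sd_resid SD of per-photograph measurement noise.
#' @param attribute Attribute label for the value columns.
#' @param seed Integer seed.
#' @return Data frame of attribute records: `unit_id`, `individual_id`,
#'   `line`, `treatment`, `time_h`, `value`, `attribute`.
#' @export
generate_attribute_records <- function(design, baseline = 50,
                                       drift_per_h = c("(Intercept)" = 0.1),
                                       sd_individual = 2, sd_resid = 0.5,
                                       attribute = "L", seed = 1L) {
  times <- data.frame(time_h = c(0, 24, 48))
  data <- merge(design, times, by = NULL)
  data <- data[order(data$unit_id, data$time_h), ]
  rownames(data) <- NULL
  fake <- data
  fake$interval <- factor("0-24", levels = levels(.INTERVALS$interval))
  dm_model <- effect_model(attribute, beta = drift_per_h, time_coding = "categorical")
  X <- .sim_design_matrix(fake, dm_model)
  rate <- as.vector(X %*% drift_per_h)
  ids <- sort(unique(design$individual_id))
  .with_seed(seed, {
    u <- stats::rnorm(length(ids), 0, sd_individual)
    names(u) <- ids
    eps <- stats::rnorm(nrow(data), 0, sd_resid)
    data$value <- baseline + u[data$individual_id] + rate * data$time_h + eps
  })
  data$attribute <- attribute
  data[, c("unit_id", "individual_id", "line", "treatment",
           "time_h", "value", "attribute")]
}
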