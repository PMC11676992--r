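# internal helpers shared across modules

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` uses the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# The HRV / haemodynamic variables carried through the analysis, in the
# canonical reporting order.
#' Names of the analysis variables
#'
#' Returns the column names of the variables a cohort table carries through
#' descriptives, ANOVA-type tests and relative-effect estimation: time- and
#' frequency-domain HRV indices, the orthostatic change in normalized LF
#' power, the composite ANSI, and systolic/diastolic arterial pressure.
#'
#' @param include_ansi logical; drop `"ansi"` when a cohort has not had the
#'   composite index computed yet.
#' @return character vector of column names.
#' @export
#' @examples
#' hrv_variables()
hrv_variables <- function(include_ansi = TRUE) {
  v <- c("rr_mean", "rr_tp", "rr_lfa", "rr_hfa", "rr_lfnu", "rr_hfnu",
         "rr_lfhf", "delta_lfnu", "ansi", "sap", "dap")
  if (!include_ansi) v <- setdiff(v, "ansi")
  v
}

# canonical factor levels of the design
design_levels <- list(
  treatment = c("-55C", "-110C"),
  time      = c("T1", "T10"),
  phase     = c("pre", "post")
)

# Coerce the design columns of a cohort data.frame to canonical factors and
# check the layout is a complete 2 (time) x 2 (phase) grid per subject.
#' @noRd
check_cohort <- function(cohort, variable = NULL, require_complete = TRUE) {
  need <- c("subject_id", "treatment", "time", "phase")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cohort$treatment <- factor(as.character(cohort$treatment))
  cohort$time <- factor(as.character(cohort$time), levels = design_levels$time)
  cohort$phase <- factor(as.character(cohort$phase),
                         levels = design_levels$phase)
  if (anyNA(cohort$time) || anyNA(cohort$phase)) {
    stop("'time' must be one of T1/T10 and 'phase' one of pre/post",
         call. = FALSE)
  }
  if (!is.null(variable)) {
    if (!variable %in% names(cohort)) {
      stop(sprintf("variable '%s' not found in cohort", variable),
           call. = FALSE)
    }
  }
  if (require_complete) {
    tab <- table(cohort$subject_id, cohort$time, cohort$phase)
    if (any(tab != 1L)) {
      bad <- rownames(tab)[apply(tab != 1L, 1L, any)]
      stop("incomplete or duplicated time-by-phase layout for subject(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    trt_per_subj <- tapply(as.character(cohort$treatment), cohort$subject_id,
                           function(x) length(unique(x)))
    if (any(trt_per_subj != 1L)) {
      stop("each subject must belong to exactly one treatment group",
           call. = FALSE)
    }
  }
  cohort
}
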