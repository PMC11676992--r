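# Orchestration: descriptive statistics and the full analysis chain
# (features -> composite index -> baseline adjustment -> rank-based tests
# and relative effects), with CSV report emission.

#' Median +/- MAD descriptives per design cell
#'
#' For every variable and every treatment x time x phase cell, reports the
#' median and the unscaled median absolute deviation
#' `MAD = median(|x - median(x)|)` — the robust descriptive pair used for
#' skewed HRV variables.
#'
#' @param cohort a long-format cohort `data.frame`.
#' @param variables variable columns to describe.
#' @return a `data.frame` with `variable, treatment, time, phase, median,
#'   mad, n`; empty cells yield `NA` with a warning.
#' @export
#' @examples
#' describe_cohort(generate_cohort(cohort_config(seed = 1)))
describe_cohort <- function(cohort,
                            variables = intersect(hrv_variables(),
                                                  names(cohort))) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  cohort <- check_cohort(cohort, require_complete = FALSE)
  cells <- expand.grid(treatment = levels(cohort$treatment),
                       time = design_levels$time,
                       phase = design_levels$phase,
                       stringsAsFactors = FALSE)
  rows <- lapply(variables, function(v) {
    cbind(variable = v, cells, t(vapply(seq_len(nrow(cells)), function(i) {
      x <- cohort[[v]][cohort$treatment == cells$treatment[i] &
                         cohort$time == cells$time[i] &
                         cohort$phase == cells$phase[i]]
      x <- x[!is.na(x)]
      if (length(x) == 0L) {
        warning(sprintf("empty cell for %s (%s, %s, %s)", v,
                        cells$treatment[i], cells$time[i], cells$phase[i]),
                call. = FALSE)
        return(c(median = NA_real_, mad = NA_real_, n = 0))
      }
      med <- stats::median(x)
      c(median = med, mad = stats::median(abs(x - med)), n = length(x))
    }, numeric(3))))
  })
  out <- do.call(rbind, rows)
  out$variable <- as.character(out$variable)
  out
}

#' Run the complete analysis chain on a cohort
#'
#' Sequences the full pipeline: (optional) composite ANSI computation,
#' median +/- MAD descriptives of the raw values, the seven ANOVA-type
#' tests per variable on the raw values, baseline adjustment
#' (`X~ = X - x(T1, pre)`), adjusted relative effects with CIs in the
#' requested scope(s), CI-disjointness flags for the pre/post comparison
#' at each time level, and per-treatment profile data (with the marginal
#' phase and time effects) for profile plots.
#'
#' @param cohort a complete long-format cohort `data.frame`, or a path to
#'   a cohort CSV.
#' @param variables variable columns to analyze.
#' @param scope `"both"` (default) emits relative effects jointly over the
#'   four time-by-phase conditions and separately within each time level;
#'   or one of `"condition"`, `"within-time"`.
#' @param conf_level confidence level for relative-effect CIs.
#' @param ci_method `"normal"` or `"logit"`, see [relative_effects()].
#' @param add_ansi compute the ANSI column when absent (default) provided
#'   its inputs are present.
#' @param out_dir optional directory; when given, writes
#'   `descriptives.csv`, `test_table.csv` (variables x 7 effects,
#'   p-values), `test_details.csv`, `effects_table.csv` (AREs, CIs and
#'   flags), `profile_data.csv` and `run_log.txt`.
#' @param seed recorded in the run log (the analysis itself is
#'   deterministic; the seed matters when the cohort was generated).
#' @return an object of class `cryohrv_report`: a list with
#'   `descriptives`, `test_table` (wide p-values), `test_details`,
#'   `effects_table`, `flags`, `profile_data`.
#' @export
run_full_analysis <- function(cohort,
                              variables = NULL,
                              scope = c("both", "condition", "within-time"),
                              conf_level = 0.95,
                              ci_method = c("normal", "logit"),
                              add_ansi = TRUE,
                              out_dir = NULL, seed = NULL) {
  scope <- match.arg(scope)
  ci_method <- match.arg(ci_method)
  if (is.character(cohort) && length(cohort) == 1L) {
    cohort <- read_cohort_csv(cohort)
  }
  cohort <- check_cohort(cohort)
  if (add_ansi && !"ansi" %in% names(cohort) &&
      all(c("rr_mean", "rr_tp", "delta_lfnu", "age", "sex") %in%
            names(cohort))) {
    cohort$ansi <- compute_ansi(cohort)$ansi
  }
  if (is.null(variables)) {
    variables <- intersect(hrv_variables(), names(cohort))
  }
  if (length(variables) == 0L) stop("no analysis variables found",
                                    call. = FALSE)

  descriptives <- describe_cohort(cohort, variables)

  test_details <- do.call(rbind, lapply(variables, anova_type_tests,
                                        cohort = cohort))
  test_table <- stats::reshape(
    test_details[, c("variable", "effect", "p_value")],
    idvar = "variable", timevar = "effect", direction = "wide")
  names(test_table) <- sub("^p_value\\.", "", names(test_table))
  test_table <- test_table[match(variables, test_table$variable),
                           c("variable", ats_effects())]
  rownames(test_table) <- NULL

  adjusted <- baseline_adjust(cohort, variables)
  scopes <- if (scope == "both") c("condition", "within-time") else scope
  effects_table <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(scopes, function(sc) {
      relative_effects(adjusted, v, scope = sc, conf_level = conf_level,
                       ci_method = ci_method)
    }))
  }))

  # pre/post CI-disjointness at each time level, per variable and scope
  prepost_pairs <- cbind(paste0(design_levels$time, ":pre"),
                         paste0(design_levels$time, ":post"))
  flags <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(scopes, function(sc) {
      eff <- effects_table[effects_table$variable == v &
                             effects_table$scope == sc, ]
      fl <- ci_overlap_significance(eff, pairs = prepost_pairs)$pairs
      cbind(variable = v, scope = sc, fl)
    }))
  }))

  profile_scopes <- c("treatment-condition", "phase", "time")
  profile_data <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(profile_scopes, function(sc) {
      relative_effects(adjusted, v, scope = sc, conf_level = conf_level,
                       ci_method = ci_method)
    }))
  }))

  report <- structure(list(descriptives = descriptives,
                           test_table = test_table,
                           test_details = test_details,
                           effects_table = effects_table,
                           flags = flags,
                           profile_data = profile_data),
                      class = "cryohrv_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir, seed = seed, conf_level = conf_level,
                 ci_method = ci_method, scope = scope)
  }
  report
}

#' @noRd
write_report <- function(report, out_dir, seed = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("descriptives", "test_table", "test_details",
               "effects_table", "flags", "profile_data")) {
    utils::write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  settings <- list(...)
  log_lines <- c(
    paste0("cryohrv ", as.character(utils::packageVersion("cryohrv"))),
    paste0("R ", paste(R.version$major, R.version$minor, sep = ".")),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    vapply(names(settings), function(k) {
      paste0(k, ": ", paste(settings[[k]], collapse = ",")) },
      character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.cryohrv_report <- function(x, ...) {
  cat("Cold-stimulation HRV analysis report\n")
  cat(sprintf("  variables: %s\n",
              paste(x$test_table$variable, collapse = ", ")))
  cat("  ANOVA-type test p-values:\n")
  tt <- x$test_table
  tt[, -1] <- lapply(tt[, -1], function(p) sprintf("%.3f", p))
  print(tt, row.names = FALSE)
  n_disj <- sum(x$flags$disjoint)
  cat(sprintf("  pre/post pairs with disjoint CIs: %d of %d\n",
              n_disj, nrow(x$flags)))
  invisible(x)
}
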