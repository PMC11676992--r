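# The Autonomic Nervous System Index (ANSI): a single composite,
# percentile-ranked proxy of cardiac autonomic control, built in three
# steps: (1) percentile-rank (PR) the three informative inputs — mean RR,
# RR variance, and the orthostatic change in normalized LF power — within
# age-by-sex classes, which removes age and sex bias; (2) draw the three
# PRs as a radar triangle and take its area as a unitary summary; (3) PR
# the areas over the whole reference population to land on a 0-100 scale
# where higher means better autonomic control.

#' Percentile-rank transformation with mid-ranks
#'
#' Maps each value to `100 * (midrank - 0.5) / n` computed within its group
#' (a Hazen-type plotting position). Ties share their mid-rank, a singleton
#' group maps to 50, and the transform never attains 0 or 100 on finite
#' data. `NA` values are excluded from ranking and returned as `NA`.
#'
#' @param values numeric vector.
#' @param group optional group labels (same length); `NULL` ranks all
#'   values together.
#' @return numeric vector of percentiles in (0, 100), aligned with input.
#' @export
#' @examples
#' percentile_rank(c(10, 20, 30, 40))  # 12.5 37.5 62.5 87.5
#' percentile_rank(c(5, 5, 9))         # 33.33 33.33 83.33
percentile_rank <- function(values, group = NULL) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (is.null(group)) group <- rep(1L, length(values))
  if (length(group) != length(values)) {
    stop("'group' must match the length of 'values'", call. = FALSE)
  }
  out <- rep(NA_real_, length(values))
  for (g in unique(group)) {
    idx <- which(group == g & !is.na(values))
    if (length(idx) == 0L) {
      stop("group '", g, "' has no non-missing values", call. = FALSE)
    }
    r <- rank(values[idx], ties.method = "average")
    out[idx] <- 100 * (r - 0.5) / length(idx)
  }
  out
}

# PR of external values against a reference sample, consistent with
# percentile_rank(): equivalent to inserting x into the reference and
# taking its mid-rank position there.
#' @noRd
percentile_rank_against <- function(x, reference) {
  reference <- reference[!is.na(reference)]
  if (length(reference) == 0L) stop("empty reference set", call. = FALSE)
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    below <- sum(reference < xi)
    ties <- sum(reference == xi)
    100 * (below + ties / 2 + 0.5) / (length(reference) + 1)
  }, numeric(1))
}

#' Age-by-sex classes
#'
#' Assigns each subject to a half-open decade-by-sex class (by default
#' `[20,30), [30,40), ... [60,70)` crossed with sex). Every subject must
#' map to exactly one class.
#'
#' @param age numeric ages in years.
#' @param sex character/factor sex labels.
#' @param age_breaks increasing break points of the half-open age bins.
#' @return a factor of class labels such as `"F:[40,50)"`.
#' @export
age_sex_class <- function(age, sex, age_breaks = seq(20, 70, by = 10)) {
  bin <- cut(age, breaks = age_breaks, right = FALSE,
             include.lowest = FALSE)
  if (anyNA(bin) | anyNA(sex)) {
    bad <- which(is.na(bin) | is.na(sex))
    stop("age/sex outside the class scheme for row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (ages must lie in [", age_breaks[1], ", ",
         age_breaks[length(age_breaks)], "))", call. = FALSE)
  }
  factor(paste0(as.character(sex), ":", as.character(bin)))
}

#' Radar-triangle area of three percentile ranks
#'
#' The three PRs are laid out as distances from the origin along three
#' radar axes 120 degrees apart; the enclosed triangle has area
#' `(sqrt(3)/4) * (a*b + b*c + c*a)`. The formula is symmetric, so the
#' ordering of the three axes is immaterial.
#'
#' @param pr_a,pr_b,pr_c percentiles in `[0, 100]` (vectorized).
#' @return triangle areas (percentile^2 units).
#' @export
#' @examples
#' triangle_area(100, 100, 100)  # (sqrt(3)/4) * 30000
triangle_area <- function(pr_a, pr_b, pr_c) {
  vals <- cbind(pr_a, pr_b, pr_c)
  if (any(!is.na(vals) & (vals < 0 | vals > 100))) {
    stop("percentile ranks must lie in [0, 100]", call. = FALSE)
  }
  (sqrt(3) / 4) * (pr_a * pr_b + pr_b * pr_c + pr_c * pr_a)
}

#' Compute the ANSI for every row of a cohort table
#'
#' Applies the two-stage percentile-rank construction to each
#' subject-occasion row: first-stage PRs of `rr_mean`, `rr_tp` and
#' `delta_lfnu` within the row's age-by-sex class (over the ranking
#' population), then the radar-triangle area, then a second-stage PR of the
#' areas over the whole ranking population. By default the cohort itself is
#' the ranking population; an external normative table can be supplied
#' instead.
#'
#' @param cohort a cohort `data.frame` with columns `age`, `sex` and the
#'   three input variables.
#' @param inputs names of the three input columns.
#' @param age_breaks passed to [age_sex_class()].
#' @param reference optional external reference population: a `data.frame`
#'   with columns `sex, age, variable, value` where `variable` covers the
#'   three inputs (first stage) and optionally `"area"` (second stage;
#'   otherwise areas are ranked within the cohort).
#' @return a `data.frame` aligned with `cohort` rows: `subject_id` (if
#'   present), first-stage PRs (`pr_rr`, `pr_var`, `pr_dlfnu`), `area` and
#'   `ansi`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7), add_ansi = FALSE)
#' res <- compute_ansi(coh)
#' range(res$ansi)  # strictly inside (0, 100)
compute_ansi <- function(cohort,
                         inputs = c("rr_mean", "rr_tp", "delta_lfnu"),
                         age_breaks = seq(20, 70, by = 10),
                         reference = NULL) {
  stopifnot(is.data.frame(cohort), length(inputs) == 3L)
  miss <- setdiff(c("age", "sex", inputs), names(cohort))
  if (length(miss)) stop("cohort is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cls <- age_sex_class(cohort$age, cohort$sex, age_breaks = age_breaks)
  singletons <- names(which(table(cls) == 1L))
  if (length(singletons) && is.null(reference)) {
    warning("age-by-sex class(es) with a single member (percentile rank ",
            "degenerates to 50): ", paste(singletons, collapse = ", "),
            call. = FALSE)
  }
  pr <- matrix(NA_real_, nrow(cohort), 3L)
  if (is.null(reference)) {
    for (j in 1:3) pr[, j] <- percentile_rank(cohort[[inputs[j]]],
                                              group = cls)
  } else {
    stopifnot(all(c("sex", "age", "variable", "value") %in%
                    names(reference)))
    ref_cls <- age_sex_class(reference$age, reference$sex,
                             age_breaks = age_breaks)
    for (j in 1:3) {
      for (g in unique(cls)) {
        idx <- which(cls == g)
        ref_vals <- reference$value[ref_cls == g &
                                      reference$variable == inputs[j]]
        if (length(ref_vals) == 0L) {
          stop("reference population has no values for variable '",
               inputs[j], "' in class ", g, call. = FALSE)
        }
        pr[idx, j] <- percentile_rank_against(cohort[[inputs[j]]][idx],
                                              ref_vals)
      }
    }
  }
  area <- triangle_area(pr[, 1], pr[, 2], pr[, 3])
  if (!is.null(reference) && "area" %in% reference$variable) {
    ansi <- percentile_rank_against(area,
                                    reference$value[reference$variable ==
                                                      "area"])
  } else {
    ansi <- percentile_rank(area)
  }
  out <- data.frame(pr_rr = pr[, 1], pr_var = pr[, 2], pr_dlfnu = pr[, 3],
                    area = area, ansi = ansi, stringsAsFactors = FALSE)
  if ("subject_id" %in% names(cohort)) {
    out <- cbind(cohort[, "subject_id", drop = FALSE], out)
  }
  out
}
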