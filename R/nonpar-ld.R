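# Nonparametric rank-based inference for the F1-LD-F2 longitudinal design:
# one whole-plot factor (treatment group) and two within-subject factors
# (time and phase), following the Brunner-Puri / Brunner-Domhof-Langer
# methodology. Hypotheses are formulated on the marginal distribution
# functions of the cells; they are tested with the ANOVA-type statistic
# (ATS), a quadratic form in the cell-wise mean ranks with Box-approximated
# degrees of freedom. Treatment effect sizes are summarized by relative
# effects: the probability that a randomly chosen observation from the
# pooled set falls below one from the condition of interest (ties counted
# half), 0.5 meaning no stochastic tendency.

# canonical within-subject cell order (time-major, phase-minor)
sub_plot_cells <- function() {
  c("T1.pre", "T1.post", "T10.pre", "T10.post")
}

# Reshape a long cohort into the subjects x cells value matrix used by the
# rank machinery.
#' @noRd
cell_matrix <- function(cohort, variable) {
  cohort <- check_cohort(cohort, variable)
  cohort$cell <- factor(paste(cohort$time, cohort$phase, sep = "."),
                        levels = sub_plot_cells())
  wide <- stats::reshape(
    cohort[, c("subject_id", "cell", variable)],
    idvar = "subject_id", timevar = "cell", direction = "wide")
  ord <- order(wide$subject_id)
  wide <- wide[ord, ]
  Y <- as.matrix(wide[, paste(variable, sub_plot_cells(), sep = "."),
                      drop = FALSE])
  if (anyNA(Y)) stop("missing '", variable, "' values in the design",
                     call. = FALSE)
  rownames(Y) <- wide$subject_id
  colnames(Y) <- sub_plot_cells()
  trt <- tapply(as.character(cohort$treatment), cohort$subject_id,
                function(x) x[1])
  lev <- intersect(design_levels$treatment, unique(trt))
  if (length(lev) < length(unique(trt))) lev <- sort(unique(trt))
  group <- factor(trt[rownames(Y)], levels = lev)
  list(Y = Y, group = group)
}

# effect labels in reporting order
ats_effects <- function() {
  c("Treat", "Time", "Phase", "Treat:Time", "Treat:Phase", "Time:Phase",
    "Treat:Time:Phase")
}

.proj_cache <- new.env(parent = emptyenv())

# Contrast projection matrices T = C'(CC')^- C for the seven hypotheses of
# a 2 (treatment) x 2 (time) x 2 (phase) layout, built from Kronecker
# products of centring matrices P = I - J/n and averaging rows.
#' @noRd
ats_projections <- function(a, t = 2L, s = 2L) {
  key <- paste(a, t, s, sep = ".")
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])
  cen <- function(n) diag(n) - matrix(1 / n, n, n)
  avg <- function(n) matrix(1 / n, 1L, n)
  C_list <- list(
    "Treat"            = cen(a) %x% avg(t) %x% avg(s),
    "Time"             = avg(a) %x% cen(t) %x% avg(s),
    "Phase"            = avg(a) %x% avg(t) %x% cen(s),
    "Treat:Time"       = cen(a) %x% cen(t) %x% avg(s),
    "Treat:Phase"      = cen(a) %x% avg(t) %x% cen(s),
    "Time:Phase"       = avg(a) %x% cen(t) %x% cen(s),
    "Treat:Time:Phase" = cen(a) %x% cen(t) %x% cen(s))
  .proj_cache[[key]] <- lapply(C_list, function(C) {
    # Moore-Penrose inverse of the (symmetric) CC' via eigendecomposition
    CtC <- C %*% t(C)
    e <- eigen(CtC, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    inv <- e$vectors[, pos, drop = FALSE] %*%
      diag(1 / e$values[pos], sum(pos)) %*%
      t(e$vectors[, pos, drop = FALSE])
    t(C) %*% inv %*% C
  })
  .proj_cache[[key]]
}

# Core ATS computation on a subjects x cells matrix.
#' @noRd
ats_engine <- function(Y, group, effects = ats_effects()) {
  d <- ncol(Y)
  N <- nrow(Y)
  M <- N * d
  a <- nlevels(group)
  n_g <- tabulate(group)
  if (any(n_g < 2L)) {
    stop("each treatment group needs at least 2 subjects", call. = FALSE)
  }
  vals <- as.vector(Y)
  if (stats::var(vals) == 0) {
    stop("zero total variance: all observations are tied", call. = FALSE)
  }
  R <- matrix(rank(vals, ties.method = "average"), N, d)
  U <- (R - 0.5) / M                     # normalized mid-rank placements

  p_hat <- numeric(a * d)                # group-major cell relative effects
  V <- matrix(0, a * d, a * d)           # N * blockdiag(S_g / n_g)
  for (g in seq_len(a)) {
    idx <- which(as.integer(group) == g)
    block <- (g - 1L) * d + seq_len(d)
    p_hat[block] <- colMeans(U[idx, , drop = FALSE])
    S_g <- stats::cov(U[idx, , drop = FALSE])
    V[block, block] <- N * S_g / n_g[g]
  }

  Ts <- ats_projections(a)[effects]
  res <- lapply(effects, function(eff) {
    T_mat <- Ts[[eff]]
    TV <- T_mat %*% V
    tr_TV <- sum(diag(TV))
    qform <- N * drop(t(p_hat) %*% T_mat %*% p_hat)
    if (tr_TV <= 1e-14 * sum(diag(V))) {
      # estimated variance vanishes in the contrast directions: the effect
      # is either exactly absent (quadratic form 0) or deterministic
      stat <- if (qform <= 1e-14) 0 else Inf
      return(data.frame(effect = eff, statistic = stat, df_num = NA_real_,
                        df_den = NA_real_,
                        p_value = if (is.finite(stat)) 1 else 0,
                        stringsAsFactors = FALSE))
    }
    stat <- qform / tr_TV
    f <- tr_TV^2 / sum(diag(TV %*% TV))
    # Box approximation of the denominator df, assembled from the
    # group-wise covariance blocks (Satterthwaite-type small-sample
    # correction; tends to infinity with the group sizes)
    denom <- 0
    for (g in seq_len(a)) {
      block <- (g - 1L) * d + seq_len(d)
      tr_g <- sum(diag(T_mat[block, block, drop = FALSE] %*%
                         V[block, block, drop = FALSE]))
      denom <- denom + tr_g^2 / (n_g[g] - 1)
    }
    f0 <- if (denom > 0) tr_TV^2 / denom else Inf
    p <- stats::pf(stat, f, f0, lower.tail = FALSE)
    data.frame(effect = eff, statistic = stat, df_num = f, df_den = f0,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' ANOVA-type tests for the F1-LD-F2 design
#'
#' Tests the seven hypotheses of the 2 (treatment, whole-plot) x 2 (time) x
#' 2 (phase) longitudinal layout — three main effects, three first-order
#' interactions and the second-order interaction — formulated on the
#' marginal distribution functions of the cells. All observations are
#' pooled and mid-ranked; the ANOVA-type statistic is a quadratic form in
#' the cell-wise mean ranks with an estimated covariance that respects
#' within-subject dependence across the four cells and independence across
#' subjects. Both degrees of freedom use Box-type approximations: the
#' numerator df from the full covariance estimate, the denominator df
#' assembled from the group-wise covariance blocks (a Satterthwaite-style
#' small-sample correction that grows without bound with the group sizes,
#' recovering the large-sample chi-square-per-df reference).
#'
#' @param cohort a complete long-format cohort `data.frame`.
#' @param variable name of the variable column to test.
#' @return a `data.frame` with one row per effect: `effect`, `statistic`,
#'   `df_num`, `df_den` (possibly `Inf`) and `p_value`.
#' @references Brunner, E., Domhof, S., Langer, F. (2002) Nonparametric
#'   Analysis of Longitudinal Data in Factorial Experiments. Wiley.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 3))
#' anova_type_tests(coh, "rr_mean")
anova_type_tests <- function(cohort, variable) {
  cm <- cell_matrix(cohort, variable)
  out <- ats_engine(cm$Y, cm$group)
  out$variable <- variable
  out[, c("variable", "effect", "statistic", "df_num", "df_den", "p_value")]
}

#' Baseline adjustment of a longitudinal variable
#'
#' Puts all subjects on the same footing by subtracting each subject's
#' baseline (time = T1, phase = pre) value from all four of their
#' measurements: `X~ = X - x(T1, pre)`. After adjustment every subject's
#' T1-pre value is exactly 0, so estimated treatment-wise relative effects
#' coincide across groups at T1-pre.
#'
#' @param cohort a complete long-format cohort `data.frame`.
#' @param variables variable column name(s) to adjust (default: all
#'   analysis variables present).
#' @return the cohort with the named columns replaced by adjusted values.
#' @export
baseline_adjust <- function(cohort,
                            variables = intersect(hrv_variables(),
                                                  names(cohort))) {
  cohort <- check_cohort(cohort)
  base_rows <- cohort$time == "T1" & cohort$phase == "pre"
  for (v in variables) {
    if (!v %in% names(cohort)) {
      stop("variable '", v, "' not found in cohort", call. = FALSE)
    }
    base <- cohort[[v]][base_rows]
    names(base) <- cohort$subject_id[base_rows]
    missing_subj <- setdiff(unique(cohort$subject_id), names(base))
    if (length(missing_subj) || anyNA(base)) {
      bad <- c(missing_subj, names(base)[is.na(base)])
      stop("missing T1-pre value of '", v, "' for subject(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cohort[[v]] <- cohort[[v]] - base[as.character(cohort$subject_id)]
  }
  cohort
}

# normalized placement of each pooled value w.r.t. the condition sample:
# F_c(x) = (#{c-values < x} + 0.5 * #{c-values = x}) / n_c
#' @noRd
placement_cdf <- function(values, cond_values) {
  n_c <- length(cond_values)
  vapply(values, function(x) {
    (sum(cond_values < x) + 0.5 * sum(cond_values == x)) / n_c
  }, numeric(1))
}

#' Relative effects of design conditions with confidence intervals
#'
#' Estimates, for each condition in the chosen scope, the probability that
#' an observation drawn at random from the pooled set is smaller than one
#' from the condition (ties counted half): `p_c = (mean mid-rank in c -
#' 0.5) / M`. Values above 0.5 mean the condition tends to larger values
#' than the pooled set. Confidence intervals use the asymptotic normal
#' approximation with a variance assembled from subject-level contributions
#' to the rank statistic (subjects are the independent units; all of a
#' subject's observations enter their contribution), clipped to `[0, 1]`;
#' a logit-scale alternative is available.
#'
#' Scopes: `"condition"` pools all observations and contrasts the four
#' time-by-phase cells; `"treatment-condition"` contrasts the eight
#' treatment-by-time-by-phase cells; `"phase"` and `"time"` contrast the
#' two marginal levels; `"within-time"` ranks each time level separately
#' and contrasts pre vs post inside it (so each pre/post pair of estimates
#' sums to 1).
#'
#' @param cohort a complete long-format cohort `data.frame` (typically
#'   baseline-adjusted, see [baseline_adjust()]).
#' @param variable variable column to analyze.
#' @param scope one of `"condition"`, `"within-time"`, `"phase"`,
#'   `"time"`, `"treatment-condition"`.
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"normal"` (estimate scale) or `"logit"`.
#' @return a `data.frame` with `variable`, `scope`, `condition`,
#'   `estimate`, `ci_lower`, `ci_upper`, `n` (observations in the
#'   condition).
#' @export
#' @examples
#' coh <- baseline_adjust(generate_cohort(cohort_config(seed = 3)))
#' relative_effects(coh, "rr_mean", scope = "within-time")
relative_effects <- function(cohort, variable,
                             scope = c("condition", "within-time", "phase",
                                       "time", "treatment-condition"),
                             conf_level = 0.95,
                             ci_method = c("normal", "logit")) {
  scope <- match.arg(scope)
  ci_method <- match.arg(ci_method)
  cohort <- check_cohort(cohort, variable)
  if (min(table(tapply(as.character(cohort$treatment), cohort$subject_id,
                       `[`, 1L))) < 2) {
    stop("each treatment group needs at least 2 subjects", call. = FALSE)
  }

  if (scope == "within-time") {
    out <- do.call(rbind, lapply(design_levels$time, function(tl) {
      sub <- cohort[cohort$time == tl, ]
      re <- relative_effects_pooled(sub, variable,
                                    cond = paste0(tl, ":", sub$phase),
                                    conf_level = conf_level,
                                    ci_method = ci_method)
      re
    }))
  } else {
    cond <- switch(scope,
      "condition" = paste0(cohort$time, ":", cohort$phase),
      "phase" = as.character(cohort$phase),
      "time" = as.character(cohort$time),
      "treatment-condition" = paste0(cohort$treatment, ":", cohort$time,
                                     ":", cohort$phase))
    out <- relative_effects_pooled(cohort, variable, cond,
                                   conf_level = conf_level,
                                   ci_method = ci_method)
  }
  out$variable <- variable
  out$scope <- scope
  rownames(out) <- NULL
  out[, c("variable", "scope", "condition", "estimate", "ci_lower",
          "ci_upper", "n")]
}

# relative effects of conditions against the pooled set of the rows given
#' @noRd
relative_effects_pooled <- function(cohort, variable, cond, conf_level,
                                    ci_method) {
  x <- cohort[[variable]]
  subj <- as.character(cohort$subject_id)
  M <- length(x)
  R <- rank(x, ties.method = "average")
  H <- (R - 0.5) / M                 # pooled normalized distribution at x
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  all_tied <- length(unique(x)) == 1L
  if (all_tied) {
    warning("all observations tied: relative effects degenerate to 0.5 ",
            "with zero-width intervals", call. = FALSE)
  }
  conds <- unique(cond)
  rows <- lapply(conds, function(cc) {
    in_c <- cond == cc
    n_c <- sum(in_c)
    if (n_c == 0L) stop("condition '", cc, "' has no observations",
                        call. = FALSE)
    p_hat <- mean(H[in_c])
    # subject-level linearization of p_hat:
    #   (1/n_c) sum_{i in c} [H(x_i) - p]  -  (1/M) sum_k [F_c(x_k) - q]
    Fc <- placement_cdf(x, x[in_c])
    q_hat <- mean(Fc)
    contrib <- rep(0, M)
    contrib[in_c] <- (H[in_c] - p_hat) / n_c
    contrib <- contrib - (Fc - q_hat) / M
    phi <- tapply(contrib, subj, sum)
    se <- sqrt(sum(phi^2))
    if (ci_method == "normal" || se == 0 || p_hat <= 0 || p_hat >= 1) {
      lo <- max(0, p_hat - z * se)
      hi <- min(1, p_hat + z * se)
    } else {
      eta <- stats::qlogis(p_hat)
      se_eta <- se / (p_hat * (1 - p_hat))
      lo <- stats::plogis(eta - z * se_eta)
      hi <- stats::plogis(eta + z * se_eta)
    }
    data.frame(condition = cc, estimate = p_hat, ci_lower = lo,
               ci_upper = hi, n = n_c, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Significance flags from confidence-interval overlap
#'
#' Applies the CI-overlap decision rules used with relative effects: two
#' conditions differ significantly iff their CIs are disjoint, and a single
#' condition differs from the pooled set iff its CI excludes 0.5.
#'
#' @param effects a `data.frame` from [relative_effects()]; all rows must
#'   share the same variable and scope.
#' @param pairs optional 2-column matrix/data.frame of condition label
#'   pairs to compare; default: all unordered pairs.
#' @return a list with `pairs` (condition_1, condition_2, `disjoint`
#'   logical) and `vs_pooled` (condition, `excludes_half` logical).
#' @export
ci_overlap_significance <- function(effects, pairs = NULL) {
  stopifnot(is.data.frame(effects),
            all(c("condition", "estimate", "ci_lower", "ci_upper") %in%
                  names(effects)))
  for (col in intersect(c("variable", "scope"), names(effects))) {
    if (length(unique(effects[[col]])) > 1L) {
      stop("effects mix different values of '", col,
           "'; flag one variable/scope at a time", call. = FALSE)
    }
  }
  if (is.null(pairs)) {
    if (nrow(effects) >= 2L) {
      pairs <- t(utils::combn(effects$condition, 2L))
    } else {
      pairs <- matrix(character(0), 0L, 2L)
    }
  }
  pairs <- as.matrix(pairs)
  get_row <- function(cc) {
    i <- match(cc, effects$condition)
    if (is.na(i)) stop("unknown condition '", cc, "'", call. = FALSE)
    effects[i, ]
  }
  pair_flags <- if (nrow(pairs)) {
    data.frame(
      condition_1 = pairs[, 1], condition_2 = pairs[, 2],
      disjoint = vapply(seq_len(nrow(pairs)), function(i) {
        a <- get_row(pairs[i, 1])
        b <- get_row(pairs[i, 2])
        a$ci_upper < b$ci_lower || b$ci_upper < a$ci_lower
      }, logical(1)), stringsAsFactors = FALSE)
  } else {
    data.frame(condition_1 = character(0), condition_2 = character(0),
               disjoint = logical(0))
  }
  vs_pooled <- data.frame(
    condition = effects$condition,
    excludes_half = effects$ci_upper < 0.5 | effects$ci_lower > 0.5,
    stringsAsFactors = FALSE)
  list(pairs = pair_flags, vs_pooled = vs_pooled)
}

#' Monte-Carlo rejection rate of an ANOVA-type test
#'
#' Simulation harness for size and power studies of the rank-based tests on
#' the two-arm F1-LD-F2 layout. Each replicate draws iid standard-normal
#' observations for every subject-by-cell entry, adds `phase_effect` to the
#' post-phase cells, runs the ANOVA-type test and records whether the
#' chosen effect's p-value is at or below `alpha`.
#'
#' @param n_reps number of simulated cohorts.
#' @param phase_effect additive shift of the post cells (0 = global null).
#' @param n_treat1,n_treat2 subjects per arm.
#' @param effect which effect's p-value to monitor (see [anova_type_tests()]
#'   effect labels).
#' @param alpha nominal significance level.
#' @param seed integer seed.
#' @return the rejection proportion across replicates.
#' @export
#' @examples
#' simulate_rejection_rate(50, seed = 1)  # near 0.05 under the null
simulate_rejection_rate <- function(n_reps, phase_effect = 0,
                                    n_treat1 = 15, n_treat2 = 8,
                                    effect = "Phase", alpha = 0.05,
                                    seed = NULL) {
  stopifnot(effect %in% ats_effects())
  N <- n_treat1 + n_treat2
  group <- factor(rep(design_levels$treatment, c(n_treat1, n_treat2)),
                  levels = design_levels$treatment)
  post_cols <- grepl("post", sub_plot_cells())
  with_seed(seed, {
    rej <- vapply(seq_len(n_reps), function(r) {
      Y <- matrix(stats::rnorm(N * 4L), N, 4L,
                  dimnames = list(sprintf("S%03d", seq_len(N)),
                                  sub_plot_cells()))
      Y[, post_cols] <- Y[, post_cols] + phase_effect
      res <- ats_engine(Y, group)
      res$p_value[res$effect == effect] <= alpha
    }, logical(1))
    mean(rej)
  })
}
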