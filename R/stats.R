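# Group-comparison layer: one-way / two-way / repeated-measures ANOVA with
# Tukey HSD post-hoc correction, and the unpaired two-group t-test, operating
# on long-format ROI tables (one row per animal x timepoint x hemisphere).

#' Validate a long-format group table
#'
#' @param df A data.frame with a numeric response column and any of the
#'   design columns `animal_id`, `group_label`, `timepoint_label`,
#'   `hemisphere_label`.
#' @param response Name of the response column (default `"value"`).
#' @return The validated data.frame, classed `group_table`.
#' @export
group_table <- function(df, response = "value") {
  if (!is.data.frame(df)) stop("group_table: expected a data.frame")
  if (!response %in% names(df))
    stop("group_table: missing response column `", response, "`")
  if (!all(is.finite(df[[response]])))
    stop("group_table: non-finite responses")
  keys <- intersect(c("animal_id", "group_label", "timepoint_label",
                      "hemisphere_label"), names(df))
  if (length(keys) && anyDuplicated(df[keys]))
    stop("group_table: duplicate (", paste(keys, collapse = ", "), ") rows")
  class(df) <- unique(c("group_table", class(df)))
  df
}

p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

# Effect table from a fitted lm, with the degenerate-data conventions:
# an effect with (numerically) zero sum of squares has F = 0, p = 1; a
# nonzero effect over a zero residual mean square has F = Inf, p = 0.
extract_effects <- function(fit) {
  # anova.lm warns on a numerically perfect fit; that degenerate case is
  # handled explicitly below
  a <- suppressWarnings(stats::anova(fit))
  res <- rownames(a) == "Residuals"
  eff <- a[!res, , drop = FALSE]
  Fv <- eff$`F value`; pv <- eff$`Pr(>F)`
  # degeneracy threshold relative to the response's own scale, so that a
  # constant response registers as zero variation rather than as 0/0
  scale <- max(sum(a$`Sum Sq`), sum(stats::fitted(fit)^2),
               .Machine$double.xmin)
  zero_eff <- eff$`Sum Sq` <= 1e-12 * scale
  Fv[zero_eff] <- 0; pv[zero_eff] <- 1
  if (a$`Sum Sq`[res] <= 1e-12 * scale) {
    Fv[!zero_eff] <- Inf; pv[!zero_eff] <- 0
  }
  list(effects = data.frame(term = trimws(rownames(eff)), df = eff$Df,
                            F = Fv, p = pv, row.names = NULL),
       df_residual = a$Df[res],
       ms_residual = a$`Sum Sq`[res] / a$Df[res])
}

new_anova_result <- function(fit, data, response, factors, kind) {
  ex <- extract_effects(fit)
  structure(list(effects = ex$effects, df_residual = ex$df_residual,
                 ms_residual = ex$ms_residual, model = fit, data = data,
                 response = response, factors = factors, kind = kind,
                 posthoc = NULL),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> ", x$kind, " (", x$response, " ~ ",
      paste(x$factors, collapse = " * "), ")\n", sep = "")
  ef <- x$effects
  ef$signif <- p_stars(ef$p)
  print(ef, digits = 4)
  if (!is.null(x$posthoc)) {
    cat("Tukey HSD post-hoc:\n")
    ph <- x$posthoc
    ph$signif <- p_stars(ph$p_adjusted)
    print(ph, digits = 4)
  }
  invisible(x)
}

check_factor_col <- function(df, nm) {
  if (!nm %in% names(df))
    stop("missing design column `", nm, "`")
  f <- factor(df[[nm]])
  if (nlevels(f) < 2L)
    stop("factor `", nm, "` needs at least 2 levels")
  f
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `response ~ A * B` (e.g. hemisphere x timepoint) and reports both
#' main effects and the interaction, the design used to test whether the
#' lactate-to-pyruvate ratio differs between injured and contralateral
#' hemispheres over time.
#'
#' @param table A long-format data.frame (see [group_table()]).
#' @param factors Character vector of the two factor column names; default
#'   `c("hemisphere_label", "timepoint_label")`.
#' @param response Response column name.
#' @return An `anova_result` with one row per effect (A, B, A:B).
#' @export
two_way_anova <- function(table,
                          factors = c("hemisphere_label", "timepoint_label"),
                          response = "value") {
  table <- group_table(as.data.frame(table), response)
  if (length(factors) != 2L) stop("two_way_anova: need exactly two factors")
  f1 <- check_factor_col(table, factors[1L])
  f2 <- check_factor_col(table, factors[2L])
  cells <- table(f1, f2)
  bad <- which(cells < 2L, arr.ind = TRUE)
  if (nrow(bad))
    stop("two_way_anova: cells with fewer than 2 observations: ",
         paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1L]],
                       colnames(cells)[bad[, 2L]]), collapse = ", "))
  dat <- data.frame(.y = table[[response]], .f1 = f1, .f2 = f2)
  fit <- stats::lm(.y ~ .f1 * .f2, data = dat)
  res <- new_anova_result(fit, table, response, factors, "two-way ANOVA")
  res$effects$term <- sub("^\\.f1:\\.f2$", paste(factors, collapse = ":"),
                          res$effects$term)
  res$effects$term <- sub("^\\.f1$", factors[1L], res$effects$term)
  res$effects$term <- sub("^\\.f2$", factors[2L], res$effects$term)
  res
}

#' One-way ANOVA
#'
#' @inheritParams two_way_anova
#' @param factor_name Single factor column name (default
#'   `"timepoint_label"`).
#' @return An `anova_result`.
#' @export
one_way_anova <- function(table, factor_name = "timepoint_label",
                          response = "value") {
  table <- group_table(as.data.frame(table), response)
  f <- check_factor_col(table, factor_name)
  cnt <- table(f)
  if (any(cnt < 2L))
    stop("one_way_anova: levels with fewer than 2 observations: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  dat <- data.frame(.y = table[[response]], .f1 = f)
  fit <- stats::lm(.y ~ .f1, data = dat)
  res <- new_anova_result(fit, table, response, factor_name, "one-way ANOVA")
  res$effects$term <- sub("^\\.f1$", factor_name, res$effects$term)
  res
}

#' Repeated-measures (within-subject) one-factor ANOVA
#'
#' Within-subject ANOVA with the animal as a blocking factor: fits
#' `response ~ within + subject` on a complete balanced panel (every animal
#' observed exactly once at every level) and tests the within factor against
#' the residual (subject x level) mean square. No sphericity correction is
#' applied.
#'
#' @inheritParams two_way_anova
#' @param within Within-subject factor column (default `"timepoint_label"`).
#' @param subject Subject identifier column (default `"animal_id"`).
#' @return An `anova_result`; the within-factor row is first.
#' @export
repeated_measures_anova <- function(table, within = "timepoint_label",
                                    subject = "animal_id",
                                    response = "value") {
  table <- group_table(as.data.frame(table), response)
  fw <- check_factor_col(table, within)
  fs <- check_factor_col(table, subject)
  panel <- table(fs, fw)
  if (any(panel != 1L))
    stop("repeated_measures_anova: unbalanced panel; every animal must be ",
         "observed exactly once at every level of `", within, "`")
  dat <- data.frame(.y = table[[response]], .f1 = fw, .subj = fs)
  fit <- stats::lm(.y ~ .f1 + .subj, data = dat)
  res <- new_anova_result(fit, table, response, within,
                          "repeated-measures ANOVA")
  res$effects$term <- sub("^\\.f1$", within, res$effects$term)
  res$effects$term <- sub("^\\.subj$", subject, res$effects$term)
  res
}

#' Tukey HSD post-hoc comparisons
#'
#' Studentized-range-based adjusted p-values for all pairwise comparisons of
#' one factor's (marginal) level means, using the fitted model's residual
#' mean square and the Tukey-Kramer standard error for unequal group sizes.
#' The adjusted p-value is never smaller than the unadjusted pairwise
#' t-test p-value.
#'
#' @param result An `anova_result`.
#' @param factor_name Factor (column of the original table) whose levels to
#'   compare; defaults to the ANOVA's first factor. Pass two names to
#'   compare interaction cells.
#' @return The `anova_result` with a `posthoc` data.frame (`level_1`,
#'   `level_2`, `diff`, `q`, `p_unadjusted`, `p_adjusted`).
#' @export
tukey_hsd <- function(result, factor_name = NULL) {
  if (!inherits(result, "anova_result")) stop("tukey_hsd: expected an anova_result")
  if (is.null(factor_name)) factor_name <- result$factors[1L]
  dat <- as.data.frame(result$data)
  fl <- lapply(factor_name, function(nm) check_factor_col(dat, nm))
  f <- if (length(fl) == 1L) fl[[1L]] else interaction(fl, sep = ":")
  y <- dat[[result$response]]
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  k <- length(means)
  if (k < 2L) stop("tukey_hsd: need at least 2 level combinations")
  s2 <- result$ms_residual
  dfres <- result$df_residual
  pairs <- utils::combn(names(means), 2L)
  out <- data.frame(level_1 = pairs[1L, ], level_2 = pairs[2L, ])
  out$diff <- means[out$level_1] - means[out$level_2]
  sehalf <- sqrt(s2 * 0.5 * (1 / ns[out$level_1] + 1 / ns[out$level_2]))
  if (s2 <= 0) {
    out$q <- ifelse(abs(out$diff) > 0, Inf, 0)
    out$p_unadjusted <- ifelse(abs(out$diff) > 0, 0, 1)
    out$p_adjusted <- out$p_unadjusted
  } else {
    out$q <- abs(out$diff) / sehalf
    tstat <- abs(out$diff) / (sehalf * sqrt(2))
    out$p_unadjusted <- 2 * stats::pt(-tstat, dfres)
    out$p_adjusted <- stats::ptukey(out$q, nmeans = k, df = dfres,
                                    lower.tail = FALSE)
  }
  rownames(out) <- NULL
  result$posthoc <- out
  result
}

#' Unpaired two-group t-test
#'
#' Two-sided comparison of exactly two groups (equal-variance pooled test by
#' default, Welch optional). When both groups are constant, equal means give
#' `t = 0, p = 1` by convention.
#'
#' @inheritParams two_way_anova
#' @param group Grouping column name (default `"group_label"`).
#' @param var_equal Logical; pooled-variance test if `TRUE` (default).
#' @return A list with `statistic`, `df`, `p_value`, `mean_diff`,
#'   `group_means`.
#' @export
two_group_ttest <- function(table, group = "group_label",
                            response = "value", var_equal = TRUE) {
  table <- group_table(as.data.frame(table), response)
  f <- check_factor_col(table, group)
  if (nlevels(f) != 2L)
    stop("two_group_ttest: need exactly two groups, got ", nlevels(f))
  sp <- split(table[[response]], f)
  if (any(vapply(sp, length, integer(1)) < 2L))
    stop("two_group_ttest: each group needs n >= 2")
  v <- vapply(sp, stats::var, numeric(1))
  m <- vapply(sp, mean, numeric(1))
  if (all(v == 0)) {
    dfree <- length(table[[response]]) - 2L
    if (m[1L] == m[2L])
      return(list(statistic = 0, df = dfree, p_value = 1,
                  mean_diff = 0, group_means = m))
    return(list(statistic = sign(m[1L] - m[2L]) * Inf, df = dfree,
                p_value = 0, mean_diff = unname(m[1L] - m[2L]),
                group_means = m))
  }
  tt <- stats::t.test(sp[[1L]], sp[[2L]], var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(m[1L] - m[2L]),
       group_means = m)
}

#' Simulate a cohort-level ratio table
#'
#' Generates the long-format per-animal, per-timepoint, per-hemisphere
#' lactate-to-pyruvate ratio records of a longitudinal cohort, without going
#' through the imaging pipeline: each animal carries a Gaussian offset
#' shared by both hemispheres (between-animal variability), every record
#' gets independent Gaussian measurement noise, and the injured hemisphere
#' is elevated by a timepoint-specific percentage of the base ratio.
#' Defaults emulate a controlled-cortical-impact cohort of 10 animals
#' imaged at baseline, 12 h, 24 h, 7 d and 28 d with elevations of 0, 23,
#' 36, 37 and 15 percent; set `elevation_pct = 0` for a sham-like cohort.
#'
#' @param n_animals Number of animals.
#' @param timepoints Character vector of timepoint labels.
#' @param elevation_pct Percent elevation of the injured hemisphere at each
#'   timepoint (recycled to `length(timepoints)`).
#' @param base_ratio Contralateral mean ratio.
#' @param animal_sd Between-animal standard deviation (ratio units).
#' @param noise_sd Per-record measurement noise standard deviation.
#' @param group_label Cohort label stored in the table.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [group_table()] data.frame with columns `animal_id`,
#'   `group_label`, `timepoint_label`, `hemisphere_label`, `value`.
#' @export
simulate_ratio_table <- function(n_animals = 10L,
                                 timepoints = c("Baseline", "12h", "24h",
                                                "7d", "28d"),
                                 elevation_pct = c(0, 23, 36, 37, 15),
                                 base_ratio = 0.40,
                                 animal_sd = 0.04,
                                 noise_sd = 0.05,
                                 group_label = "CCI",
                                 seed = 1L) {
  elevation_pct <- rep_len(elevation_pct, length(timepoints))
  with_preserved_seed(seed, {
    offs <- stats::rnorm(n_animals, 0, animal_sd)
    rows <- expand.grid(hemisphere_label = c("contralateral", "injured"),
                        timepoint_label = timepoints,
                        animal_id = sprintf("%s_%02d", group_label,
                                            seq_len(n_animals)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ai <- match(rows$animal_id, unique(rows$animal_id))
    ti <- match(rows$timepoint_label, timepoints)
    inj <- rows$hemisphere_label == "injured"
    mu <- base_ratio + offs[ai] +
      ifelse(inj, base_ratio * elevation_pct[ti] / 100, 0)
    rows$group_label <- group_label
    rows$value <- mu + stats::rnorm(nrow(rows), 0, noise_sd)
    group_table(rows[, c("animal_id", "group_label", "timepoint_label",
                         "hemisphere_label", "value")])
  })
}
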