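#' Response transform for mixed modelling
#'
#' `y = log2(x + 1)`: log transform with a small constant c = 1 so that
#' zeros (below detection) map to zero. Negative inputs — possible after
#' additive batch correction — are floored at 0 here (and only here),
#' with the count recorded in the `n_floored` attribute. Base 2 is fixed
#' by the percent-difference conversion `(2^beta - 1) * 100`.
#'
#' @param x concentrations (nmol/L).
#' @return transformed vector.
#' @export
transform_response <- function(x) {
  n_floored <- sum(x < 0, na.rm = TRUE)
  out <- log2(pmax(x, 0) + 1)
  attr(out, "n_floored") <- n_floored
  out
}

#' Convert a log2 coefficient to a percent difference
#'
#' @param beta log2-scale model coefficient(s).
#' @return `(2^beta - 1) * 100`, the relative concentration difference in
#'   percent.
#' @examples
#' percent_difference(1)    # 100
#' percent_difference(-1)   # -50
#' @export
percent_difference <- function(beta) {
  (2^beta - 1) * 100
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of p-values (q-values), via
#' [stats::p.adjust()]. NAs are preserved.
#'
#' @param p vector of p-values.
#' @return BH-adjusted q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Per-lipid sex-difference mixed models
#'
#' Fits, per lipid, `log2(conc + 1) ~ sex + age + sex:age` with a random
#' intercept and a random age slope per participant (REML), on study
#' injections. Age is centred at the cohort mean so the sex coefficient
#' is the estimated female-minus-male difference at the mean age (sex
#' coded female = 1, male = 0: positive coefficients mean higher in
#' females). Singular random-slope fits are refit with a random intercept
#' only and flagged; designs with fewer than `min_timepoints_for_slope`
#' time points skip the slope from the start. Degrees of freedom use the
#' between-subject approximation `n_participants - 2` (at cohorts of
#' hundreds of participants this is indistinguishable from finer df
#' approximations); p-values are BH-adjusted across all modelled lipids.
#'
#' @param mat matrix or [abundance_matrix()] (typically batch-corrected
#'   concentrations) with study injections in rows.
#' @param manifest manifest data frame (needs `sex`, `age`,
#'   `participant_id`).
#' @param registry optional registry to annotate lipid classes.
#' @param z_scale also standardize the transformed response to unit
#'   variance (default FALSE: z-scaling would break the exactness of the
#'   percent-difference conversion).
#' @param min_timepoints_for_slope minimum time points required to
#'   attempt a random age slope (default 3).
#' @return data frame of class `sex_diff_result`: `lipid`, `class`,
#'   `beta_sex` (log2), `se`, `df`, `t`, `p`, `q`, `percent_difference`,
#'   `direction`, `random_structure`, `converged`, `message`.
#' @export
fit_sex_model <- function(mat, manifest, registry = NULL, z_scale = FALSE,
                          min_timepoints_for_slope = 3) {
  values <- if (inherits(mat, "abundance_matrix")) unclass_matrix(mat) else mat
  study <- manifest[manifest$role == "study", ]
  keep <- intersect(study$injection_id, rownames(values))
  X <- values[keep, , drop = FALSE]
  meta <- study[match(keep, study$injection_id), ]
  if (length(unique(meta$sex)) < 2) stop("both sexes must be present")
  data <- data.frame(participant = factor(meta$participant_id),
                     female = as.numeric(meta$sex == "F"),
                     age_c = meta$age - mean(meta$age))
  n_tp <- length(unique(meta$timepoint))
  try_slope <- n_tp >= min_timepoints_for_slope
  form_full <- .y ~ female * age_c + (1 + age_c | participant)
  form_red <- .y ~ female * age_c + (1 | participant)
  tmpl_full <- NULL
  tmpl_red <- NULL
  df_approx <- nlevels(data$participant) - 2

  fresh_fit <- function(formula, y) {
    sub <- data[!is.na(y), , drop = FALSE]
    sub$.y <- y[!is.na(y)]
    tryCatch(list(fit = suppressMessages(
      lmer(formula, data = sub, REML = TRUE,
           control = lmerControl(calc.derivs = FALSE))),
      ok = TRUE, message = ""),
      error = function(e) list(fit = NULL, ok = FALSE,
                               message = conditionMessage(e)))
  }

  fit_one <- function(y) {
    complete <- !anyNA(y)
    structure_used <- NA_character_
    res <- NULL
    if (try_slope) {
      if (complete) {
        res <- refit_or_fit(tmpl_full, y, form_full, data)
        if (res$ok && is.null(tmpl_full)) tmpl_full <<- res$fit
      } else {
        res <- fresh_fit(form_full, y)
      }
      structure_used <- "intercept_and_slope"
      if (!res$ok || isSingular(res$fit, tol = 1e-4)) {
        res <- NULL   # fall through to reduced model
      }
    }
    if (is.null(res)) {
      if (complete) {
        res <- refit_or_fit(tmpl_red, y, form_red, data)
        if (res$ok && is.null(tmpl_red)) tmpl_red <<- res$fit
      } else {
        res <- fresh_fit(form_red, y)
      }
      structure_used <- if (try_slope) "intercept_only(singular_slope)" else
        "intercept_only(few_timepoints)"
    }
    list(res = res, structure = structure_used)
  }

  rows <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    y <- as.numeric(transform_response(X[, j]))
    if (z_scale) y <- (y - mean(y, na.rm = TRUE)) / sd(y, na.rm = TRUE)
    if (all(is.na(y)) || sd(y, na.rm = TRUE) == 0) {
      rows[[j]] <- data.frame(beta_sex = NA_real_, se = NA_real_,
                              df = df_approx, t = NA_real_, p = NA_real_,
                              random_structure = NA_character_,
                              converged = FALSE,
                              message = "constant or all-missing response")
      next
    }
    f <- fit_one(y)
    if (!f$res$ok) {
      rows[[j]] <- data.frame(beta_sex = NA_real_, se = NA_real_,
                              df = df_approx, t = NA_real_, p = NA_real_,
                              random_structure = f$structure,
                              converged = FALSE, message = f$res$message)
      next
    }
    fit <- f$res$fit
    beta <- unname(fixef(fit)["female"])
    se <- sqrt(as.matrix(vcov(fit))["female", "female"])
    tval <- beta / se
    rows[[j]] <- data.frame(beta_sex = beta, se = se, df = df_approx,
                            t = tval, p = 2 * pt(-abs(tval), df_approx),
                            random_structure = f$structure,
                            converged = !nzchar(f$res$message),
                            message = f$res$message)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(lipid = colnames(X), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$class <- if (!is.null(registry)) {
    registry$class[match(out$lipid, registry$name)]
  } else NA_character_
  out$q <- bh_adjust(out$p)
  out$percent_difference <- percent_difference(out$beta_sex)
  out$direction <- ifelse(is.na(out$beta_sex), NA_character_,
                          ifelse(out$beta_sex > 0, "higher-in-female",
                                 "higher-in-male"))
  out <- out[, c("lipid", "class", "beta_sex", "se", "df", "t", "p", "q",
                 "percent_difference", "direction", "random_structure",
                 "converged", "message")]
  class(out) <- c("sex_diff_result", "data.frame")
  out
}
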