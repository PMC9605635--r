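# Downstream prognostic pipeline on a cohort feature table: PET-MRI feature
# correlation, median dichotomization with group tests, ROC cutoff
# selection, Kaplan-Meier/log-rank and Cox proportional-hazards models.

endpoint_columns <- function(data, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  time_col <- paste0(endpoint, "_months")
  event_col <- paste0(endpoint, "_event")
  if (!all(c(time_col, event_col) %in% names(data))) {
    stop("cohort table lacks columns ", time_col, "/", event_col,
         call. = FALSE)
  }
  list(time = data[[time_col]], event = as.logical(data[[event_col]]),
       endpoint = endpoint)
}

#' Pairwise Pearson correlation of PET and MRI features
#'
#' Pearson r and two-sided p for every (PET, MRI) feature pair over the
#' patients with both values present; pairs with `r > robust_r` and
#' `p < alpha` are flagged robust. Constant columns yield `NA` correlations.
#'
#' @param data Cohort feature table (one row per patient).
#' @param pet_vars,mri_vars Character vectors of column names.
#' @param robust_r,alpha Robustness thresholds (defaults 0.75, 0.05).
#' @return A tibble: `pet_var, mri_var, n, r, p, robust`.
#' @export
correlate_features <- function(data, pet_vars, mri_vars,
                               robust_r = 0.75, alpha = 0.05) {
  stopifnot(all(pet_vars %in% names(data)), all(mri_vars %in% names(data)))
  grid <- tidyr::expand_grid(pet_var = pet_vars, mri_var = mri_vars)
  res <- purrr::pmap(grid, function(pet_var, mri_var) {
    x <- data[[pet_var]]; y <- data[[mri_var]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(n = n, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  dplyr::mutate(out,
                robust = !is.na(.data$r) & .data$r > robust_r & .data$p < alpha)
}

#' Median dichotomization of survival with per-feature group tests
#'
#' Splits patients at the median of the endpoint time (`<=` median vs `>`,
#' ties at the median going to the low group) and compares each feature
#' between groups with a two-sample t-test (Welch by default). Normality of
#' each feature is pre-checked with a Kolmogorov-Smirnov test against a
#' normal with the feature's moments and flagged, not enforced. Features
#' constant across patients give `NA` p-values, reported as such.
#'
#' @param data Cohort feature table.
#' @param endpoint `"os"` or `"pfs"`.
#' @param features Character vector of feature columns.
#' @param var_equal Pooled-variance t-test instead of Welch (default FALSE).
#' @return A tibble with one row per feature: group sizes, means, SDs, the
#'   t-test p, and the KS normality p.
#' @export
dichotomize_and_test <- function(data, endpoint = c("os", "pfs"), features,
                                 var_equal = FALSE) {
  ep <- endpoint_columns(data, endpoint)
  med <- stats::median(ep$time)
  lo <- ep$time <= med
  if (sum(lo) < 2 || sum(!lo) < 2) {
    stop("median split leaves a group with fewer than 2 patients",
         call. = FALSE)
  }
  purrr::map_dfr(features, function(f) {
    x <- data[[f]]
    ks_p <- tryCatch(
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value),
      error = function(e) NA_real_)
    t_p <- if (stats::sd(x) == 0 ||
               (stats::sd(x[lo]) == 0 && stats::sd(x[!lo]) == 0)) {
      NA_real_
    } else {
      stats::t.test(x[lo], x[!lo], var.equal = var_equal)$p.value
    }
    tibble::tibble(
      feature = f, endpoint = ep$endpoint, split_months = med,
      n_low = sum(lo), n_high = sum(!lo),
      mean_low = mean(x[lo]), sd_low = stats::sd(x[lo]),
      mean_high = mean(x[!lo]), sd_high = stats::sd(x[!lo]),
      p = t_p, normality_p = ks_p
    )
  })
}

#' ROC curve and Youden-optimal cutoff for one feature
#'
#' Builds the empirical ROC of a continuous feature against a binary class
#' (higher feature values predict the positive class), with AUC by the
#' trapezoidal rule and the operating cutoff maximising Youden's J
#' (sensitivity + specificity - 1); J ties resolve to the lowest cutoff.
#' Candidate cutoffs are midpoints between consecutive distinct feature
#' values (plus open ends), a voxel classified positive when
#' `feature >= cutoff`.
#'
#' @param data Cohort feature table.
#' @param class_col Name of a logical column: the positive class (e.g.
#'   survival below the median).
#' @param feature Name of the feature column.
#' @param endpoint Optional endpoint tag carried into the result.
#' @return A one-row tibble of class `roc_result`: `variable, cutoff, auc,
#'   sensitivity, specificity, endpoint`, with the full ROC curve in
#'   `attr(, "curve")`.
#' @export
roc_cutoff <- function(data, class_col, feature, endpoint = NA_character_) {
  cls <- as.logical(data[[class_col]])
  x <- data[[feature]]
  ok <- is.finite(x) & !is.na(cls)
  cls <- cls[ok]; x <- x[ok]
  n_pos <- sum(cls); n_neg <- sum(!cls)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be non-empty for a ROC curve", call. = FALSE)
  }
  uv <- sort(unique(x))
  cuts <- c(uv[1] - 1,
            if (length(uv) > 1) (uv[-1] + uv[-length(uv)]) / 2,
            uv[length(uv)] + 1)
  sens <- vapply(cuts, function(ct) sum(cls & x >= ct) / n_pos, numeric(1))
  spec <- vapply(cuts, function(ct) sum(!cls & x < ct) / n_neg, numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(cuts[best])]
  out <- tibble::tibble(
    variable = feature, cutoff = cuts[best], auc = auc,
    sensitivity = sens[best], specificity = spec[best],
    endpoint = endpoint
  )
  attr(out, "curve") <- tibble::tibble(cutoff = cuts, sensitivity = sens,
                                       specificity = spec)
  class(out) <- c("roc_result", class(out))
  out
}

#' Kaplan-Meier curves and log-rank test between two groups
#'
#' Kaplan-Meier survival estimates per group with the two-sided log-rank
#' (Mantel-Cox) p-value.
#'
#' @param data Cohort table.
#' @param endpoint `"os"` or `"pfs"`.
#' @param group Name of a logical/factor column defining the groups.
#' @return A `km_result`: list with `curves` (tidy tibble of the step
#'   curves), `logrank_p`, `medians` (per-group median survival), `endpoint`
#'   and the underlying `survfit` object.
#' @export
km_logrank <- function(data, endpoint = c("os", "pfs"), group) {
  ep <- endpoint_columns(data, endpoint)
  grp <- data[[group]]
  if (length(unique(grp[!is.na(grp)])) < 2) {
    stop("grouping column must have at least two non-empty levels",
         call. = FALSE)
  }
  df <- data.frame(time = ep$time, event = as.integer(ep$event),
                   grp = factor(grp))
  if (any(tapply(df$event, df$grp, sum) == 0)) {
    stop("each group needs at least one observed event for the log-rank test",
         call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  sm <- summary(fit)
  curves <- tibble::tibble(
    group = sub("^grp=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv, lower = sm$lower, upper = sm$upper
  )
  med <- summary(fit)$table
  medians <- tibble::tibble(
    group = sub("^grp=", "", rownames(med)),
    n = med[, "records"], events = med[, "events"],
    median_months = med[, "median"]
  )
  structure(list(curves = curves, logrank_p = p, medians = medians,
                 endpoint = ep$endpoint, fit = fit),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result %s> log-rank p = %.4g\n", toupper(x$endpoint),
              x$logrank_p))
  print(x$medians)
  invisible(x)
}

#' @export
tidy.km_result <- function(x, ...) x$curves

#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(endpoint = x$endpoint, logrank_p = x$logrank_p,
                 n_groups = nrow(x$medians))
}

#' Univariate and multivariate Cox proportional-hazards screening
#'
#' Fits one Cox model per univariate variable and a single multivariate
#' model, with Efron handling of ties. Variables listed in `per_tenth`
#' (default `"sphericity"`) enter divided by 0.1 so their hazard ratio is
#' expressed per tenth of increase. Non-convergence is reported per model
#' in the `converged` column, never fatal to the run. A warning (not an
#' error) is issued when there are fewer than 10 events per fitted
#' covariate.
#'
#' @param data Cohort table.
#' @param endpoint `"os"` or `"pfs"`.
#' @param univariate Character vector of variables screened one at a time.
#' @param multivariate Character vector for the joint model (`NULL` to
#'   skip).
#' @param per_tenth Variables whose HR is reported per 0.1 increase.
#' @return A `cox_screen` tibble: `analysis` (`"univariate"`/
#'   `"multivariate"`), `variable`, `term`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `n`, `events`, `scale_note`, `converged`.
#' @export
cox_models <- function(data, endpoint = c("os", "pfs"),
                       univariate = character(), multivariate = NULL,
                       per_tenth = "sphericity") {
  ep <- endpoint_columns(data, endpoint)
  df <- as.data.frame(data)
  df$.time <- ep$time
  df$.event <- as.integer(ep$event)
  n_events <- sum(df$.event)

  prep_term <- function(v) {
    if (v %in% per_tenth) {
      nm <- paste0(v, "_per_tenth")
      df[[nm]] <<- df[[v]] / 0.1
      nm
    } else {
      v
    }
  }

  fit_one <- function(vars, analysis) {
    terms <- vapply(vars, prep_term, character(1))
    if (n_events < 10 * length(terms)) {
      warning(sprintf("%s %s model: %d events for %d covariate(s); fewer than 10 events per covariate",
                      ep$endpoint, analysis, n_events, length(terms)),
              call. = FALSE)
    }
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                   paste(terms, collapse = " + ")))
    fit <- tryCatch(
      survival::coxph(fml, data = df, ties = "efron"),
      error = function(e) e, warning = function(w) {
        suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
      })
    if (inherits(fit, "error")) {
      return(tibble::tibble(
        analysis = analysis, variable = vars, term = terms,
        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p = NA_real_, n = nrow(df), events = n_events,
        scale_note = ifelse(vars %in% per_tenth, "per tenth", ""),
        converged = FALSE))
    }
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    # map each requested variable to its coefficient row(s)
    rows <- purrr::map_dfr(seq_along(vars), function(i) {
      hit <- grep(paste0("^", terms[i]), rownames(co))
      tibble::tibble(
        analysis = analysis, variable = vars[i],
        term = rownames(co)[hit],
        hr = unname(co[hit, "exp(coef)"]),
        ci_low = unname(ci[hit, "lower .95"]),
        ci_high = unname(ci[hit, "upper .95"]),
        p = unname(co[hit, "Pr(>|z|)"]),
        n = s$n, events = unname(s$nevent),
        scale_note = if (vars[i] %in% per_tenth) "per tenth" else "",
        converged = TRUE)
    })
    rows
  }

  out <- purrr::map_dfr(univariate, function(v) fit_one(v, "univariate"))
  if (!is.null(multivariate) && length(multivariate)) {
    out <- dplyr::bind_rows(out, fit_one(multivariate, "multivariate"))
  }
  out$endpoint <- ep$endpoint
  class(out) <- c("cox_screen", class(out))
  out
}
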