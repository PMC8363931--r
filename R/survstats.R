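#' Cox proportional-hazards fit with per-covariate summaries
#'
#' Fits a Cox model by partial-likelihood maximization (Efron tie handling by
#' default) on complete cases and returns one row per coefficient with the
#' hazard ratio, 95% Wald confidence interval and Wald p-value. Errors on
#' fewer than two events, constant covariates, non-convergence, and monotone
#' likelihood (perfect separation).
#'
#' @param data data.frame holding covariates, time and event columns
#' @param covariates character vector of covariate column names
#' @param time_col,event_col column names of follow-up time (months) and the
#'   event flag (1 death, 0 censored)
#' @param ties tie-handling method, `"efron"` or `"breslow"`
#' @return a `cox_result` data.frame: variable, beta, HR, ci_low, ci_high,
#'   se, p, n_used, n_events; the `coxph` fit in `attr(, "fit")`
#' @export
cox_fit <- function(data, covariates, time_col = "months",
                    event_col = "event", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c(covariates, time_col, event_col) %in% names(data)))
  d <- data[stats::complete.cases(data[c(covariates, time_col, event_col)]), ,
            drop = FALSE]
  if (sum(d[[event_col]]) < 2) stop("fewer than 2 events", call. = FALSE)
  for (v in covariates) {
    if (length(unique(d[[v]])) < 2) {
      stop("constant covariate: ", v, call. = FALSE)
    }
  }
  fml <- stats::reformulate(sprintf("`%s`", covariates),
                            response = sprintf("survival::Surv(`%s`, `%s`)",
                                               time_col, event_col))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite", msg, ignore.case = TRUE)) {
        stop("monotone likelihood (perfect separation): ", msg,
             call. = FALSE)
      }
      if (grepl("Ran out of iterations", msg)) {
        stop("Cox fit did not converge in 100 iterations", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  out <- data.frame(
    variable = names(beta), beta = unname(beta), HR = unname(exp(beta)),
    ci_low = unname(exp(beta - 1.96 * se)),
    ci_high = unname(exp(beta + 1.96 * se)),
    se = unname(se), p = unname(2 * stats::pnorm(-abs(z))),
    n_used = nrow(d), n_events = sum(d[[event_col]]),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Bonferroni correction
#'
#' `p_corrected = min(1, m * p)` with family size `m` (default: the number of
#' p-values supplied). `m` is explicit configuration: for the marker screens
#' it is the number of screened intensity variables (markers x 10
#' compartments).
#'
#' @param p numeric p-values in \[0, 1\]
#' @param m family size (>= 1)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (length(m) != 1 || !is.finite(m) || m < 1) {
    stop("family size m must be >= 1", call. = FALSE)
  }
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  pmin(1, p * m)
}

#' Proportional-hazards diagnostics from Schoenfeld residuals
#'
#' Regresses scaled Schoenfeld residuals on event time (identity time
#' transform) and reports the per-covariate and global score-test p-values.
#'
#' @param fit a `coxph` fit or a [cox_fit()] result
#' @return data.frame: variable, ph_p (last row `GLOBAL`)
#' @export
ph_test <- function(fit) {
  if (inherits(fit, "cox_result")) fit <- attr(fit, "fit")
  stopifnot(inherits(fit, "coxph"))
  if (sum(fit$nevent) < 3) stop("fewer than 3 events", call. = FALSE)
  zp <- survival::cox.zph(fit, transform = "identity")
  data.frame(variable = rownames(zp$table), ph_p = zp$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-rank test
#'
#' Compares survival between groups with the standard log-rank statistic on
#' the pooled risk sets.
#'
#' @param months follow-up times
#' @param event event flags (1 death, 0 censored)
#' @param group group labels (>= 2 non-empty groups)
#' @return list: chisq, df, p, observed, expected
#' @export
logrank <- function(months, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  if (sum(event) < 1) stop("need >= 1 event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(months, event) ~ group)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison: exact enumeration for small samples
#' (`n_x * n_y <= 400`, no ties), tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y numeric samples (non-empty)
#' @return list: U (number of (x, y) pairs with x > y), p
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; exact permutation p-value for n <= 8
#' without ties, t approximation otherwise. Zero rank variance yields a
#' missing coefficient with a warning.
#'
#' @param x,y numeric vectors, length >= 3
#' @return list: rho, p, n
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("zero variance in ranks; rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 8 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Survival-association screen over the patient variable table
#'
#' Reproduces the screening stack: (i) univariate Cox regression per scaled
#' intensity variable with Bonferroni correction over the family of screened
#' variables; (ii) optional multivariable Cox models for selected marker
#' variables adjusted for the clinical covariates; (iii) proportional-hazards
#' diagnostics per model. Complete-case analysis per model, with `n_used`
#' reported.
#'
#' @param table scaled patient variable table from [scale_for_cox()]
#' @param cohort clinical table with patient_id, the adjuster columns,
#'   `months` and `event`
#' @param multivariable_sets list of character vectors of table variables;
#'   each gets one adjusted model
#' @param adjusters clinical covariates for the multivariable models
#' @param m Bonferroni family size (default: number of screened variables)
#' @param ph run Schoenfeld-residual diagnostics per model?
#' @return a `screen_report` list: `report` (combined rows sorted by
#'   corrected p), `univariate`, `multivariable`, `m`
#' @export
run_screen <- function(table, cohort, multivariable_sets = list(),
                       adjusters = c("age", "sex", "side", "stage",
                                     "histology"),
                       m = NULL, ph = TRUE) {
  if (identical(attr(table, "scale"), "raw")) {
    stop("variable table is on the raw scale; apply scale_for_cox() first",
         call. = FALSE)
  }
  vars <- setdiff(names(table), "patient_id")
  d <- merge(table, cohort, by = "patient_id")
  if (sum(stats::complete.cases(d[c("months", "event")])) < 10) {
    stop("join produces < 10 complete cases", call. = FALSE)
  }
  m <- m %||% length(vars)

  uni <- do.call(rbind, lapply(vars, function(v) {
    res <- tryCatch(cox_fit(d, v), error = function(e) e)
    if (inherits(res, "error")) {
      # e.g. a zone variable empty on every core; keep the row, flag it
      return(data.frame(variable = v, n_used = sum(!is.na(d[[v]])),
                        HR = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, ph_p = NA_real_,
                        model_id = "univariate", stringsAsFactors = FALSE))
    }
    php <- if (ph) tryCatch(ph_test(res)$ph_p[1],
                            error = function(e) NA_real_) else NA_real_
    data.frame(variable = v, n_used = res$n_used, HR = res$HR,
               ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
               ph_p = php, model_id = "univariate",
               stringsAsFactors = FALSE)
  }))
  uni$p_corrected <- bonferroni(uni$p, m)

  multi <- NULL
  if (length(multivariable_sets)) {
    multi <- do.call(rbind, lapply(seq_along(multivariable_sets), function(i) {
      set <- multivariable_sets[[i]]
      res <- cox_fit(d, c(set, adjusters))
      phtab <- if (ph) tryCatch(ph_test(res), error = function(e) NULL)
      ph <- if (is.null(phtab)) rep(NA_real_, nrow(res)) else
        phtab$ph_p[match(res$variable, phtab$variable)]
      data.frame(variable = res$variable, n_used = res$n_used, HR = res$HR,
                 ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
                 ph_p = ph,
                 model_id = sprintf("multivariable_%d", i),
                 p_corrected = NA_real_, stringsAsFactors = FALSE)
    }))
  }
  cols <- c("variable", "n_used", "HR", "ci_low", "ci_high", "p",
            "p_corrected", "ph_p", "model_id")
  report <- rbind(uni[cols], if (!is.null(multi)) multi[cols])
  ord <- order(report$model_id != "univariate", report$p_corrected, report$p)
  report <- report[ord, ]
  rownames(report) <- NULL
  structure(list(report = report, univariate = uni, multivariable = multi,
                 m = m), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d univariate variable(s), Bonferroni m = %d\n",
              nrow(x$univariate), x$m))
  top <- utils::head(x$report, 10)
  top[c("HR", "ci_low", "ci_high")] <-
    lapply(top[c("HR", "ci_low", "ci_high")], round, 3)
  top[c("p", "p_corrected", "ph_p")] <-
    lapply(top[c("p", "p_corrected", "ph_p")], signif, 2)
  print(top, row.names = FALSE)
  invisible(x)
}
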