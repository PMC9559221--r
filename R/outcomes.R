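## Outcome stage: Kaplan-Meier / log-rank comparisons and Cox / logistic
## models across dnDSA concordance groups. Numerics are delegated to the
## survival package (Efron tie handling) and stats::glm; this module owns
## the comparison plan, group encoding and NA flagging for degenerate strata.

event_columns <- function(event = c("abmr", "graft_loss", "death")) {
  event <- match.arg(event)
  list(time = paste0(event, "_time"), flag = paste0(event, "_event"))
}

check_records <- function(records, cols) {
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
}

#' Kaplan-Meier curves and log-rank comparison across groups
#'
#' Product-limit curves per group at observed event times, a global log-rank
#' test, and all pairwise log-rank p-values. With no events anywhere the
#' statistic is 0 and p is 1 (curves stay flat at 1).
#'
#' @param records Cohort data frame with `<event>_time` (months),
#'   `<event>_event` (0/1) and the grouping column.
#' @param event `"abmr"`, `"graft_loss"` or `"death"`.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return List with `curves` (data frame: `group`, `time`, `surv`,
#'   `n_risk`, `n_event`), `logrank` (`chisq`, `df`, `p`), and `pairwise`
#'   (data frame of group pairs with p-values).
#' @export
km_logrank <- function(records, event = c("abmr", "graft_loss", "death"),
                       group_col = "group") {
  event <- match.arg(event)
  cols <- event_columns(event)
  check_records(records, c(cols$time, cols$flag, group_col))
  time <- as.numeric(records[[cols$time]])
  status <- as.integer(records[[cols$flag]])
  grp <- factor(records[[group_col]])
  if (nlevels(grp) < 2L) {
    stop("log-rank comparison needs at least two non-empty groups",
         call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ grp)
  sm <- summary(fit, censored = FALSE)
  strata <- if (is.null(sm$strata)) rep(levels(grp)[1L], length(sm$time))
  else sub("^grp=", "", as.character(sm$strata))
  curves <- data.frame(group = strata, time = sm$time, surv = sm$surv,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       stringsAsFactors = FALSE)
  logrank_of <- function(t, s, g) {
    if (sum(s) == 0L) return(list(chisq = 0, df = nlevels(droplevels(g)) - 1L,
                                  p = 1))
    sd <- survival::survdiff(survival::Surv(t, s) ~ g)
    df <- sum(sd$exp > 0) - 1L
    list(chisq = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  }
  global <- logrank_of(time, status, grp)
  lv <- levels(grp)
  pw <- list()
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      sel <- grp %in% lv[c(i, j)]
      res <- logrank_of(time[sel], status[sel], droplevels(grp[sel]))
      pw[[length(pw) + 1L]] <- data.frame(group1 = lv[i], group2 = lv[j],
                                          chisq = res$chisq, p = res$p,
                                          stringsAsFactors = FALSE)
    }
  }
  list(curves = curves, logrank = global,
       pairwise = if (length(pw)) do.call(rbind, pw) else NULL)
}

## A fitted binary/continuous term is flagged degenerate (reported NA, as
## for exposure groups with zero events) when the likelihood is monotone:
## huge |coef| or standard error.
coef_degenerate <- function(coef, se) {
  !is.finite(coef) || !is.finite(se) || abs(coef) > 15 || se > 100
}

extract_model_rows <- function(coefs, ses, ps, n_events) {
  out <- data.frame(term = names(coefs),
                    estimate = exp(unname(coefs)),
                    conf_low = exp(unname(coefs - 1.96 * ses)),
                    conf_high = exp(unname(coefs + 1.96 * ses)),
                    p = unname(ps),
                    n_events = n_events,
                    flagged_na = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    if (coef_degenerate(coefs[k], ses[k])) {
      out$estimate[k] <- NA_real_
      out$conf_low[k] <- NA_real_
      out$conf_high[k] <- NA_real_
      out$p[k] <- NA_real_
      out$flagged_na[k] <- TRUE
    }
  }
  out
}

#' Cox proportional-hazards models for a cohort
#'
#' `mode = "univariate"` fits one model per term; `"multivariate"` fits all
#' terms jointly. Collinear exposure encodings (e.g. `lr_dnDSA` and the
#' confirmed subgroup flag) should be passed to separate calls, mirroring
#' independent-models-due-to-collinearity practice. Ties use the Efron
#' approximation. Degenerate strata (zero events in an exposure level,
#' non-converged coefficients) are returned as NA-flagged rows, not errors.
#'
#' @param records Cohort data frame.
#' @param event `"abmr"`, `"graft_loss"` or `"death"`.
#' @param terms Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return Data frame with `term`, `estimate` (hazard ratio), `conf_low`,
#'   `conf_high` (95% Wald CI), `p`, `n_events`, `flagged_na`.
#' @export
cox_models <- function(records, event = c("abmr", "graft_loss", "death"),
                       terms, mode = c("univariate", "multivariate")) {
  event <- match.arg(event)
  mode <- match.arg(mode)
  cols <- event_columns(event)
  check_records(records, c(cols$time, cols$flag, terms))
  n_events <- sum(records[[cols$flag]])
  if (n_events < 1L) {
    return(data.frame(term = terms, estimate = NA_real_, conf_low = NA_real_,
                      conf_high = NA_real_, p = NA_real_, n_events = 0L,
                      flagged_na = TRUE, stringsAsFactors = FALSE))
  }
  surv <- sprintf("survival::Surv(%s, %s)", cols$time, cols$flag)
  fit_one <- function(rhs) {
    f <- stats::as.formula(paste(surv, "~", paste(rhs, collapse = " + ")))
    fit <- tryCatch(survival::coxph(f, data = records, ties = "efron"),
                    error = function(e) NULL, warning = function(w) {
                      suppressWarnings(survival::coxph(f, data = records,
                                                       ties = "efron"))
                    })
    if (is.null(fit)) return(NULL)
    s <- summary(fit)
    extract_model_rows(stats::coef(fit), s$coefficients[, "se(coef)"],
                       s$coefficients[, "Pr(>|z|)"], n_events)
  }
  if (mode == "multivariate") {
    res <- fit_one(terms)
    if (is.null(res)) {
      res <- data.frame(term = terms, estimate = NA_real_, conf_low = NA_real_,
                        conf_high = NA_real_, p = NA_real_,
                        n_events = n_events, flagged_na = TRUE,
                        stringsAsFactors = FALSE)
    }
    return(res)
  }
  out <- lapply(terms, function(t) {
    res <- fit_one(t)
    if (is.null(res)) {
      data.frame(term = t, estimate = NA_real_, conf_low = NA_real_,
                 conf_high = NA_real_, p = NA_real_, n_events = n_events,
                 flagged_na = TRUE, stringsAsFactors = FALSE)
    } else res
  })
  do.call(rbind, out)
}

#' Logistic models for a binary outcome
#'
#' Analogous to [cox_models()] with odds ratios. Complete separation (all
#' events in one exposure level) yields an NA-flagged row.
#'
#' @param records Cohort data frame.
#' @param outcome Name of the 0/1 outcome column (e.g. `"abmr_event"`).
#' @param terms Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return Data frame with `term`, `estimate` (odds ratio), `conf_low`,
#'   `conf_high`, `p`, `n_events`, `flagged_na`.
#' @export
logistic_models <- function(records, outcome, terms,
                            mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  check_records(records, c(outcome, terms))
  y <- as.integer(records[[outcome]])
  n_events <- sum(y)
  fit_one <- function(rhs) {
    f <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(f, data = records, family = stats::binomial()))
    s <- summary(fit)
    co <- s$coefficients
    co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
    coefs <- stats::setNames(co[, "Estimate"], rownames(co))
    extract_model_rows(coefs, co[, "Std. Error"], co[, "Pr(>|z|)"], n_events)
  }
  if (mode == "multivariate") return(fit_one(terms))
  do.call(rbind, lapply(terms, fit_one))
}
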