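# Residual-based normalization of affinity against molecular size (and
# other risk factors): fit -dG or pK_D by ordinary least squares on N_nH,
# logP, ..., then rank compounds by their residuals. Unlike ligand
# efficiency the residual ranking is invariant to the concentration unit,
# because a common shift of the response is absorbed by the intercept.

#' Fit a linear affinity-versus-risk-factor model
#'
#' Ordinary least squares with intercept of an affinity response on one or
#' more risk factors (heavy-atom count, logP, MW, or user indicator
#' columns). The response is either -dG in kcal/mol (at the context's
#' standard concentration) or pK_D; a common change of concentration unit
#' shifts the response by a constant, which only moves the intercept —
#' slopes, residuals and residual rankings are unchanged.
#'
#' @param records list of \code{compound_record}s, or a data.frame with an
#'   \code{id} column, the predictor columns, and (for data.frame input)
#'   either a \code{neg_dg} or \code{pkd} response column.
#' @param predictors character vector of predictor column names; for
#'   record input any of "n_nh", "logp", "mw", "hbd", "hba". Default
#'   "n_nh".
#' @param response_kind "neg_dg" (kcal/mol, default) or "pkd".
#' @param ctx a \code{thermo_context}; supplies T and C-standard for the
#'   -dG response.
#' @return object of class \code{affinity_fit}: the coefficient table
#'   (estimate, std. error), \code{rmse} (residual standard error,
#'   n-k-1 denominator), \code{r2}, \code{n}, the underlying \code{lm} in
#'   \code{$fit}, and the model frame ids. If R-squared < 0.3 a warning
#'   notes that normalization by this trend may be uninformative.
#' @examples
#' recs <- make_linear_series(sigma = 0, seed = 1)
#' fit_affinity_model(recs)
#' @export
fit_affinity_model <- function(records, predictors = "n_nh",
                               response_kind = c("neg_dg", "pkd"),
                               ctx = thermo_context()) {
  response_kind <- match.arg(response_kind)
  df <- model_frame_from(records, predictors, response_kind, ctx)
  k <- length(predictors)
  if (nrow(df) <= k + 1L)
    stop(sprintf("need more than %d observations to fit %d predictor(s)",
                 k + 1L, k), call. = FALSE)
  for (p in predictors)
    if (length(unique(df[[p]])) == 1L)
      stop(sprintf("predictor '%s' is constant", p), call. = FALSE)
  fml <- stats::as.formula(paste(".response ~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  # summary.lm warns on zero-residual fits; exact synthetic series are a
  # legitimate input here
  sm <- suppressWarnings(summary(fit))
  out <- structure(list(
    fit = fit,
    coefficients = sm$coefficients[, c("Estimate", "Std. Error"),
                                   drop = FALSE],
    rmse = sm$sigma, r2 = sm$r.squared, n = nrow(df),
    predictors = predictors, response_kind = response_kind,
    ids = df$id,
    cstd_molar = as_molar(ctx$c_standard),
    temperature = ctx$temperature), class = "affinity_fit")
  if (out$r2 < 0.3)
    warning(sprintf("weak trend (R^2 = %.2f): residual normalization may be uninformative",
                    out$r2), call. = FALSE)
  out
}

model_frame_from <- function(records, predictors, response_kind, ctx) {
  if (is.data.frame(records)) {
    df <- records
    if (is.null(df$id)) df$id <- as.character(seq_len(nrow(df)))
    rcol <- if (response_kind == "neg_dg") "neg_dg" else "pkd"
    if (is.null(df[[rcol]]))
      stop(sprintf("data.frame input needs a '%s' response column", rcol),
           call. = FALSE)
    df$.response <- df[[rcol]]
  } else {
    stopifnot(is_record_list(records))
    df <- data.frame(id = vapply(records, `[[`, character(1), "id"),
                     n_nh = vapply(records, `[[`, integer(1), "n_nh"),
                     mw = vapply(records, `[[`, numeric(1), "mw"),
                     logp = vapply(records, `[[`, numeric(1), "logp"),
                     hbd = as.numeric(vapply(records, `[[`, integer(1), "hbd")),
                     hba = as.numeric(vapply(records, `[[`, integer(1), "hba")),
                     pkd = vapply(records, `[[`, numeric(1), "pkd"),
                     stringsAsFactors = FALSE)
    # -dG = RT ln(C°/K_D) = RT ln10 (pK_D + log10 C°), pK_D on the 1 M scale
    df$.response <- if (response_kind == "neg_dg")
      rtln10(ctx) * (df$pkd + log10(as_molar(ctx$c_standard))) else df$pkd
  }
  miss <- predictors[!predictors %in% names(df)]
  if (length(miss))
    stop(sprintf("predictor column(s) not found: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  keep <- stats::complete.cases(df[, c(".response", predictors)])
  excluded <- df$id[!keep]
  df <- df[keep, , drop = FALSE]
  attr(df, "excluded") <- excluded
  df
}

#' @export
print.affinity_fit <- function(x, ...) {
  resp <- if (x$response_kind == "neg_dg")
    sprintf("-dG/(kcal/mol) @ C° = %g M, T = %g K", x$cstd_molar,
            x$temperature) else "pK_D"
  cat("<affinity_fit> ", resp, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  cat(sprintf("  n = %d, RMSE = %.3g, R^2 = %.3g\n", x$n, x$rmse, x$r2))
  invisible(x)
}

#' Summary in the layout of a small-n affinity-regression table
#'
#' One row per dataset: n, each coefficient with its standard error, RMSE
#' (residual standard error) and R-squared.
#'
#' @param object an \code{affinity_fit}.
#' @param ... unused.
#' @return data.frame of class \code{summary.affinity_fit}.
#' @export
summary.affinity_fit <- function(object, ...) {
  co <- object$coefficients
  row <- data.frame(n = object$n)
  cn <- rownames(co)
  labels <- sub("^\\(Intercept\\)$", "A0", cn)
  labels[labels != "A0"] <- paste0("A", seq_len(sum(labels != "A0")))
  for (i in seq_along(cn)) {
    row[[labels[i]]] <- co[i, "Estimate"]
    row[[paste0("SE_", labels[i])]] <- co[i, "Std. Error"]
  }
  row$RMSE <- object$rmse
  row$R2 <- object$r2
  class(row) <- c("summary.affinity_fit", "data.frame")
  row
}

#' @export
coef.affinity_fit <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.affinity_fit <- function(object, ...) {
  r <- stats::residuals(object$fit)
  names(r) <- object$ids
  r
}

#' @export
predict.affinity_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  if (is_record_list(newdata))
    newdata <- model_frame_from(newdata, object$predictors,
                                object$response_kind, thermo_context(
                                  object$temperature, object$cstd_molar))
  stats::predict(object$fit, newdata = newdata)
}

#' @export
plot.affinity_fit <- function(x, ...) {
  df <- x$fit$model
  p1 <- x$predictors[1L]
  resp_lab <- if (x$response_kind == "neg_dg") "-dG (kcal/mol)" else "pK_D"
  graphics::plot(df[[p1]], df$.response, xlab = p1, ylab = resp_lab,
                 pch = 19, ...)
  if (length(x$predictors) == 1L)
    graphics::abline(stats::coef(x$fit)[1L], stats::coef(x$fit)[2L],
                     lty = 2)
  invisible(x)
}

#' Normalize affinity by regression residuals
#'
#' Subtracts the model-predicted affinity from the observed value for each
#' compound: positive residuals bind better than their size (or other risk
#' factors) predicts. The residual ranking is invariant under a common
#' change of concentration unit. Residuals larger in magnitude than the
#' threshold are flagged as activity-cliff-like.
#'
#' @param records list of \code{compound_record}s or a data.frame as in
#'   \code{fit_affinity_model} (typically the data the model was fitted
#'   on, or new compounds with the same predictors).
#' @param model an \code{affinity_fit}.
#' @param cliff_threshold flag threshold on |residual|; default 1.0
#'   (kcal/mol for a -dG response, log units for pK_D).
#' @param ctx a \code{thermo_context} matching the model's response.
#' @return data.frame of class \code{residual_table}: id, observed,
#'   predicted, residual, rank (1 = largest positive residual), cliff
#'   flag; records dropped for missing predictors are listed in attribute
#'   \code{excluded}.
#' @export
residual_normalize <- function(records, model, cliff_threshold = 1.0,
                               ctx = thermo_context()) {
  stopifnot(inherits(model, "affinity_fit"))
  df <- model_frame_from(records, model$predictors, model$response_kind,
                         ctx)
  pred <- stats::predict(model$fit, newdata = df)
  res <- df$.response - pred
  out <- data.frame(id = df$id, observed = df$.response, predicted = pred,
                    residual = res,
                    rank = rank(-res, ties.method = "first"),
                    cliff = abs(res) > cliff_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- attr(df, "excluded")
  attr(out, "cliff_threshold") <- cliff_threshold
  class(out) <- c("residual_table", "data.frame")
  out
}

#' Refit excluding named compounds, reporting both models
#'
#' The two-step normalization workflow: fit on everything, spot the
#' structural outlier by its residual, then exclude it and refit so the
#' remaining compounds are normalized against their own trend. Both fits
#' and both residual tables are returned side by side.
#'
#' @param records as in \code{fit_affinity_model}.
#' @param exclude character ids to drop from the refit.
#' @param predictors,response_kind,ctx as in \code{fit_affinity_model}.
#' @param cliff_threshold as in \code{residual_normalize}.
#' @return list of class \code{affinity_refit} with elements \code{before},
#'   \code{after} (\code{affinity_fit}s), \code{residuals_before},
#'   \code{residuals_after}, \code{excluded}.
#' @export
refit_excluding <- function(records, exclude = character(0),
                            predictors = "n_nh",
                            response_kind = c("neg_dg", "pkd"),
                            ctx = thermo_context(), cliff_threshold = 1.0) {
  response_kind <- match.arg(response_kind)
  before <- fit_affinity_model(records, predictors, response_kind, ctx)
  rb <- residual_normalize(records, before, cliff_threshold, ctx)
  if (length(exclude) == 0L) {
    return(structure(list(before = before, after = before,
                          residuals_before = rb, residuals_after = rb,
                          excluded = character(0)),
                     class = "affinity_refit"))
  }
  kept <- if (is.data.frame(records)) {
    records[!records$id %in% exclude, , drop = FALSE]
  } else {
    Filter(function(r) !r$id %in% exclude, records)
  }
  nkept <- if (is.data.frame(kept)) nrow(kept) else length(kept)
  if (nkept <= length(predictors) + 1L)
    stop("exclusion leaves too few observations to fit", call. = FALSE)
  after <- fit_affinity_model(kept, predictors, response_kind, ctx)
  ra <- residual_normalize(kept, after, cliff_threshold, ctx)
  structure(list(before = before, after = after, residuals_before = rb,
                 residuals_after = ra, excluded = exclude),
            class = "affinity_refit")
}

#' @export
print.affinity_refit <- function(x, ...) {
  cat("<affinity_refit>\n  before: "); print(summary(x$before))
  cat("  after (excluding ", paste(x$excluded, collapse = ", "), "): ",
      sep = ""); print(summary(x$after))
  invisible(x)
}
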