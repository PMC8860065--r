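# Internal Gaussian OLS engine shared by ols_fit/all_subsets.  Returns the
# pieces every caller needs without the weight of an lm object.
.ols_engine <- function(y, Xd) {
  n <- length(y)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xd))]]
    stop("singular fit; aliased column(s): ", paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  rss <- sum(res^2)
  p <- ncol(Xd) - 1L                     # predictors excluding intercept
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  df_res <- n - p - 1L
  sigma2 <- rss / df_res
  R <- qr.R(qrX)
  xtx_inv <- chol2inv(R)
  # columns of R follow the pivot; map the covariance back to input order
  piv <- qrX$pivot
  se <- sqrt(diag(xtx_inv) * sigma2)[order(piv)]
  names(se) <- colnames(Xd)
  # an (essentially) exact fit gets infinite likelihood rather than a
  # machine-noise-dependent one, so perfect submodels rank deterministically
  loglik <- if (rss <= 1e-12 * max(tss, .Machine$double.xmin)) Inf else
    -0.5 * n * (log(2 * pi) + log(rss / n) + 1)
  list(n = n, p = p, coef = coef, se = se, residuals = res, rss = rss,
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / df_res,
       sigma2 = sigma2, df_res = df_res, loglik = loglik)
}

#' Small-sample Akaike Information Criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `k = p + 2` parameters
#' (p slopes, intercept, residual variance), the convention of the usual R
#' information-criterion tooling, so rankings are comparable with it.
#'
#' @param loglik Gaussian maximised log-likelihood.
#' @param n observations; @param p number of predictors (excl. intercept).
#' @return AICc value; `Inf` when `n - k - 1 <= 0` (model too large).
#' @export
aicc <- function(loglik, n, p) {
  k <- p + 2
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Ordinary least squares fit with anomaly-regression diagnostics
#'
#' Gaussian OLS with intercept of `y` on the named subset of columns of
#' `X`.  Beyond coefficients and AICc, the fit carries the diagnostics
#' used for coefficient tables: per-predictor partial correlations `pR`
#' (see [partial_correlations()]), partial determination `pR^2`, and
#' variance inflation factors.
#'
#' @param y numeric response (typically standardised anomaly by year).
#' @param X numeric matrix of covariates, columns named.
#' @param predictors character vector of column names (may be empty for
#'   the intercept-only model).
#' @param response label stored on the fit.
#' @return An object of class `regression_fit`.
#' @export
ols_fit <- function(y, X, predictors = colnames(X), response = "y") {
  if (length(predictors) && any(!predictors %in% colnames(X))) {
    stop("unknown predictor(s): ",
         paste(setdiff(predictors, colnames(X)), collapse = ", "))
  }
  n <- length(y)
  if (n <= length(predictors) + 2) {
    stop("need n > p + 2 (n = ", n, ", p = ", length(predictors), ")")
  }
  Xs <- X[, predictors, drop = FALSE]
  Xd <- cbind(`(Intercept)` = rep(1, n), Xs)
  eng <- .ols_engine(y, Xd)
  tval <- eng$coef / eng$se
  pval <- 2 * stats::pt(-abs(tval), eng$df_res)
  pr <- if (length(predictors)) partial_correlations(y, X, predictors) else numeric(0)
  fit <- list(response = response, predictors = predictors, n = n,
              coefficients = eng$coef, std_errors = eng$se,
              t_values = tval, p_values = pval,
              r2 = eng$r2, adj_r2 = eng$adj_r2,
              loglik = eng$loglik, aicc = aicc(eng$loglik, n, eng$p),
              delta_aicc = NA_real_,
              sigma = sqrt(eng$sigma2), residuals = eng$residuals,
              vif = if (length(predictors)) vif(X, predictors) else numeric(0),
              pR = pr, partial_r2 = pr^2)
  class(fit) <- "regression_fit"
  fit
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s ~ %s\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1"))
  cat(sprintf("  n = %d, AdjR2 = %.3f, AICc = %.2f\n", x$n, x$adj_r2, x$aicc))
  if (length(x$predictors)) {
    tab <- coef_table(x)
    print(tab, digits = 3)
  }
  invisible(x)
}

#' Coefficient table of a fit, one row per predictor
#'
#' @param fit a `regression_fit`.
#' @return data frame with `Estimate`, `SE`, `t`, `p`, `VIF`, `R2`
#'   (partial determination), `pR` columns.
#' @export
coef_table <- function(fit) {
  p <- fit$predictors
  data.frame(predictor = p,
             Estimate = unname(fit$coefficients[p]),
             SE = unname(fit$std_errors[p]),
             t = unname(fit$t_values[p]),
             p = unname(fit$p_values[p]),
             VIF = unname(fit$vif[p]),
             R2 = unname(fit$partial_r2[p]),
             pR = unname(fit$pR[p]),
             stringsAsFactors = FALSE)
}

#' Partial correlation of each predictor with the response
#'
#' `pR(x_i)` is the Pearson correlation between (a) the residuals of `y`
#' regressed (with intercept) on all predictors except `x_i` and (b) the
#' residuals of `x_i` regressed on the same set.  It measures direction
#' and strength of the response–predictor association with the other
#' predictors' linear effects removed.  With one predictor it reduces to
#' the marginal Pearson correlation.
#'
#' @inheritParams ols_fit
#' @return Named numeric vector of partial correlations in `[-1, 1]`.
#' @export
partial_correlations <- function(y, X, predictors) {
  if (!length(predictors)) stop("need at least one predictor")
  out <- numeric(length(predictors))
  names(out) <- predictors
  n <- length(y)
  for (i in seq_along(predictors)) {
    others <- predictors[-i]
    Z <- cbind(rep(1, n), X[, others, drop = FALSE])
    qz <- qr(Z)
    ry <- qr.resid(qz, y)
    rx <- qr.resid(qz, X[, predictors[i]])
    if (stats::sd(ry) < 1e-12 || stats::sd(rx) < 1e-12) {
      stop("degenerate residuals for predictor ", predictors[i],
           ": partial correlation undefined")
    }
    out[i] <- stats::cor(ry, rx)
  }
  out
}

#' Variance inflation factors
#'
#' `VIF(x_i) = 1 / (1 - R^2)` of `x_i` regressed on the other predictors
#' in the subset (with intercept); 1 for a lone predictor; `Inf` under
#' perfect collinearity.
#'
#' @inheritParams ols_fit
#' @param predictors the predictor subset to diagnose.
#' @return Named numeric vector, all values `>= 1`.
#' @export
vif <- function(X, predictors) {
  out <- numeric(length(predictors))
  names(out) <- predictors
  n <- nrow(X)
  for (i in seq_along(predictors)) {
    if (length(predictors) == 1) { out[i] <- 1; next }
    others <- predictors[-i]
    Z <- cbind(rep(1, n), X[, others, drop = FALSE])
    xi <- X[, predictors[i]]
    res <- qr.resid(qr(Z), xi)
    tss <- sum((xi - mean(xi))^2)
    r2 <- 1 - sum(res^2) / tss
    out[i] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' All-subsets regression ranked by AICc
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model), enumerated by binary counting over the
#' candidate order so runs are reproducible, and ranks ascending by
#' AICc.  Ties within 1e-9 rank the smaller model first, then
#' lexicographically by predictor names.  Subsets too large for the AICc
#' correction (`n - k - 1 < 1`) or singular are skipped with a warning.
#'
#' @inheritParams ols_fit
#' @param candidates candidate predictor names (at most 16).
#' @return An object of class `subset_ranking`: list with `table` (one
#'   row per fitted subset: `predictors`, `size`, `aicc`, `delta_aicc`,
#'   `adj_r2`, `r2`), plus `y`, `X`, `candidates` for later refits.
#' @export
all_subsets <- function(y, X, candidates = colnames(X)) {
  q <- length(candidates)
  if (q > 16) stop("at most 16 candidate predictors (2^16 fits)")
  n <- length(y)
  rows <- vector("list", 2^q)
  skipped <- character(0)
  for (m in 0:(2^q - 1)) {
    subset <- candidates[bitwAnd(m, bitwShiftL(1L, seq_len(q) - 1L)) > 0]
    p <- length(subset)
    if (n - (p + 2) - 1 < 1) {
      skipped <- c(skipped, paste(subset, collapse = "+"))
      next
    }
    Xd <- cbind(rep(1, n), X[, subset, drop = FALSE])
    eng <- tryCatch(.ols_engine(y, Xd), error = function(e) NULL)
    if (is.null(eng)) {
      skipped <- c(skipped, paste(subset, collapse = "+"))
      next
    }
    rows[[m + 1]] <- data.frame(
      predictors = paste(subset, collapse = "+"), size = p,
      aicc = aicc(eng$loglik, n, p), adj_r2 = eng$adj_r2, r2 = eng$r2,
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning(length(skipped), " subset(s) skipped (singular or too large)")
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ord <- order(tab$aicc + 1e-9 * tab$size, tab$size, tab$predictors)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  structure(list(table = tab, y = y, X = X, candidates = candidates,
                 skipped = skipped),
            class = "subset_ranking")
}

#' @export
print.subset_ranking <- function(x, ...) {
  cat(sprintf("<subset_ranking> %d fits over %d candidates; best: %s\n",
              nrow(x$table), length(x$candidates),
              if (nzchar(x$table$predictors[1])) x$table$predictors[1]
              else "(intercept only)"))
  print(utils::head(x$table, 5), digits = 4)
  invisible(x)
}

.split_predictors <- function(s) {
  if (!nzchar(s)) character(0) else strsplit(s, "+", fixed = TRUE)[[1]]
}

#' Top-model set by a delta-AICc cutoff
#'
#' Refits (with full diagnostics) every subset whose AICc lies strictly
#' within `delta_max` of the best model.
#'
#' @param ranking a `subset_ranking` from [all_subsets()].
#' @param delta_max cutoff (default 2; strict inequality).
#' @param response label passed to the fits.
#' @return list of `regression_fit`, best first; the matching rows of the
#'   ranking table as attribute `"table"`.
#' @export
top_models <- function(ranking, delta_max = 2, response = "y") {
  tab <- ranking$table[ranking$table$delta_aicc < delta_max, , drop = FALSE]
  fits <- lapply(seq_len(nrow(tab)), function(i) {
    f <- ols_fit(ranking$y, ranking$X, .split_predictors(tab$predictors[i]),
                 response = response)
    f$delta_aicc <- tab$delta_aicc[i]
    f
  })
  attr(fits, "table") <- tab
  fits
}

#' Fraction of top models containing a variable
#'
#' Presence frequency: the share of the top-model set whose predictor
#' list contains `variable` (the default reading of "contribution";
#' [akaike_weight_contribution()] gives the weight-sum alternative).
#'
#' @param variable predictor name.
#' @param top list of `regression_fit` (see [top_models()]).
#' @return number in `[0, 1]`.
#' @export
contribution <- function(variable, top) {
  if (!length(top)) stop("empty top-model set")
  mean(vapply(top, function(f) variable %in% f$predictors, logical(1)))
}

#' Akaike-weight-sum contribution over a top-model set
#'
#' @inheritParams contribution
#' @return Sum of the normalised Akaike weights of the top models that
#'   contain `variable`.
#' @export
akaike_weight_contribution <- function(variable, top) {
  if (!length(top)) stop("empty top-model set")
  d <- vapply(top, function(f) f$delta_aicc, numeric(1))
  w <- exp(-d / 2); w <- w / sum(w)
  sum(w[vapply(top, function(f) variable %in% f$predictors, logical(1))])
}

#' Contribution of every candidate over a top-model set
#'
#' @param top list of `regression_fit`.
#' @param candidates candidate names.
#' @param method `"presence"` (default) or `"akaike_weight"`.
#' @return Named numeric vector.
#' @export
contribution_table <- function(top, candidates,
                               method = c("presence", "akaike_weight")) {
  method <- match.arg(method)
  fun <- if (method == "presence") contribution else akaike_weight_contribution
  vapply(stats::setNames(candidates, candidates), fun, numeric(1), top = top)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values (monotone, `>=` raw, capped at 1).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Linear year-trends with Benjamini-Hochberg correction
#'
#' Regresses each anomaly series on calendar year and adjusts the slope
#' p-values across the supplied family (the set of tests reported
#' together).  `total_shift` is the absolute fitted change between the
#' first and last year, `|slope| * (last - first)`.
#'
#' @param series named list; each element a numeric vector of anomalies
#'   named by year.
#' @param family which elements form the correction family (default all).
#' @return data frame: `response`, `n`, `slope`, `se`, `r2`, `p_raw`,
#'   `p_bh`, `total_shift`.
#' @export
trend_with_bh <- function(series, family = names(series)) {
  rows <- lapply(family, function(nm) {
    y <- series[[nm]]
    yr <- as.numeric(names(y))
    if (length(y) < 3) stop("need >= 3 years for a trend: ", nm)
    if (stats::sd(y) < 1e-12) {
      # a perfectly flat series: no trend by definition
      return(data.frame(response = nm, n = length(y), slope = 0, se = 0,
                        r2 = NA_real_, p_raw = 1, total_shift = 0,
                        stringsAsFactors = FALSE))
    }
    Xd <- cbind(1, yr)
    colnames(Xd) <- c("(Intercept)", "year")
    eng <- .ols_engine(y, Xd)
    # a perfectly flat series has slope 0 with zero residual error: no trend
    tval <- if (eng$se[2] > 0) eng$coef[2] / eng$se[2] else 0
    data.frame(response = nm, n = eng$n, slope = unname(eng$coef[2]),
               se = unname(eng$se[2]), r2 = eng$r2,
               p_raw = unname(2 * stats::pt(-abs(tval), eng$df_res)),
               total_shift = abs(unname(eng$coef[2])) * (max(yr) - min(yr)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p_raw)
  out[, c("response", "n", "slope", "se", "r2", "p_raw", "p_bh",
          "total_shift")]
}

#' Moving-window partial-correlation profile
#'
#' For each overlapping sub-period anomaly series, fits the full model on
#' all selected covariates and stores the sign-inverted partial
#' correlation `-pR` per covariate, so positive profile values indicate
#' "higher index, earlier passage".  The windows overlap, so the profile
#' is an exploratory display, not a set of independent models.
#'
#' @param sub_anomalies named list of anomaly series (one per sub-period),
#'   each a numeric vector named by year.
#' @param covariates numeric matrix `years x variables` (rownames =
#'   years), typically the nine selected variables.
#' @param standardized if `TRUE` (default), response and covariates are
#'   z-scored over each model's years before fitting.
#' @return An object of class `window_profile`: list with `matrix`
#'   (sub-periods x variables of `-pR`) and `long` (tidy data frame).
#' @export
window_profile <- function(sub_anomalies, covariates, standardized = TRUE) {
  vars <- colnames(covariates)
  M <- matrix(NA_real_, nrow = length(sub_anomalies), ncol = length(vars),
              dimnames = list(names(sub_anomalies), vars))
  for (sp in names(sub_anomalies)) {
    y <- sub_anomalies[[sp]]
    yrs <- intersect(names(y), rownames(covariates))
    y <- y[yrs]
    X <- covariates[yrs, , drop = FALSE]
    if (standardized) {
      y <- standardize(y)
      X <- standardize_matrix(X)
    }
    M[sp, ] <- -partial_correlations(y, X, vars)
  }
  long <- data.frame(
    sub_period = rep(rownames(M), times = ncol(M)),
    variable = rep(colnames(M), each = nrow(M)),
    neg_pR = as.vector(M), stringsAsFactors = FALSE)
  structure(list(matrix = M, long = long), class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("<window_profile> %d sub-periods x %d variables (-pR)\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, 2))
  invisible(x)
}
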