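# Environmental-driver analyses: trailing-window precipitation means,
# correlation tests, collinearity screening and AICc forward selection with
# model averaging.

#' Trailing-window mean of a daily series
#'
#' Mean daily precipitation over the \code{window_days} days strictly before
#' each target date (start-inclusive, end-exclusive: the window for date t is
#' [t - window_days, t - 1]). Used to summarise the hydrological conditions an
#' individual experienced during larval development.
#'
#' @param series An \code{env_series} data.frame (\code{date},
#'   \code{precipitation}).
#' @param dates Target date(s).
#' @param window_days Window length in days (>= 1).
#' @return Numeric vector of window means, one per target date.
#' @export
trailing_window_mean <- function(series, dates, window_days) {
  if (!is_count(window_days, min = 1))
    stopf("window_days must be an integer >= 1")
  dates <- as.Date(dates)
  if (anyNA(dates)) stopf("unparseable target date(s)")
  sdates <- as.Date(series$date)
  precip <- setNames(series$precipitation, format(sdates))
  vapply(seq_along(dates), function(k) {
    want <- dates[k] - seq_len(window_days)
    key <- format(want)
    hit <- key %in% names(precip)
    if (!all(hit))
      stopf("precipitation series does not cover the %d-day window before %s (missing: %s%s)",
            window_days, format(dates[k]),
            paste(utils::head(key[!hit], 5), collapse = ", "),
            if (sum(!hit) > 5) ", ..." else "")
    mean(precip[key])
  }, numeric(1))
}

#' Pearson correlation test
#'
#' Thin wrapper over \code{\link[stats]{cor.test}} with the input checks the
#' pipeline needs (n >= 3, both variances positive). Two-sided.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
cor_pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("Pearson correlation requires n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("zero variance in x or y; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Spearman rank correlation test
#'
#' Rank-based correlation with midranks for ties; two-sided p-value. For
#' n <= 10 without ties the exact null distribution is used; otherwise the
#' t approximation.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
cor_spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("Spearman correlation requires n >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stopf("all-tied vector; rank correlation undefined")
  exact <- length(x) <= 10
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# VIF of each column of the numeric predictor matrix X: 1 / (1 - R^2) of that
# column regressed on all the others.
vif_values <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ ., data = as.data.frame(X[, -j, drop = FALSE]))
    r2 <- summary(fit)$r.squared
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Collinearity screen: pairwise correlation filter then VIF removal
#'
#' Two-stage predictor screening used before model building. Stage 1 walks
#' ordered predictor pairs (input order) and, whenever |r| exceeds
#' \code{corr_threshold} between two still-retained predictors, drops the
#' later one. Stage 2 iteratively removes the predictor with the highest
#' variance inflation factor until all VIF <= \code{vif_threshold}.
#'
#' @param predictors Data.frame of numeric candidate predictors.
#' @param corr_threshold Absolute pairwise correlation cutoff (default 0.60).
#' @param vif_threshold VIF cutoff (default 10).
#' @return List with \code{retained} (character), \code{excluded}
#'   (data.frame: variable, reason, detail).
#' @export
collinearity_screen <- function(predictors, corr_threshold = 0.60,
                                vif_threshold = 10) {
  if (!is.data.frame(predictors) || ncol(predictors) < 2)
    stopf("need a data.frame with >= 2 predictors")
  if (nrow(predictors) <= ncol(predictors))
    stopf("need more observations than predictors")
  num <- vapply(predictors, is.numeric, logical(1))
  if (!all(num))
    stopf("non-numeric predictor(s): %s",
          paste(names(predictors)[!num], collapse = ", "))

  vars <- names(predictors)
  dropped <- data.frame(variable = character(), reason = character(),
                        detail = character(), stringsAsFactors = FALSE)
  # stage 1: pairwise |r| filter, dropping the later variable in input order
  keep <- vars
  cm <- cor(predictors)
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      vi <- vars[i]; vj <- vars[j]
      if (!(vi %in% keep) || !(vj %in% keep)) next
      r <- cm[vi, vj]
      if (abs(r) > corr_threshold) {
        keep <- setdiff(keep, vj)
        dropped <- rbind(dropped, data.frame(
          variable = vj, reason = "pairwise-correlation",
          detail = sprintf("|r| = %.3f with %s", abs(r), vi),
          stringsAsFactors = FALSE))
        log_msg("collinearity_screen: dropped '%s' (|r| = %.2f with '%s')",
                vj, abs(r), vi)
      }
    }
  }
  # stage 2: iterative VIF removal
  while (length(keep) >= 2) {
    v <- vif_values(as.matrix(predictors[keep]))
    if (all(is.finite(v)) && max(v) <= vif_threshold) break
    worst <- keep[which.max(v)]
    dropped <- rbind(dropped, data.frame(
      variable = worst, reason = "VIF",
      detail = sprintf("VIF = %.2f", max(v)), stringsAsFactors = FALSE))
    log_msg("collinearity_screen: dropped '%s' (VIF = %.2f)", worst, max(v))
    keep <- setdiff(keep, worst)
  }
  if (length(keep) == 0)
    stopf("screening removed every predictor; design is singular")
  list(retained = keep, excluded = dropped)
}

# AICc of a least-squares fit: n log(RSS/n) + 2k + 2k(k+1)/(n-k-1), with k
# counting all estimated parameters (intercept, slopes, error variance).
aicc_lm <- function(fit) {
  n <- length(resid(fit))
  rss <- sum(resid(fit)^2)
  k <- length(coef(fit)) + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc forward selection with model averaging
#'
#' Greedy forward selection for a linear model: starting from the
#' intercept-only model, each step adds the predictor that most lowers AICc
#' (small-sample-corrected AIC, with parameter count including intercept and
#' error variance), stopping when no addition lowers it. Exact AICc ties are
#' broken in favour of fewer predictors, then input order. All models
#' evaluated during the search form the candidate set; Akaike weights are
#' computed over that set, the confidence subset is all candidates with
#' delta-AICc < \code{aicc_delta}, and model-averaged coefficients are
#' subset-weight-renormalised means (a coefficient is 0 in models that omit
#' it).
#'
#' The fit is reported as unsupported (\code{supported = FALSE}) when the
#' intercept-only model itself lies within \code{aicc_delta} of the best
#' candidate: no predictor model is then convincingly better than the null,
#' i.e. there is no support for any model.
#'
#' @param response Numeric response vector.
#' @param predictors Data.frame of numeric candidate predictors (typically
#'   already passed through \code{\link{collinearity_screen}}).
#' @param aicc_delta Equivalence band on the AICc scale (default 2).
#' @return A list of class \code{model_selection}: \code{candidates}
#'   (data.frame: model, k, aicc, delta_aicc, weight, in_subset),
#'   \code{best} (predictor names of the lowest-AICc model),
#'   \code{supported}, \code{averaged_coefficients}, \code{n}.
#' @export
aicc_forward_selection <- function(response, predictors, aicc_delta = 2) {
  if (!is.numeric(response)) stopf("response must be numeric")
  if (!is.data.frame(predictors) || ncol(predictors) < 1)
    stopf("predictors must be a data.frame with >= 1 column")
  n <- length(response)
  if (n != nrow(predictors))
    stopf("response and predictors disagree on n")
  # every candidate model (largest: all predictors) needs n >= k + 2
  if (n < 4) stopf("too few observations for AICc model selection")

  dat <- cbind(data.frame(.y = response), predictors)
  fit_model <- function(terms) {
    f <- if (length(terms) == 0) .y ~ 1
         else as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    lm(f, data = dat)
  }
  model_id <- function(terms) {
    if (length(terms) == 0) "(intercept)" else paste(terms, collapse = " + ")
  }

  visited <- list()
  note_model <- function(terms) {
    id <- model_id(terms)
    if (is.null(visited[[id]])) {
      fit <- fit_model(terms)
      visited[[id]] <<- list(terms = terms, fit = fit, aicc = aicc_lm(fit))
    }
    visited[[id]]
  }

  current <- character()
  note_model(current)
  repeat {
    remaining <- setdiff(names(predictors), current)
    if (length(remaining) == 0) break
    cand <- lapply(remaining, function(v) note_model(c(current, v)))
    aiccs <- vapply(cand, `[[`, numeric(1), "aicc")
    best_j <- which.min(aiccs)          # input order breaks exact ties
    if (aiccs[best_j] < visited[[model_id(current)]]$aicc) {
      current <- c(current, remaining[best_j])
    } else break
  }

  ids <- names(visited)
  aiccs <- vapply(visited, `[[`, numeric(1), "aicc")
  ks <- vapply(visited, function(m) length(m$terms) + 2, numeric(1))
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  in_subset <- delta < aicc_delta
  candidates <- data.frame(model = ids, k = ks, aicc = aiccs,
                           delta_aicc = delta, weight = w,
                           in_subset = in_subset,
                           stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$aicc), , drop = FALSE]
  rownames(candidates) <- NULL

  best <- visited[[ids[which.min(aiccs)]]]$terms
  null_delta <- delta[["(intercept)"]]
  supported <- null_delta >= aicc_delta

  # model-averaged coefficients over the confidence subset
  sub <- visited[in_subset]
  wsub <- w[in_subset] / sum(w[in_subset])
  all_terms <- c("(Intercept)", names(predictors))
  avg <- setNames(numeric(length(all_terms)), all_terms)
  for (m in seq_along(sub)) {
    cf <- coef(sub[[m]]$fit)
    avg[names(cf)] <- avg[names(cf)] + wsub[m] * cf
  }

  structure(list(candidates = candidates, best = best,
                 supported = supported,
                 averaged_coefficients = avg, n = n,
                 aicc_delta = aicc_delta),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("AICc forward selection (n = %d)\n", x$n))
  if (x$supported) {
    cat(sprintf("Best model: %s\n",
                if (length(x$best) == 0) "(intercept)" else
                  paste(x$best, collapse = " + ")))
  } else {
    cat("No supported model: intercept-only is within",
        x$aicc_delta, "AICc of the best candidate\n")
  }
  print(format(utils::head(x$candidates, 8), digits = 4), row.names = FALSE)
  invisible(x)
}
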