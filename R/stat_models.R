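## stat_models: %CV, Mann-Whitney depth comparisons, the +/-1 SD depth
## window, and logistic regression of call discordance on QC covariates.

#' Percent coefficient of variation
#'
#' `100 * SD / mean`. The default SD convention is the population SD
#' (n denominator), which reproduces the published per-sample call-count
#' %CV values at printed precision; `sd_type = "sample"` uses the usual
#' n-1 denominator.
#'
#' @param values numeric vector, `length >= 2`, nonzero mean.
#' @param sd_type `"population"` or `"sample"`.
#' @return percentage.
#' @export
percent_cv <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2L) stop("percent_cv needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("percent_cv undefined for zero mean")
  s <- sd(values)
  if (sd_type == "population")
    s <- s * sqrt((length(values) - 1) / length(values))
  100 * s / m
}

#' Mann-Whitney U test for depth differences
#'
#' Two-sided test of whether read depths differ between concordant and
#' discordant calls. When both groups have at most `exact_max` observations
#' the p-value is computed by exhaustive enumeration of all
#' `choose(n1 + n2, n1)` group labelings (valid with ties); otherwise the
#' tie-corrected normal approximation of [stats::wilcox.test()] is used.
#'
#' @param x,y numeric vectors (e.g. depths of concordant / discordant calls).
#' @param exact_max exhaustive-enumeration threshold per group.
#' @return list with `U` (statistic for the first group), `p_value`,
#'   `method`.
#' @export
mann_whitney_depth <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pooled <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2, function(ix)
      sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p_value = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(U = U, p_value = wt$p.value, method = "normal approximation")
  }
}

#' Build discordance observations for regression
#'
#' One observation per (site, sample) for an NGS platform versus the array
#' reference: the discordance indicator (alt-positivity disagreement), the
#' platform's read depth at the pair, and the site's GC and homopolymer
#' covariates. Pairs without depth are excluded (the array carries no depth).
#'
#' @param tensor a [call_tensor].
#' @param features [annotate_features()] output aligned to the panel.
#' @param platform NGS platform label.
#' @param reference_platform array platform label (default from roles).
#' @return data.table: site, sample, discordant, depth, gc, homopolymer.
#' @export
discordance_observations <- function(tensor, features, platform,
                                     reference_platform =
                                       role_platform(tensor, "array_reference")) {
  a <- platform_pos(tensor, platform)
  b <- platform_pos(tensor, reference_platform)
  d <- platform_slice(tensor$depth, check_platform(tensor, platform))
  ns <- length(tensor$samples)
  dt <- data.table(site = rep(seq_len(nrow(tensor$panel)), times = ns),
                   sample = rep(tensor$samples, each = nrow(tensor$panel)),
                   discordant = as.vector(a != b),
                   depth = as.vector(d))
  dt[, gc := features$gc[site]]
  dt[, homopolymer := features$homopolymer[site]]
  dt[!is.na(depth)]
}

#' Keep observations within +/- 1 SD of the mean depth
#'
#' Mean and SD are computed over the input observations (per platform when a
#' `platform` column is present and `by_platform = TRUE`). With zero SD all
#' observations are retained.
#'
#' @param observations data.table with a `depth` column.
#' @param n_sd window half-width in SDs.
#' @param by_platform compute the window per `platform` group if present.
#' @return the filtered data.table.
#' @export
depth_window_filter <- function(observations, n_sd = 1, by_platform = TRUE) {
  obs <- as.data.table(observations)
  window <- function(d) {
    m <- mean(d); s <- sd(d)
    if (is.na(s) || s == 0) rep(TRUE, length(d)) else abs(d - m) <= n_sd * s
  }
  if (by_platform && "platform" %in% names(obs)) {
    obs[, keep__ := window(depth), by = platform]
  } else obs[, keep__ := window(depth)]
  out <- obs[keep__ == TRUE][, keep__ := NULL]
  out[]
}

#' Logistic regression of discordance on QC covariates
#'
#' Maximum-likelihood logistic regression of the discordance indicator on a
#' subset of `depth`, `gc`, `homopolymer` plus an intercept. Reports
#' coefficients with standard errors and McFadden's pseudo-R-squared
#' (`1 - logLik(model) / logLik(intercept-only)`), which is non-decreasing in
#' nested model specs. Complete separation is flagged, not fatal.
#'
#' @param observations data.table with logical `discordant` and the covariate
#'   columns (normally pre-filtered by [depth_window_filter()]).
#' @param model_spec non-empty subset of `c("depth", "gc", "homopolymer")`.
#' @param standardize center/scale covariates before fitting.
#' @return object of class `logistic_fit`: list with `model_spec`,
#'   `coefficients` (matrix with estimate/SE), `pseudo_r2`, `n`, `separation`.
#' @export
fit_discordance_model <- function(observations,
                                  model_spec = c("depth", "gc", "homopolymer"),
                                  standardize = FALSE) {
  obs <- as.data.table(observations)
  model_spec <- match.arg(model_spec, several.ok = TRUE)
  if (nrow(obs) < 10L) stop("fewer than 10 observations")
  dat <- obs[, c("discordant", model_spec), with = FALSE]
  dat <- dat[complete.cases(dat)]
  if (standardize)
    for (v in model_spec) dat[[v]] <- as.numeric(scale(dat[[v]]))
  form <- stats::as.formula(paste("discordant ~", paste(model_spec, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  null <- glm(discordant ~ 1, family = binomial(), data = dat)
  ll1 <- as.numeric(logLik(fit)); ll0 <- as.numeric(logLik(null))
  r2 <- if (ll0 == 0) 0 else 1 - ll1 / ll0
  sm <- summary(fit)$coefficients
  # residual deviance near zero = every observation perfectly classified
  if (!sep && (fit$deviance < 1e-6 || any(abs(coef(fit)[-1]) > 50))) sep <- TRUE
  structure(list(model_spec = model_spec,
                 coefficients = sm[, c("Estimate", "Std. Error"), drop = FALSE],
                 pseudo_r2 = r2, n = nrow(dat), separation = sep,
                 fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> discordant ~ %s  (n=%d, McFadden R2=%.4f%s)\n",
              paste(x$model_spec, collapse = " + "), x$n, x$pseudo_r2,
              if (x$separation) ", SEPARATION FLAGGED" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit the factor-combination table for one platform
#'
#' Fits the single-factor models `depth`, `gc`, `homopolymer` and the
#' combinations `depth+gc`, `depth+homopolymer`, `depth+gc+homopolymer`
#' on the same (depth-windowed) observations and tabulates the McFadden
#' pseudo-R-squared of each — the published layout for comparing QC factors.
#'
#' @param observations output of [discordance_observations()], already
#'   depth-window filtered (or not, caller's choice).
#' @param standardize see [fit_discordance_model()].
#' @return list with `table` (data.table model/pseudo_r2/n) and `fits`.
#' @export
fit_model_combinations <- function(observations, standardize = FALSE) {
  specs <- list(A = "depth", B = "gc", C = "homopolymer",
                `A + B` = c("depth", "gc"),
                `A + C` = c("depth", "homopolymer"),
                `A + B + C` = c("depth", "gc", "homopolymer"))
  fits <- lapply(specs, function(sp)
    fit_discordance_model(observations, sp, standardize = standardize))
  tab <- data.table(model = names(specs),
                    covariates = vapply(specs, paste, character(1), collapse = "+"),
                    pseudo_r2 = vapply(fits, `[[`, numeric(1), "pseudo_r2"),
                    n = vapply(fits, `[[`, numeric(1), "n"))
  list(table = tab, fits = fits)
}
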