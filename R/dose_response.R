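## Dose-response competition fitting: per-site four-parameter logistic fits
## on log2 site intensities, apparent IC50 with asymmetric 95% CI, and the
## competed/stable/ambiguous call.

## Competition is multiplicative on the intensity scale: the site intensity
## follows I(c) = B + (T - B) / (1 + (c / ic50)^h). Responses are the
## plotted log2 intensities, so the fitted mean function is
##   y(c) = log2( 2^bottom + (2^top - 2^bottom) / (1 + (c / ic50)^h) ),
## with top = log2 T and bottom = log2 B, parameterized internally by
## lic50 = log10(ic50 / nM). The DMSO control (c = 0) evaluates to top
## exactly, so the vehicle condition anchors the upper plateau without a
## pseudo-dose, and IC50 keeps its standard meaning: the concentration
## halving the background-subtracted intensity.

.fourpl <- function(dose, top, bottom, lic50, h) {
  log2(2^bottom + (2^top - 2^bottom) / (1 + (dose / 10^lic50)^h))
}

#' Fit a four-parameter logistic competition curve
#'
#' Least-squares fit of the competition model
#' `I(c) = B + (T - B) / (1 + (c/IC50)^h)` (intensity scale) to
#' per-replicate log2 site intensities, i.e. the fitted mean is
#' `y(c) = log2(2^bottom + (2^top - 2^bottom) / (1 + (c/IC50)^h))` with
#' `top = log2(T)` and `bottom = log2(B)`. IC50 is parameterized as
#' log10(IC50) and the Hill slope is bounded. A
#' deterministic multi-start scheme (plateau estimates from the extreme
#' doses; log10 IC50 started at every tested positive dose) guards against
#' local minima; the lowest-RSS converged start wins. Requires at least 4
#' distinct dose levels with data; never silently accepts a non-converged
#' optimum.
#'
#' @param dose Numeric vector of doses in nM (0 = DMSO), one per response.
#' @param response Numeric responses (log2 intensity); NA allowed.
#' @param hill_bounds Allowed Hill-slope range.
#' @param level Confidence level for the IC50 interval.
#' @return A `FourPLFit`: list with `top`, `bottom`, `hill`, `ic50`, `lic50`,
#'   `se_lic50`, `ci95` (nM, asymmetric), `rss`, `df`, `n`, `converged`,
#'   `call` (`"not_fit"` until classified, see [classify_site()]) and
#'   `flags`.
#' @export
fit_4pl <- function(dose, response, hill_bounds = c(0.1, 10), level = 0.95) {
  stopifnot(length(dose) == length(response), all(dose >= 0, na.rm = TRUE))
  ok <- !is.na(dose) & !is.na(response)
  d <- dose[ok]; y <- response[ok]
  base <- structure(
    list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
         ic50 = NA_real_, lic50 = NA_real_, se_lic50 = NA_real_,
         ci95 = c(NA_real_, NA_real_), rss = NA_real_, df = NA_integer_,
         n = length(y), converged = FALSE, call = "not_fit",
         flags = character(0)),
    class = "FourPLFit")
  if (length(unique(d)) < 4L) {
    base$flags <- "fewer than 4 distinct dose levels"
    return(base)
  }
  if (stats::sd(y) == 0) {
    ## perfectly flat data: no competition signal, IC50 undefined
    base$top <- base$bottom <- y[1]
    base$rss <- 0; base$df <- length(y) - 1L
    base$call <- "stable"; base$converged <- TRUE
    base$flags <- "flat responses"
    return(base)
  }
  pos <- sort(unique(d[d > 0]))
  lo_d <- min(pos); hi_d <- max(pos)
  top0 <- mean(y[d == min(d)])
  bot0 <- mean(y[d == max(d)])
  starts <- c(log10(pos), log10(sqrt(lo_d * hi_d)))
  lower <- c(top = -Inf, bottom = -Inf,
             lic50 = log10(lo_d) - 4, h = hill_bounds[1])
  upper <- c(top = Inf, bottom = Inf,
             lic50 = log10(hi_d) + 4, h = hill_bounds[2])
  dat <- data.frame(d = d, y = y)
  try_start <- function(t0, b0, s) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ log2(2^bottom + (2^top - 2^bottom) / (1 + (d / 10^lic50)^h)),
        data = dat,
        start = list(top = t0, bottom = b0, lic50 = s, h = 1),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
  }
  best <- NULL
  for (s in starts) {
    fit <- try_start(top0, bot0, s)
    if (is.null(fit)) {
      ## near-flat data make the Jacobian singular when the plateau starts
      ## coincide; retry with a separated bottom start
      fit <- try_start(top0, top0 - 1, s)
    }
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    ## derivative-free fallback; no parameter covariance available
    obj <- function(p) {
      p[3] <- min(max(p[3], lower["lic50"]), upper["lic50"])
      p[4] <- min(max(p[4], lower["h"]), upper["h"])
      sum((y - .fourpl(d, p[1], p[2], p[3], p[4]))^2)
    }
    op <- stats::optim(c(top0, top0 - 1, stats::median(starts), 1), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (!is.finite(op$value)) {
      base$flags <- "optimizer failed from all starts"
      return(base)
    }
    out <- base
    out$top <- op$par[1]; out$bottom <- op$par[2]
    out$lic50 <- min(max(op$par[3], lower["lic50"]), upper["lic50"])
    out$hill <- min(max(op$par[4], lower["h"]), upper["h"])
    out$ic50 <- 10^out$lic50
    out$rss <- op$value
    out$df <- length(y) - 4L
    out$converged <- TRUE
    out$se_lic50 <- NA_real_
    out$ci95 <- c(0, Inf)
    out$flags <- "covariance unavailable (fallback optimizer)"
    return(out)
  }
  cf <- stats::coef(best$fit)
  out <- base
  out$top <- unname(cf["top"]); out$bottom <- unname(cf["bottom"])
  out$hill <- unname(cf["h"]); out$lic50 <- unname(cf["lic50"])
  out$ic50 <- 10^out$lic50
  out$rss <- best$rss
  out$df <- length(y) - 4L
  out$converged <- TRUE
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit)))["lic50"],
                 error = function(e) NA_real_)
  out$se_lic50 <- unname(se)
  out$ci95 <- ic50_confidence_interval(out, level = level)
  if (out$ic50 < lo_d || out$ic50 > hi_d) {
    out$flags <- c(out$flags, "IC50 outside tested dose range (extrapolated)")
  }
  if (abs(out$hill - hill_bounds[1]) < 1e-8 ||
      abs(out$hill - hill_bounds[2]) < 1e-8) {
    out$flags <- c(out$flags, "Hill slope at bound")
  }
  out
}

#' @export
print.FourPLFit <- function(x, ...) {
  if (!x$converged) {
    cat("FourPLFit: not converged (", paste(x$flags, collapse = "; "), ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "FourPLFit: IC50 = %.3g nM (95%% CI %.3g-%.3g), hill = %.2f, top = %.2f, bottom = %.2f, call = %s\n",
    x$ic50, x$ci95[1], x$ci95[2], x$hill, x$top, x$bottom, x$call))
  invisible(x)
}

#' Asymptotic confidence interval for the fitted IC50
#'
#' Wald interval on log10(IC50) from the residual-variance-scaled parameter
#' covariance, back-transformed to nM — hence asymmetric around the IC50 on
#' the concentration scale (e.g. 17 nM with CI 10-28 nM). A singular
#' covariance yields an unbounded interval, flagged rather than hidden.
#'
#' @param fit A converged `FourPLFit`.
#' @param level Confidence level.
#' @return `c(low, high)` in nM.
#' @export
ic50_confidence_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "FourPLFit"))
  if (!fit$converged || is.na(fit$lic50)) return(c(NA_real_, NA_real_))
  se <- fit$se_lic50
  if (is.na(se) || !is.finite(se)) return(c(0, Inf))
  df <- max(fit$df, 1L)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  10^(fit$lic50 + c(-1, 1) * tq * se)
}

#' Classify a site as competed, stable or ambiguous
#'
#' A site is called *competed* when (i) the 4PL model beats the constant
#' (no-competition) model in an extra-sum-of-squares F-test at p < 0.05,
#' (ii) the fitted dynamic range `top - bottom` is at least 1 log2 unit, and
#' (iii) the IC50 falls within `min positive dose / 10` to `max dose * 10`.
#' It is called *stable* when the F-test is not significant (p >= 0.05);
#' anything else (significant but shallow or out-of-range) is *ambiguous*.
#'
#' @param fit A `FourPLFit`.
#' @param dose,response The data the fit was attempted on.
#' @param p_threshold F-test significance threshold.
#' @param min_drop Minimum fitted log2 drop to call competition.
#' @return The fit with its `call` field set, plus `p_value` and `f_stat`.
#' @export
classify_site <- function(fit, dose, response, p_threshold = 0.05,
                          min_drop = 1) {
  stopifnot(inherits(fit, "FourPLFit"))
  if (!fit$converged) {
    fit$call <- if (identical(fit$call, "stable")) "stable" else "not_fit"
    return(fit)
  }
  if (!is.na(fit$rss) && fit$rss == 0 && is.na(fit$ic50)) {
    return(fit)  # flat-data shortcut already called stable
  }
  ok <- !is.na(dose) & !is.na(response)
  y <- response[ok]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- fit$rss
  df1 <- n - 4L
  if (df1 <= 0L) {
    fit$call <- "ambiguous"
    fit$flags <- c(fit$flags, "no residual degrees of freedom")
    return(fit)
  }
  f <- max(0, (rss0 - rss1) / 3) / (rss1 / df1)
  p <- stats::pf(f, 3, df1, lower.tail = FALSE)
  fit$f_stat <- f
  fit$p_value <- p
  pos <- dose[ok & dose > 0]
  in_range <- !is.na(fit$ic50) &&
    fit$ic50 >= min(pos) / 10 && fit$ic50 <= max(dose[ok]) * 10
  drop_ok <- !is.na(fit$top) && (fit$top - fit$bottom) >= min_drop
  fit$call <- if (p >= p_threshold) "stable"
              else if (drop_ok && in_range) "competed"
              else "ambiguous"
  fit
}

#' Fit competition curves for every site and protease
#'
#' Builds one dose series per (site, protease) from the log2 layer of the
#' site matrix and fits it independently — evidence is never pooled across
#' proteases, so a site detected by both digests yields two rows. Ordering
#' is deterministic (site key, then protease).
#'
#' @param sqm A `SiteQuantMatrix`.
#' @param p_threshold,min_drop Classification thresholds, see
#'   [classify_site()].
#' @return data.frame with one row per site x protease: identifiers, call,
#'   `ic50_nM`, `ci_low_nM`, `ci_high_nM`, `hill`, `top`, `bottom`, `rss`,
#'   `p_value`, `n_points`, `converged`, `flags`.
#' @export
fit_all_sites <- function(sqm, p_threshold = 0.05, min_drop = 1) {
  stopifnot(inherits(sqm, "SiteQuantMatrix"))
  ann <- sqm$annotation
  proteases <- sort(unique(ann$protease), method = "radix")
  keys <- rownames(sqm$log2)
  rows <- list()
  for (key in keys) {
    for (prot in proteases) {
      ids <- ann$sample_id[ann$protease == prot]
      ids <- intersect(ids, colnames(sqm$log2))
      if (length(ids) == 0L) next
      y <- sqm$log2[key, ids]
      if (all(is.na(y))) next
      d <- ann$dose[match(ids, ann$sample_id)]
      fit <- fit_4pl(d, y)
      fit <- classify_site(fit, d, y, p_threshold = p_threshold,
                           min_drop = min_drop)
      site_row <- sqm$sites[sqm$sites$site_key == key, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        site_key = key,
        site_id = if (nrow(site_row) == 1L) site_row$site_id else key,
        protease = prot,
        call = fit$call,
        ic50_nM = fit$ic50,
        ci_low_nM = fit$ci95[1], ci_high_nM = fit$ci95[2],
        hill = fit$hill, top = fit$top, bottom = fit$bottom,
        rss = fit$rss,
        p_value = if (is.null(fit$p_value)) NA_real_ else fit$p_value,
        n_points = sum(!is.na(y)),
        converged = fit$converged,
        flags = paste(fit$flags, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  out <- .bind_or_empty(rows, data.frame(
    site_key = character(0), site_id = character(0), protease = character(0),
    call = character(0), ic50_nM = numeric(0), ci_low_nM = numeric(0),
    ci_high_nM = numeric(0), hill = numeric(0), top = numeric(0),
    bottom = numeric(0), rss = numeric(0), p_value = numeric(0),
    n_points = integer(0), converged = logical(0), flags = character(0)))
  out <- out[order(out$site_key, out$protease, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
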