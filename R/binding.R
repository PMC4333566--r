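# Competition-binding dose-response fitting: variable-slope sigmoidal
# (four-parameter logistic) model
#   Y = bottom + (top - bottom) / (1 + 10^((log10(IC50) - log10(X)) * hill))
# parameterised internally by pIC50 = -log10(IC50 in M).

#' Construct a dose-response dataset
#'
#' @param concentration molar concentrations of the competing compound
#'   (> 0).
#' @param signal measured bound radioligand (raw counts or percent of B0).
#' @param b0 optional binding in the absence of competitor, used by
#'   [normalize_b0()].
#' @return a data.frame of class `dose_response` with attribute `b0`.
#' @export
dose_response <- function(concentration, signal, b0 = NULL) {
  stopifnot(length(concentration) == length(signal))
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be finite and positive (molar)")
  }
  if (any(!is.finite(signal))) stop("signal values must be finite")
  out <- data.frame(concentration = concentration, signal = signal)
  attr(out, "b0") <- b0
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Normalize a dose-response dataset to percent of B0
#'
#' B0 is the bound radioligand signal without competitor; the normalized
#' signal is `100 * signal / b0`, so the uninhibited level reads 100.
#'
#' @param data a `dose_response` with a `b0` attribute (or `b0` supplied).
#' @param b0 override for the stored B0 value.
#' @return a `dose_response` in percent-of-B0 units (`b0` becomes 100).
#' @export
normalize_b0 <- function(data, b0 = attr(data, "b0")) {
  stopifnot(inherits(data, "dose_response"))
  if (is.null(b0)) stop("no B0 value available for normalization")
  if (b0 <= 0) stop("B0 must be positive")
  out <- dose_response(data$concentration, 100 * data$signal / b0, b0 = 100)
  out
}

# 4PL forward model on molar concentrations.
fourpl <- function(conc, pIC50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^(((-pIC50) - log10(conc)) * hill))
}

#' Fit a variable-slope sigmoidal dose-response curve
#'
#' Bounded Levenberg-Marquardt least squares (via
#' [minpack.lm::nlsLM()]) of the four-parameter logistic model, with
#' data-driven starting values and three additional jittered starts to
#' escape poor basins. Requires at least 5 distinct concentrations spanning
#' at least 2 log units. Flat curves (no resolvable inhibition/stimulation)
#' are flagged rather than fitted.
#'
#' @param data a `dose_response`.
#' @param init optional named list overriding starting values
#'   (`pIC50`, `hill`, `top`, `bottom`).
#' @return an object of class `fit_4pl`: list with `pIC50`, `hill_slope`,
#'   `top`, `bottom`, `se` (named standard errors), `rss`, `converged`,
#'   `no_inhibition`, `at_bounds`, and `fitted` values. When
#'   `no_inhibition` is `TRUE`, `pIC50` is `NA`.
#' @export
fit_dose_response <- function(data, init = NULL) {
  stopifnot(inherits(data, "dose_response"))
  conc <- data$concentration
  sig <- data$signal
  if (length(unique(conc)) < 5L) {
    stop("need at least 5 distinct concentrations")
  }
  if (diff(range(log10(conc))) < 2) {
    stop("concentrations must span at least 2 log10 units")
  }

  flat_result <- function() {
    structure(list(pIC50 = NA_real_, hill_slope = NA_real_,
                   top = mean(sig), bottom = mean(sig),
                   se = c(pIC50 = NA, hill = NA, top = NA, bottom = NA),
                   rss = sum((sig - mean(sig))^2), converged = TRUE,
                   no_inhibition = TRUE, at_bounds = FALSE,
                   fitted = rep(mean(sig), length(sig)), data = data),
              class = "fit_4pl")
  }
  if (diff(range(sig)) <= 1e-9 * max(1, abs(mean(sig)))) return(flat_result())

  # starting values: asymptotes from the data, IC50 at half-maximal signal,
  # hill sign from the response direction
  half <- (max(sig) + min(sig)) / 2
  direction <- sign(stats::cor(log10(conc), sig))
  if (is.na(direction) || direction == 0) direction <- -1
  start0 <- list(pIC50 = -log10(conc[which.min(abs(sig - half))]),
                 hill = direction, top = max(sig), bottom = min(sig))
  if (!is.null(init)) start0[names(init)] <- init

  lo <- c(pIC50 = -log10(max(conc) * 100), hill = -10,
          top = min(sig) - 2 * diff(range(sig)),
          bottom = min(sig) - 2 * diff(range(sig)))
  hi <- c(pIC50 = -log10(min(conc) / 100), hill = 10,
          top = max(sig) + 2 * diff(range(sig)),
          bottom = max(sig) + 2 * diff(range(sig)))

  starts <- list(start0)
  with_seed(derive_seed(1203, "fit4pl-jitter"), {
    for (k in 1:3) {
      s <- start0
      s$pIC50 <- s$pIC50 + rnorm(1, 0, 0.5)
      s$hill <- s$hill * runif(1, 0.5, 2)
      starts[[k + 1]] <- s
    }
  })

  df <- data.frame(conc = conc, sig = sig)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        sig ~ fourpl(conc, pIC50, hill, top, bottom),
        data = df, start = s, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(pIC50 = NA_real_, hill_slope = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          se = c(pIC50 = NA, hill = NA, top = NA, bottom = NA),
                          rss = NA_real_, converged = FALSE,
                          no_inhibition = FALSE, at_bounds = FALSE,
                          fitted = rep(NA_real_, length(sig)), data = data),
                     class = "fit_4pl"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    setNames(rep(NA_real_, 4), names(cf)))
  # canonical orientation: top > bottom (swapping asymptotes is exactly
  # equivalent to negating the hill slope)
  if (cf["top"] < cf["bottom"]) {
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    se[c("top", "bottom")] <- se[c("bottom", "top")]
    cf["hill"] <- -cf["hill"]
  }
  sigma_hat <- sqrt(best$rss / max(1, length(sig) - 4))
  no_inh <- abs(cf["top"] - cf["bottom"]) < 3 * sigma_hat
  at_bounds <- any(abs(cf - lo[names(cf)]) < 1e-6) ||
    any(abs(cf - hi[names(cf)]) < 1e-6)
  structure(list(
    pIC50 = if (no_inh) NA_real_ else unname(cf["pIC50"]),
    hill_slope = unname(cf["hill"]),
    top = unname(cf["top"]),
    bottom = unname(cf["bottom"]),
    se = setNames(as.numeric(se[c("pIC50", "hill", "top", "bottom")]),
                  c("pIC50", "hill", "top", "bottom")),
    rss = best$rss,
    converged = TRUE,
    no_inhibition = unname(no_inh),
    at_bounds = at_bounds,
    fitted = stats::fitted(best$fit),
    data = data), class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  if (x$no_inhibition) {
    cat("4PL fit: no resolvable inhibition (flat curve); pIC50 undefined\n")
  } else if (!x$converged) {
    cat("4PL fit: did not converge\n")
  } else {
    cat(sprintf(
      "4PL fit: pIC50 %.3f (SE %.3f), hill %.2f, top %.1f, bottom %.1f, RSS %.3g\n",
      x$pIC50, x$se["pIC50"], x$hill_slope, x$top, x$bottom, x$rss))
  }
  invisible(x)
}

#' Read dose-response experiments from CSV
#'
#' Expects columns `experiment_id`, `concentration_M`, `signal`, and
#' optionally `b0`.
#'
#' @param path CSV path.
#' @return data.frame with the columns above.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "concentration_M", "signal")
  if (!all(need %in% names(df))) {
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Fit every experiment in a dose-response table
#'
#' Per-experiment 4PL fits (on percent-of-B0 when a `b0` column is present
#' and `normalize = TRUE`), followed by the replicate summary: mean and SD
#' of the per-experiment pIC50 values — replicate aggregation is over
#' independent fits, not a pooled fit.
#'
#' @param df table from [read_dose_response_csv()].
#' @param normalize normalize to %B0 when available? Default `TRUE`.
#' @return list with `fits` (named by experiment) and `summary`
#'   (data.frame `n`, `mean_pIC50`, `sd_pIC50`, `n_no_inhibition`).
#' @export
fit_binding_experiments <- function(df, normalize = TRUE) {
  ids <- unique(df$experiment_id)
  fits <- lapply(ids, function(id) {
    sub <- df[df$experiment_id == id, ]
    b0 <- if ("b0" %in% names(sub)) sub$b0[1] else NULL
    dr <- dose_response(sub$concentration_M, sub$signal, b0 = b0)
    if (normalize && !is.null(b0) && is.finite(b0)) dr <- normalize_b0(dr)
    fit_dose_response(dr)
  })
  names(fits) <- ids
  p <- vapply(fits, function(f) f$pIC50, numeric(1))
  ok <- !is.na(p)
  list(fits = fits,
       summary = data.frame(
         n = length(ids),
         mean_pIC50 = if (any(ok)) mean(p[ok]) else NA_real_,
         sd_pIC50 = if (sum(ok) > 1L) sd(p[ok]) else NA_real_,
         n_no_inhibition = sum(vapply(fits, function(f) f$no_inhibition,
                                      logical(1)))))
}
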