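#' Fit the exponential washout model
#'
#' Nonlinear least-squares fit of `c(t) = aw * exp(-bw * t)` to retained
#' concentration against washout time. With all-positive concentrations
#' the fit is initialized by log-linear regression (which is already exact
#' on noiseless data); otherwise a direct NLS from
#' `aw0 = max(c)`, `bw0 = 1 / range(t)` is attempted. A constant series
#' (zero log-slope) is returned flagged `degenerate` — the decay rate sits
#' on the `bw = 0` boundary and no washout time is defined. A fit that
#' fails outright returns a `fit_failure` object.
#'
#' @param times washout times, hours (>= 3 points).
#' @param concentrations retained concentrations, mgI/mL.
#' @return An object of class `washout_fit`: `aw` (mgI/mL), `bw` (1/h),
#'   `r2`, `residuals`, `n`, `degenerate`; or a `fit_failure`.
#' @export
#' @examples
#' w <- simulate_washout_curve(10, 0.01)
#' fit_washout(w$times, w$concentration)
fit_washout <- function(times, concentrations) {
  if (length(times) != length(concentrations))
    stopf("times (%d) and concentrations (%d) lengths differ",
          length(times), length(concentrations))
  if (length(times) < 3L) stopf("at least 3 washout points are required")

  if (all(concentrations > 0)) {
    ll <- stats::lm(log(concentrations) ~ times)
    aw0 <- exp(unname(coef(ll)[1])); bw0 <- -unname(coef(ll)[2])
  } else {
    aw0 <- max(concentrations, 1e-6); bw0 <- 1 / diff(range(times))
  }
  if (is.finite(bw0) && abs(bw0) < 1e-12) {
    return(structure(
      list(aw = mean(concentrations), bw = 0, r2 = NA_real_,
           residuals = concentrations - mean(concentrations),
           n = length(times), degenerate = TRUE),
      class = "washout_fit"))
  }
  if (bw0 <= 0) bw0 <- 1e-6

  fit <- tryCatch(
    minpack.lm::nlsLM(concentrations ~ aw * exp(-bw * times),
                      start = list(aw = aw0, bw = bw0),
                      lower = c(aw = 1e-12, bw = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(message = "washout fit failed to converge"),
                     class = c("washout_fit_failure", "fit_failure")))
  est <- coef(fit)
  res <- stats::resid(fit)
  tss <- sum((concentrations - mean(concentrations))^2)
  structure(
    list(aw = unname(est["aw"]), bw = unname(est["bw"]),
         r2 = if (tss > 0) 1 - sum(res^2) / tss else 1,
         residuals = as.numeric(res), n = length(times),
         degenerate = unname(est["bw"]) <= 0),
    class = "washout_fit"
  )
}

#' Washout time to 5% of a reference concentration
#'
#' Solves `aw * exp(-bw * t) = 0.05 * reference` for `t`: the time for the
#' retained contrast to fall to 5% of the reference level (conventionally
#' the concentration reached after the 24-h immersion). With
#' `reference = aw` this is `ln(20) / bw`. If the fitted curve already
#' starts below the 5% level the time is undefined and an error is
#' signalled; exactly at the level the answer is 0.
#'
#' @param fit a `washout_fit`.
#' @param reference reference concentration, mgI/mL (> 0).
#' @return Washout time, hours.
#' @export
washout_time <- function(fit, reference) {
  if (inherits(fit, "fit_failure"))
    stopf("cannot derive a washout time: %s", fit$message)
  stopifnot(inherits(fit, "washout_fit"))
  if (isTRUE(fit$degenerate))
    stopf("degenerate washout fit (bw = 0): washout time undefined")
  check_scalar_pos(reference, "reference")
  level <- 0.05 * reference
  if (level > fit$aw)
    stopf("fitted curve starts below 5%% of the reference; washout time undefined")
  log(fit$aw / level) / fit$bw
}

#' @export
print.washout_fit <- function(x, ...) {
  if (isTRUE(x$degenerate))
    cat(sprintf("Washout fit (degenerate): aw = %.5g, bw at 0 boundary\n", x$aw))
  else
    cat(sprintf("Washout fit: aw = %.5g mgI/mL, bw = %.5g 1/h, r2 = %.4f (n = %d)\n",
                x$aw, x$bw, x$r2, x$n))
  invisible(x)
}

#' Cohen's d effect size
#'
#' Standardized mean difference with pooled standard deviation
#' `sqrt(((nx-1) sx^2 + (ny-1) sy^2) / (nx + ny - 2))`. Reported as a
#' magnitude by default (the convention used in tissue-distinguishability
#' tables); `signed = TRUE` keeps the sign of `mean(x) - mean(y)`. Equal
#' samples give 0; a zero pooled SD with unequal means is signalled as an
#' infinite effect with a warning.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param signed keep the sign of the mean difference?
#' @return Effect size `d`.
#' @export
#' @examples
#' cohens_d(c(2, 4), c(0, 2))  # sqrt(2)
cohens_d <- function(x, y, signed = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stopf("each sample needs at least 2 values")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (dm == 0) return(0)
    warning("zero pooled SD with unequal means: infinite effect size",
            call. = FALSE)
    return(if (signed) sign(dm) * Inf else Inf)
  }
  d <- dm / sqrt(sp2)
  if (signed) d else abs(d)
}

#' Nonparametric two-sample battery: Kolmogorov-Smirnov and Mann-Whitney
#'
#' Runs the two-sided two-sample Kolmogorov-Smirnov test (statistic
#' `sup |ECDF_x - ECDF_y|`, asymptotic p-value) and the two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. The Mann-Whitney p-value is
#' exact when both samples have at most 8 observations and no ties are
#' present; otherwise the normal approximation with midranks and tie
#' correction is used. Rejection flags are evaluated at `alpha`.
#'
#' @param x,y numeric samples (nonempty; ties permitted).
#' @param alpha significance level for the rejection flags.
#' @param ks_exact compute the exact KS p-value instead of the asymptotic
#'   one (small samples only).
#' @return List: `ks_D`, `ks_p`, `mw_U`, `mw_p`, `reject_ks`, `reject_mw`,
#'   `alpha`.
#' @export
two_sample_tests <- function(x, y, alpha = 0.05, ks_exact = FALSE) {
  if (length(x) == 0L || length(y) == 0L) stopf("samples must be nonempty")
  ks <- suppressWarnings(stats::ks.test(x, y, exact = ks_exact))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact_mw <- length(x) <= 8L && length(y) <= 8L && !ties
  mw <- suppressWarnings(stats::wilcox.test(x, y, exact = exact_mw,
                                            correct = !exact_mw))
  list(ks_D = unname(ks$statistic), ks_p = ks$p.value,
       mw_U = unname(mw$statistic), mw_p = mw$p.value,
       reject_ks = ks$p.value < alpha, reject_mw = mw$p.value < alpha,
       alpha = alpha)
}

#' One-sample normality check
#'
#' Kolmogorov-Smirnov-type check that a sample is consistent with a
#' normal distribution. Two reference conventions are provided and the
#' one used is always recorded in the output:
#' * `"estimated"` (default): mean and SD estimated from the sample, with
#'   the Lilliefors correction of the null distribution (via
#'   `nortest::lillie.test`) — the statistically sound choice when the
#'   normal parameters are unknown;
#' * `"standard"`: plain one-sample KS of the standardized sample against
#'   N(0, 1), which ignores the parameter estimation and is
#'   anti-conservative.
#'
#' @param x numeric sample (n >= 5, non-constant).
#' @param alpha significance level.
#' @param reference `"estimated"` or `"standard"`.
#' @return List: `statistic`, `p`, `pass` (`TRUE` when not rejected at
#'   `alpha`), `reference`, `alpha`.
#' @export
normality_check <- function(x, alpha = 0.05,
                            reference = c("estimated", "standard")) {
  reference <- match.arg(reference)
  if (length(x) < 5L) stopf("at least 5 observations are required")
  if (sd(x) == 0) stopf("constant sample: normality check undefined")
  res <- if (reference == "estimated") {
    lt <- nortest::lillie.test(x)
    list(statistic = unname(lt$statistic), p = lt$p.value)
  } else {
    z <- (x - mean(x)) / sd(x)
    kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
    list(statistic = unname(kt$statistic), p = kt$p.value)
  }
  c(res, list(pass = res$p >= alpha, reference = reference, alpha = alpha))
}

#' Tissue distinguishability table
#'
#' Pairwise comparison of attenuation samples from connective tissue (L),
#' bone (B) and cartilage (C): Cohen's d (magnitude), KS p-value and
#' Mann-Whitney p-value for each tissue pair, in the conventional row
#' order L-B, B-C, C-L.
#'
#' @param connective,bone,cartilage numeric attenuation samples.
#' @param alpha significance level passed to [two_sample_tests()].
#' @return Data frame with columns `pair`, `cohens_d`, `ks_p`, `mw_p`.
#' @export
tissue_distinguishability <- function(connective, bone, cartilage,
                                      alpha = 0.05) {
  pairs <- list("L-B" = list(connective, bone),
                "B-C" = list(bone, cartilage),
                "C-L" = list(cartilage, connective))
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    ts <- two_sample_tests(p[[1]], p[[2]], alpha = alpha)
    data.frame(pair = nm, cohens_d = cohens_d(p[[1]], p[[2]]),
               ks_p = ts$ks_p, mw_p = ts$mw_p)
  })
  do.call(rbind, rows)
}
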