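#' Likelihood-ratio test between nested maximum-likelihood fits
#'
#' `chi^2 = 2 (logLik_1 - logLik_0)` (clipped at zero) referred to a
#' chi-square distribution with degrees of freedom equal to the
#' parameter-count difference. The fits must be of the same model family,
#' fitted to the same rows and the same outcome, with the null model's
#' fixed terms a subset of the alternative's.
#'
#' @param fit0 The null (smaller) fit, `mh_lmm` or `mh_clmm`.
#' @param fit1 The alternative (larger) fit of the same class.
#' @return A one-row tibble: `n`, `chisq`, `df`, `p.value`, `cohens_w`.
#' @examples
#' trial <- generate_trial(seed = 1)
#' lrt(fit_lmm(trial, isr ~ 1), fit_lmm(trial, isr ~ strategy))
#' @export
lrt <- function(fit0, fit1) {
  ok_class <- (inherits(fit0, "mh_lmm") && inherits(fit1, "mh_lmm")) ||
    (inherits(fit0, "mh_clmm") && inherits(fit1, "mh_clmm"))
  if (!ok_class) {
    abort("`fit0` and `fit1` must both be mh_lmm or both mh_clmm fits.")
  }
  if (fit0$n_obs != fit1$n_obs) {
    abort("Fits use different numbers of observations; refit on common rows.")
  }
  if (!identical(fit0$outcome, fit1$outcome)) {
    abort("Fits model different outcomes.")
  }
  if (!all(fit0$term_labels %in% fit1$term_labels) ||
      fit1$n_params < fit0$n_params) {
    abort("`fit0` must be nested in `fit1`.")
  }
  if (fit1$n_params == fit0$n_params &&
      !setequal(fit0$term_labels, fit1$term_labels)) {
    abort("`fit0` must be nested in `fit1`.")
  }
  if (isFALSE(fit0$converged) || isFALSE(fit1$converged)) {
    abort("Likelihood-ratio test on a non-converged fit.")
  }
  df <- fit1$n_params - fit0$n_params
  chi2 <- max(0, 2 * (fit1$loglik - fit0$loglik))
  p <- if (df == 0L) 1 else pchisq(chi2, df, lower.tail = FALSE)
  tibble(n = fit0$n_obs, chisq = chi2, df = df, p.value = p,
         cohens_w = cohen_w(chi2, fit0$n_obs))
}

#' Cohen's w effect size for a chi-square statistic
#'
#' `w = sqrt(chisq / n)`; invariant under joint rescaling of `chisq` and
#' `n`.
#'
#' @param chisq Chi-square statistic (>= 0).
#' @param n Number of observations (> 0).
#' @return Numeric effect size(s).
#' @examples
#' cohen_w(142.98, 477)
#' @export
cohen_w <- function(chisq, n) {
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(chisq < 0)) abort("`chisq` must be non-negative.")
  sqrt(chisq / n)
}

#' Pseudo-R-squared for a nested model comparison
#'
#' Both the McFadden (`1 - logLik_1 / logLik_0`) and Nagelkerke
#' (likelihood-ratio based, rescaled to a 0-1 maximum) variants are
#' reported; published pseudo-R2 values computed by unspecified methods may
#' match either, both, or neither, so no single variant is privileged.
#'
#' @inheritParams lrt
#' @return One-row tibble: `mcfadden`, `nagelkerke`.
#' @export
pseudo_r2 <- function(fit0, fit1) {
  n <- fit0$n_obs
  ll0 <- fit0$loglik; ll1 <- fit1$loglik
  mcfadden <- 1 - ll1 / ll0
  nagelkerke <- (1 - exp(-2 / n * (ll1 - ll0))) /
    (1 - exp(2 / n * ll0))
  tibble(mcfadden = mcfadden, nagelkerke = nagelkerke)
}

#' Manipulation check: did respondents read the scenarios as scripted?
#'
#' For each manipulated scenario variable (severity, stance), fits
#' cumulative-link mixed models of the reported level with and without the
#' scripted level (coded -1/0/1, one degree of freedom) and compares them
#' by likelihood ratio, with Cohen's w and pseudo-R2 for the comparison.
#'
#' @param data Trial data with `perceived_severity`, `perceived_stance`,
#'   `severity`, `stance` and the grouping column.
#' @param group Grouping column name.
#' @param n_quad Gauss-Hermite nodes for the ordinal fits.
#' @return Tibble with one row per check: `check`, `n`, `chisq`, `df`,
#'   `p.value`, `cohens_w`, `r2_mcfadden`, `r2_nagelkerke`.
#' @export
manipulation_check <- function(data, group = "participant_id",
                               n_quad = 15L) {
  checks <- list(
    severity = list(reported = "perceived_severity", scripted = "severity",
                    levels = .mh_levels$severity),
    stance = list(reported = "perceived_stance", scripted = "stance",
                  levels = .mh_levels$stance)
  )
  purrr::imap_dfr(checks, function(ch, nm) {
    d <- data
    d$scripted_code <- match(as.character(d[[ch$scripted]]), ch$levels) - 2L
    f1 <- stats::reformulate("scripted_code", response = ch$reported)
    f0 <- stats::reformulate("1", response = ch$reported)
    fit0 <- fit_clmm(d, f0, group = group, n_quad = n_quad)
    fit1 <- fit_clmm(d, f1, group = group, n_quad = n_quad)
    res <- lrt(fit0, fit1)
    r2 <- pseudo_r2(fit0, fit1)
    tibble(check = nm, n = res$n, chisq = res$chisq, df = res$df,
           p.value = res$p.value, cohens_w = res$cohens_w,
           r2_mcfadden = r2$mcfadden, r2_nagelkerke = r2$nagelkerke)
  })
}
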