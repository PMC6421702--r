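#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + b_group + e`, with `b_group ~ N(0, sigma_p^2)` and
#' `e ~ N(0, sigma_e^2)`, by full maximum likelihood (not REML, because the
#' model comparisons of interest are likelihood-ratio tests on fixed
#' effects). The likelihood is profiled analytically down to the single
#' variance ratio `theta = sigma_p^2 / sigma_e^2`: for fixed `theta` the GLS
#' fixed effects and the residual variance have closed forms through the
#' Woodbury identity on each group's compound-symmetric block, and `theta`
#' is then optimised on `[0, 1e4]` by golden-section search with tolerance
#' `1e-10`. The `theta = 0` boundary (no participant variance) is checked
#' explicitly.
#'
#' Factors entering the fixed part are coded with sum-to-zero contrasts, so
#' the intercept estimates the grand mean and its deviation from the
#' neutral score 0 can be tested directly (see [wald_intercept()]).
#'
#' @param data Long-format data frame (one row per scenario-chat).
#' @param formula Fixed-effects formula, e.g. `isr ~ situation + strategy`
#'   or `isr ~ 1`. Character predictors are converted to factors.
#' @param group Name of the grouping column (default `"participant_id"`).
#' @return An object of class `mh_lmm` with components `beta`, `sigma_p`,
#'   `sigma_e`, `theta`, `loglik`, `n_obs`, `n_groups`, `n_params`,
#'   `vcov_beta`, `converged`, plus bookkeeping used by [lrt()].
#' @examples
#' trial <- generate_trial(seed = 1)
#' fit0 <- fit_lmm(trial, isr ~ 1)
#' fit1 <- fit_lmm(trial, isr ~ strategy)
#' lrt(fit0, fit1)
#' @export
fit_lmm <- function(data, formula, group = "participant_id") {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  if (!group %in% names(data)) {
    abort(sprintf("Grouping column '%s' not found.", group))
  }
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Column(s) not found in data: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[c(vars, group)])
  data <- data[keep, , drop = FALSE]

  mf_data <- prepare_model_factors(data, setdiff(vars, vars[1]))
  mf <- stats::model.frame(formula, mf_data)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) abort("The outcome must be numeric (a centred score).")
  X <- sum_contrast_matrix(formula, mf)
  g <- factor(data[[group]])

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Fixed-effect design is rank deficient; aliased term(s): %s.",
                  paste(aliased, collapse = ", ")))
  }

  fit <- profile_ml_random_intercept(y, X, g)
  structure(
    c(fit,
      list(formula = formula, outcome = vars[1],
           term_labels = attr(stats::terms(formula), "term.labels"),
           group = group, n_groups = nlevels(g),
           n_params = length(fit$beta) + 2L)),
    class = "mh_lmm"
  )
}

prepare_model_factors <- function(data, predictor_vars) {
  for (v in predictor_vars) {
    col <- data[[v]]
    if (is.character(col) || is.numeric(col) && v == "situation") {
      canonical <- switch(v,
        strategy = .mh_levels$strategy,
        situation = as.character(1:9),
        stance = .mh_levels$stance,
        severity = .mh_levels$severity,
        sit_type = .mh_levels$sit_type,
        NULL)
      lv <- if (!is.null(canonical)) {
        intersect(canonical, unique(as.character(col)))
      } else {
        sort(unique(as.character(col)))
      }
      data[[v]] <- factor(as.character(col), levels = lv)
    } else if (is.factor(col)) {
      data[[v]] <- droplevels(col)
    }
  }
  data
}

sum_contrast_matrix <- function(formula, mf) {
  fvars <- names(mf)[vapply(mf, is.factor, logical(1))]
  contrasts_arg <- if (length(fvars)) {
    stats::setNames(rep(list("contr.sum"), length(fvars)), fvars)
  } else NULL
  X <- stats::model.matrix(formula, mf, contrasts.arg = contrasts_arg)
  # keep the factor level name in sum-coded column labels
  for (v in fvars) {
    lv <- levels(mf[[v]])
    for (i in seq_len(length(lv) - 1)) {
      colnames(X) <- sub(paste0("^", v, i, "$"), paste0(v, "[", lv[i], "]"),
                         colnames(X))
    }
  }
  X
}

# Profiled ML for the random-intercept model. For theta = sigma_p^2/sigma_e^2
# each group block has V_g = I + theta J, V_g^{-1} = I - c_g J with
# c_g = theta / (1 + m_g theta), log det V_g = log(1 + m_g theta); all GLS
# cross-products reduce to the raw cross-products minus c-weighted group-sum
# outer products, so one likelihood evaluation is O(n p + G p^2).
profile_ml_random_intercept <- function(y, X, g) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  S <- rowsum(X, g); tg <- rowsum(y, g)[, 1]
  m <- as.vector(table(g))

  eval_theta <- function(theta) {
    cg <- theta / (1 + m * theta)
    A <- XtX - crossprod(S, S * cg)
    b <- Xty - crossprod(S, cg * tg)
    beta <- solve(A, b)
    rss <- yty - sum(cg * tg^2) - sum(b * beta)
    sigma2 <- rss / n
    logdet <- sum(log1p(m * theta))
    loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
    list(loglik = loglik, beta = beta, sigma2 = sigma2, A = A)
  }

  opt <- optimize(function(th) -eval_theta(th)$loglik,
                  interval = c(0, 1e4), tol = 1e-10)
  cand <- opt$minimum
  at0 <- eval_theta(0)
  theta <- if (-opt$objective >= at0$loglik) cand else 0
  best <- eval_theta(theta)
  beta <- drop(best$beta)
  names(beta) <- colnames(X)
  sigma_e <- sqrt(best$sigma2)
  list(beta = beta, sigma_e = sigma_e, sigma_p = sqrt(theta) * sigma_e,
       theta = theta, loglik = best$loglik, n_obs = n,
       vcov_beta = best$sigma2 * solve(best$A), converged = TRUE)
}

#' @export
print.mh_lmm <- function(x, ...) {
  cat("<mh_lmm> ", deparse(x$formula), "  (ML)\n", sep = "")
  cat("  n = ", x$n_obs, " obs, ", x$n_groups, " groups; logLik = ",
      formatC(x$loglik, format = "f", digits = 3), "\n", sep = "")
  cat("  sigma_participant = ", formatC(x$sigma_p, digits = 4),
      ", sigma_residual = ", formatC(x$sigma_e, digits = 4), "\n", sep = "")
  print(round(x$beta, 4))
  invisible(x)
}

#' Tidy and summarise fitted triage models
#'
#' Broom-style methods: `tidy()` returns one row per fixed-effect term with
#' Wald statistics (naive `t` with `n_groups - 1` degrees of freedom);
#' `glance()` returns a one-row model summary. `tidy()` on a detection
#' decision returns its trace.
#'
#' @param x A fitted `mh_lmm` / `mh_clmm` object (or an `mh_detection`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mh_lmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov_beta))
  stat <- x$beta / se
  df <- x$n_groups - 1
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(se), statistic = unname(stat), df = df,
         p.value = 2 * pt(abs(stat), df, lower.tail = FALSE))
}

#' @rdname tidy.mh_lmm
#' @export
glance.mh_lmm <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = -2 * x$loglik + 2 * x$n_params,
         sigma_participant = x$sigma_p, sigma_residual = x$sigma_e,
         n_obs = x$n_obs, n_groups = x$n_groups, n_params = x$n_params)
}

#' Wald test of the model intercept against the neutral score
#'
#' With sum-to-zero factor coding the intercept of a (null) model is the
#' grand mean of the centred outcome, so this tests deviation from the
#' neutral point 0. Degrees of freedom are the naive `n_groups - 1`; the
#' statistic is reported both as `t` and as `F = t^2` on (1, `n_groups - 1`)
#' degrees of freedom.
#'
#' @param fit An `mh_lmm` fit whose design contains an intercept.
#' @return One-row tibble: `estimate`, `std.error`, `t`, `f`, `df1`, `df2`,
#'   `p.value`, `n`.
#' @export
wald_intercept <- function(fit) {
  stopifnot(inherits(fit, "mh_lmm"))
  idx <- match("(Intercept)", names(fit$beta))
  if (is.na(idx)) abort("Model has no intercept term.")
  est <- fit$beta[[idx]]
  se <- sqrt(fit$vcov_beta[idx, idx])
  df2 <- fit$n_groups - 1
  tstat <- est / se
  tibble(estimate = est, std.error = se, t = tstat, f = tstat^2,
         df1 = 1L, df2 = df2,
         p.value = 2 * pt(abs(tstat), df2, lower.tail = FALSE),
         n = fit$n_obs)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
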