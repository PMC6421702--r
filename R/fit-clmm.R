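#' Fit a cumulative-link (ordinal logit) mixed model
#'
#' Maximum-likelihood fit of a proportional-odds model with a participant
#' random intercept, used for the manipulation checks: the probability of
#' reporting at most level `j` is `logit^{-1}(zeta_j - eta - u)`, with `eta`
#' the fixed-effect predictor and `u ~ N(0, sigma_p^2)`. The random
#' intercept is integrated out by adaptive-free Gauss-Hermite quadrature
#' (default 15 nodes); thresholds are kept ordered through a log-difference
#' parameterisation and the joint likelihood is maximised with BFGS.
#' Non-convergence is reported with a warning and flagged on the fit, never
#' returned silently.
#'
#' @param data Long-format data frame.
#' @param formula Formula whose response is an ordinal outcome with at
#'   least 3 levels (a factor, or a character vector over a known level set
#'   such as low/medium/high), e.g. `perceived_severity ~ severity_code`.
#' @param group Grouping column name.
#' @param n_quad Number of Gauss-Hermite quadrature nodes (default 15).
#' @return An object of class `mh_clmm`: `zeta` (thresholds), `beta`,
#'   `sigma_p`, `loglik`, `n_obs`, `n_groups`, `n_params`, `converged`.
#' @examples
#' trial <- generate_trial(trial_design(n_participants = 40), seed = 2)
#' trial$severity_code <- match(trial$severity, c("low", "medium", "high")) - 2
#' fit_clmm(trial, perceived_severity ~ severity_code)
#' @export
fit_clmm <- function(data, formula, group = "participant_id", n_quad = 15L) {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  vars <- all.vars(formula)
  missing_cols <- setdiff(c(vars, group), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Column(s) not found in data: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[c(vars, group)])
  data <- data[keep, , drop = FALSE]
  y <- as_ordinal(data[[vars[1]]], vars[1])
  K <- nlevels(y)
  g <- factor(data[[group]])

  mf_data <- prepare_model_factors(data, setdiff(vars, vars[1]))
  labels <- attr(stats::terms(formula), "term.labels")
  X <- if (length(labels)) {
    rhs <- stats::reformulate(labels, intercept = FALSE)
    mf <- stats::model.frame(rhs, mf_data)
    sum_contrast_matrix(rhs, mf)
  } else {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  }
  p <- ncol(X)

  gh <- pracma::gaussHermite(n_quad)
  # E[f(u)] for u ~ N(0,1): sum w_k/sqrt(pi) f(sqrt(2) x_k)
  nodes <- sqrt(2) * gh$x
  logw <- log(gh$w) - 0.5 * log(pi)

  yi <- as.integer(y)
  gi <- as.integer(g)
  G <- nlevels(g)
  n <- length(yi)

  negll <- function(par) {
    zeta <- cumsum(c(par[1], exp(par[2:(K - 1)])))
    beta <- if (p) par[K:(K + p - 1)] else numeric(0)
    sigma <- exp(par[K + p])
    eta <- if (p) drop(X %*% beta) else numeric(n)
    upper <- c(zeta, Inf)[yi]
    lower <- c(-Inf, zeta)[yi]
    # log-likelihood per group at each quadrature node
    lse <- rep(-Inf, G)
    node_mat <- matrix(0, G, length(nodes))
    for (k in seq_along(nodes)) {
      shift <- eta + sigma * nodes[k]
      pr <- plogis(upper - shift) - plogis(lower - shift)
      pr <- pmax(pr, 1e-300)
      node_mat[, k] <- rowsum(log(pr), gi)[, 1] + logw[k]
    }
    mx <- apply(node_mat, 1, max)
    -sum(mx + log(rowSums(exp(node_mat - mx))))
  }

  # starting values: marginal cumulative logits, zero slopes, sigma = 0.5
  cum <- cumsum(table(yi) / n)[1:(K - 1)]
  z0 <- qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  start <- c(z0[1], log(pmax(diff(z0), 1e-2)), rep(0, p), log(0.5))
  opt <- optim(start, negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-10))
  converged <- opt$convergence == 0
  if (!converged) {
    warn(sprintf("Cumulative-link mixed model did not converge (optim code %d).",
                 opt$convergence))
  }
  par <- opt$par
  zeta <- cumsum(c(par[1], exp(par[2:(K - 1)])))
  names(zeta) <- paste(levels(y)[-K], levels(y)[-1], sep = "|")
  beta <- if (p) stats::setNames(par[K:(K + p - 1)], colnames(X)) else numeric(0)

  structure(
    list(zeta = zeta, beta = beta, sigma_p = exp(par[K + p]),
         loglik = -opt$value, n_obs = n, n_groups = G,
         n_params = (K - 1) + p + 1L,
         outcome = vars[1],
         term_labels = attr(stats::terms(formula), "term.labels"),
         formula = formula, converged = converged),
    class = "mh_clmm"
  )
}

as_ordinal <- function(y, name) {
  if (is.factor(y)) {
    y <- droplevels(y)
  } else {
    y <- as.character(y)
    known <- purrr::detect(.mh_levels[c("severity", "stance")],
                           function(lv) all(y %in% lv))
    y <- factor(y, levels = known %||% sort(unique(y)))
  }
  if (nlevels(y) < 3L) {
    abort(sprintf("Ordinal outcome '%s' needs at least 3 observed levels.",
                  name))
  }
  y
}

#' @export
print.mh_clmm <- function(x, ...) {
  cat("<mh_clmm> ", deparse(x$formula), "  (ML, Gauss-Hermite)\n", sep = "")
  cat("  n = ", x$n_obs, " obs, ", x$n_groups, " groups; logLik = ",
      formatC(x$loglik, format = "f", digits = 3),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("  thresholds: ", paste(names(x$zeta), round(x$zeta, 3),
                              collapse = ", "), "\n", sep = "")
  if (length(x$beta)) {
    cat("  fixed effects:\n"); print(round(x$beta, 4))
  }
  cat("  sigma_participant = ", formatC(x$sigma_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.mh_lmm
#' @export
tidy.mh_clmm <- function(x, ...) {
  tibble(term = c(names(x$zeta), names(x$beta)),
         type = c(rep("threshold", length(x$zeta)),
                  rep("fixed", length(x$beta))),
         estimate = c(unname(x$zeta), unname(x$beta)))
}

#' @rdname tidy.mh_lmm
#' @export
glance.mh_clmm <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = -2 * x$loglik + 2 * x$n_params,
         sigma_participant = x$sigma_p, n_obs = x$n_obs,
         n_groups = x$n_groups, n_params = x$n_params,
         converged = x$converged)
}
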