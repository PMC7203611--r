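# Cluster-robust logistic regression by generalized estimating equations.
#
# Liang–Zeger estimating equations with logit link and binomial variance,
# solved by Fisher scoring. Working correlation: independence or
# exchangeable; scale and exchangeable alpha by the usual Pearson-residual
# moment estimators, updated between scoring steps. Variance by the
# cluster-robust sandwich estimator (no small-sample correction). The
# exchangeable working inverse R^-1 = 1/(1-a) [I - a/(1+(n-1)a) J] is used
# in closed form, so all per-cluster sums reduce to rowsum() calls and no
# per-cluster matrix is ever formed.

fit_gee_core <- function(y, X, cluster, working, tol, max_iter) {
  n <- length(y)
  p <- ncol(X)
  cluster <- as.factor(cluster)
  sizes <- as.integer(table(cluster))
  n_pairs <- sum(sizes * (sizes - 1)) / 2

  # initialise at the independence ML solution
  init <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  beta <- init$coefficients
  beta[!is.finite(beta)] <- 0
  alpha <- 0
  phi <- 1
  converged <- FALSE
  iter <- 0

  size_of <- sizes[as.integer(cluster)]
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    res <- y - mu
    r <- res / sqrt(w)

    # moment estimators for scale and exchangeable correlation
    phi <- sum(r^2) / (n - p)
    if (working == "exchangeable" && n_pairs > p) {
      sum_r <- drop(rowsum(r, cluster))
      sum_r2 <- drop(rowsum(r^2, cluster))
      pair_sum <- sum((sum_r^2 - sum_r2) / 2)
      alpha <- pair_sum / ((n_pairs - p) * phi)
      alpha <- min(max(alpha, 0), 0.99)
    } else {
      alpha <- 0
    }

    # score and information under R(alpha)^-1 = c1 (I - c2 J) per cluster
    c1 <- 1 / (1 - alpha)
    c2_of <- alpha / (1 + (size_of - 1) * alpha)
    sqw <- sqrt(w)
    S <- rowsum(X * sqw, cluster)                 # G x p
    t_i <- drop(rowsum(res / sqw, cluster))       # sum (y-mu)/sqrt(w)
    c2_i <- alpha / (1 + (sizes - 1) * alpha)
    M <- c1 * (crossprod(X, X * w) - crossprod(S, S * c2_i))
    U <- c1 * (crossprod(X, res) - crossprod(S, t_i * c2_i))
    step <- tryCatch(solve(M, U), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (iter >= max_iter) break
  }

  # sandwich variance at the final estimate
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  res <- y - mu
  c1 <- 1 / (1 - alpha)
  sqw <- sqrt(w)
  S <- rowsum(X * sqw, cluster)
  t_i <- drop(rowsum(res / sqw, cluster))
  c2_i <- alpha / (1 + (sizes - 1) * alpha)
  M <- c1 * (crossprod(X, X * w) - crossprod(S, S * c2_i))
  G <- c1 * (rowsum(X * res, cluster) - S * (t_i * c2_i))  # per-cluster scores
  B <- crossprod(G)
  Minv <- tryCatch(solve(M), error = function(e) matrix(NA_real_, p, p))
  V <- Minv %*% B %*% Minv
  # extreme fitted probabilities indicate separation / a degenerate outcome
  if (all(mu < 1e-8) || all(mu > 1 - 1e-8)) converged <- FALSE

  list(coefficients = beta, vcov = V, alpha = alpha, phi = phi,
       converged = converged, n_iter = iter,
       n_obs = n, n_clusters = length(sizes))
}

#' Cluster-robust logistic regression (GEE)
#'
#' Fits a marginal logistic model to correlated binary outcomes by
#' generalized estimating equations — the estimator of choice for repeated
#' within-patient test results. Coefficients solve the logistic estimating
#' equations under the chosen working correlation (Fisher scoring with
#' moment updates of the scale and, for `"exchangeable"`, the common
#' within-cluster correlation); standard errors are cluster-robust
#' (sandwich), so inference is valid even when the working correlation is
#' wrong. With one observation per cluster, or independence working
#' correlation, the coefficients coincide with ordinary logistic maximum
#' likelihood.
#'
#' Aliased model terms (collinear or all-constant indicators, e.g. a THC
#' indicator with no positive test) are dropped from the scoring step and
#' reported as `NA` — the fit is flagged rather than crashing. An outcome
#' with no events (or no non-events) yields `converged = FALSE`.
#'
#' @param data Data frame of one row per observation (tested visit).
#' @param formula Model formula; the response must be logical or 0/1 (e.g.
#'   `inconsistent ~ category + visit_index`).
#' @param cluster Name of the cluster (patient) identifier column.
#' @param working `"exchangeable"` (default) or `"independence"`.
#' @param conf_level Confidence level for reported intervals.
#' @param tol Convergence tolerance on the coefficient step.
#' @param max_iter Iteration cap.
#' @return An object of class `udt_gee`; see [tidy.udt_gee()] and
#'   [glance.udt_gee()] for tibble summaries.
#' @export
#' @examples
#' prm <- cohort_params(n_patients = 150, seed = 11)
#' visits <- simulate_visits(generate_cohort(prm), prm)
#' tested <- dplyr::mutate(dplyr::filter(visits, tested),
#'                         inconsistent = status == "inconsistent")
#' fit <- fit_gee_logistic(tested, inconsistent ~ category + visit_index,
#'                         cluster = "patient_id")
#' tidy(fit, exponentiate = TRUE)
fit_gee_logistic <- function(data, formula, cluster = "patient_id",
                             working = c("exchangeable", "independence"),
                             conf_level = 0.95, tol = 1e-10, max_iter = 100) {
  working <- match.arg(working)
  data <- as.data.frame(data)
  stop_if_missing_cols(data, cluster, "model data")
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("outcome must be binary (logical or 0/1)")
  X <- model.matrix(formula, mf)
  cl <- data[[cluster]]
  if (length(unique(cl)) < 2) abort("at least 2 clusters are required")

  # drop aliased columns (rank deficiency), keep them as NA in the report
  qr_x <- qr(X)
  aliased <- rep(FALSE, ncol(X))
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    aliased[-keep] <- TRUE
  }
  X_fit <- X[, !aliased, drop = FALSE]

  core <- fit_gee_core(y, X_fit, cl, working, tol, max_iter)

  terms_all <- colnames(X)
  coef <- se <- setNames(rep(NA_real_, length(terms_all)), terms_all)
  coef[!aliased] <- core$coefficients
  se[!aliased] <- sqrt(pmax(diag(core$vcov), 0))
  structure(list(coefficients = coef, robust_se = se, vcov = core$vcov,
                 aliased = aliased, alpha = core$alpha, phi = core$phi,
                 working = working, conf_level = conf_level,
                 converged = core$converged, n_iter = core$n_iter,
                 n_obs = core$n_obs, n_clusters = core$n_clusters,
                 formula = formula, cluster = cluster),
            class = "udt_gee")
}

#' Tidy a GEE fit
#'
#' @param x A `udt_gee` object.
#' @param exponentiate Report odds ratios (and exponentiated CI) instead of
#'   log-odds; standard errors stay on the log-odds scale.
#' @param conf_level Confidence level (defaults to the fit's).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.udt_gee <- function(x, exponentiate = FALSE, conf_level = x$conf_level, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  se <- x$robust_se
  stat <- est / se
  out <- tibble(term = names(est), estimate = unname(est),
                std.error = unname(se), statistic = unname(stat),
                p.value = unname(2 * pnorm(-abs(stat))),
                conf.low = unname(est - z * se),
                conf.high = unname(est + z * se))
  if (exponentiate) {
    out <- mutate(out, estimate = exp(.data$estimate),
                  conf.low = exp(.data$conf.low),
                  conf.high = exp(.data$conf.high))
  }
  out
}

#' Fit diagnostics of a GEE fit
#'
#' @param x A `udt_gee` object.
#' @param ... Unused.
#' @return One-row tibble with `n_obs`, `n_clusters`, `working`, `alpha`,
#'   `phi`, `n_iter`, `converged`, `n_aliased`.
#' @export
glance.udt_gee <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_clusters = x$n_clusters, working = x$working,
         alpha = x$alpha, phi = x$phi, n_iter = x$n_iter,
         converged = x$converged, n_aliased = sum(x$aliased))
}

#' @export
print.udt_gee <- function(x, ...) {
  cat("Cluster-robust logistic GEE fit (", x$working,
      " working correlation)\n", sep = "")
  cat(sprintf("%d observations in %d clusters; alpha = %.4f; converged: %s\n",
              x$n_obs, x$n_clusters, x$alpha, x$converged))
  print(tidy(x, exponentiate = TRUE), ...)
  invisible(x)
}

#' Category and THC marginal models
#'
#' Convenience wrappers fitting the two standard evaluation models on a
#' visit table: inconsistency against risk category (low reference) plus a
#' continuous 1-based visit index, and inconsistency against a per-test THC
#' indicator plus visit index. Both restrict to performed tests and cluster
#' on the patient.
#'
#' @param visits Visit table (see [simulate_visits()]).
#' @param working Working correlation passed to [fit_gee_logistic()].
#' @param ... Further arguments passed to [fit_gee_logistic()].
#' @return A `udt_gee` object.
#' @export
fit_category_model <- function(visits, working = "exchangeable", ...) {
  tested <- prepare_model_data(visits)
  fit_gee_logistic(tested, inconsistent ~ category + visit_index,
                   cluster = "patient_id", working = working, ...)
}

#' @rdname fit_category_model
#' @export
fit_thc_model <- function(visits, working = "exchangeable", ...) {
  tested <- prepare_model_data(visits)
  stop_if_missing_cols(tested, "thc_positive", "visit table")
  fit_gee_logistic(tested, inconsistent ~ thc_positive + visit_index,
                   cluster = "patient_id", working = working, ...)
}

prepare_model_data <- function(visits) {
  visits <- as_tibble(visits)
  stop_if_missing_cols(visits, c("patient_id", "visit_index", "category",
                                 "tested", "status"), "visit table")
  tested <- filter(visits, .data$tested)
  if (any(is.na(tested$status))) abort("tested visits must carry a verdict")
  lv <- if (is.factor(tested$category)) levels(tested$category) else risk_levels()
  lv <- intersect(lv, unique(as.character(tested$category)))
  mutate(tested,
         inconsistent = .data$status == "inconsistent",
         category = factor(as.character(.data$category), levels = lv))
}
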