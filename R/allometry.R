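#' Grafen branch lengths
#'
#' Assigns branch lengths to a rooted tree by Grafen's rule: each node's
#' height is its number of descendant tips minus one, normalized so the
#' root has height 1 and tips height 0; a branch's length is the height
#' difference between parent and child. The result is ultrametric (all
#' root-to-tip paths equal 1), the standard arbitrary-branch-length choice
#' for phylogenetically controlled regression when divergence times are
#' unavailable.
#'
#' @param tree a rooted \code{ape::phylo} tree.
#' @return The tree with Grafen branch lengths.
#' @export
grafen_branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::compute.brlen(tree, method = "Grafen", power = 1)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' The species-by-species covariance implied by Brownian evolution on the
#' tree: entry (i, j) is the shared root-to-MRCA path length; the diagonal
#' is each tip's root-to-tip depth. Symmetric positive semi-definite by
#' construction.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths (see
#'   [grafen_branch_lengths()]).
#' @return A species-by-species covariance matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::vcv.phylo(tree)
}

#' Phylogenetically controlled (generalized least squares) regression
#'
#' Fits \eqn{y = X\beta + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2 C)}
#' with C the (phylogenetic) correlation structure, by Cholesky whitening:
#' \eqn{\hat\beta = (X'C^{-1}X)^{-1} X'C^{-1} y} with GLS standard errors.
#' With \code{C = I} this reduces exactly to ordinary least squares.
#' Allometric fits pass log-scaled variables.
#'
#' @param formula model formula.
#' @param data data.frame; rows must be named by (or carry a
#'   \code{species} column matching) the rownames of \code{C}.
#' @param C covariance/correlation structure across rows (defaults to the
#'   identity, i.e. OLS), e.g. from [phylo_covariance()].
#' @return An object of class \code{"pgls"} with lm-style methods
#'   (\code{coef}, \code{summary}, \code{confint}, \code{predict},
#'   \code{residuals}, \code{logLik}, \code{AICc}).
#' @examples
#' d <- data.frame(x = 1:6, y = 2 * (1:6))
#' coef(pgls(y ~ x, d))  # OLS reduction
#' @export
pgls <- function(formula, data, C = NULL) {
  data <- as.data.frame(data)
  if (!is.null(C)) {
    key <- if ("species" %in% names(data)) as.character(data$species)
           else rownames(data)
    if (!is.null(rownames(C))) {
      if (!all(key %in% rownames(C)))
        stop("data rows do not match the covariance matrix species")
      C <- C[key, key]
    } else if (nrow(C) != nrow(data))
      stop("covariance dimension does not match the data")
  } else C <- diag(nrow(data))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  U <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is not positive definite"))
  # whiten: C = U'U  =>  (U')^{-1} C (U)^{-1} = I
  yw <- forwardsolve(t(U), y)
  Xw <- forwardsolve(t(U), X)
  colnames(Xw) <- colnames(X)
  fit <- stats::lm.fit(Xw, yw)
  if (fit$rank < ncol(X)) stop("singular design matrix")
  n <- length(yw); p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  vc <- sigma2 * XtX_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  logdetC <- 2 * sum(log(diag(U)))
  s2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + logdetC + n)
  structure(list(
    coefficients = fit$coefficients, se = se, t = tval, p = pval,
    vcov = vc, df_residual = n - p, sigma2 = sigma2, rss = rss,
    loglik = ll, n = n, k = p + 1,
    aicc = aicc_value(ll, p + 1, n),
    formula = formula, terms = stats::terms(mf),
    residuals_whitened = fit$residuals, fitted = as.numeric(X %*%
      fit$coefficients), y = y, call = match.call()),
    class = "pgls")
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...)
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")

#' @export
AICc.pgls <- function(object) object$aicc

#' @export
residuals.pgls <- function(object, type = c("response", "whitened"), ...) {
  type <- match.arg(type)
  if (type == "whitened") object$residuals_whitened
  else object$y - object$fitted
}

#' @export
confint.pgls <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  if (missing(parm)) parm <- names(est)
  q <- stats::qt(1 - (1 - level) / 2, df = object$df_residual)
  out <- cbind(est[parm] - q * object$se[parm],
               est[parm] + q * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(object$terms),
                           as.data.frame(newdata))
  as.numeric(X %*% object$coefficients)
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS fit:",
      deparse(x$formula), "\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t, `Pr(>|t|)` = object$p)
  structure(list(call = object$call, formula = object$formula,
                 coefficients = tab, ci = confint.pgls(object),
                 sigma2 = object$sigma2, n = object$n,
                 aicc = object$aicc),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nn = %d, residual scale %.4g, AICc %.2f\n",
              x$n, sqrt(x$sigma2), x$aicc))
  invisible(x)
}

# --- bias-versus-mass model comparison -------------------------------------

logistic_curve <- function(x, a, r, k, x0) a + r / (1 + exp(-k * (x - x0)))

fit_logistic_gls <- function(y, x, U) {
  wh <- function(v) forwardsolve(t(U), v)
  yw <- wh(y)
  rss_fun <- function(p) {
    f <- logistic_curve(x, p[1], p[2], p[3], p[4])
    if (any(!is.finite(f))) return(1e12)
    sum((yw - wh(f))^2)
  }
  ry <- range(y)
  starts <- list(c(ry[1], diff(ry), -2, stats::median(x)),
                 c(ry[2], -diff(ry), -2, stats::median(x)),
                 c(ry[1], diff(ry), 2, stats::median(x)),
                 c(mean(y), diff(ry) / 2, 1, mean(x)))
  best <- NULL
  for (s in starts) {
    op <- tryCatch(stats::optim(s, rss_fun, method = "Nelder-Mead",
                                control = list(maxit = 2000,
                                               reltol = 1e-12)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) return(NULL)
  list(par = stats::setNames(best$par, c("a", "r", "k", "x0")),
       rss = best$value, converged = best$convergence == 0)
}

#' Compare intercept-only, linear and logistic bias-versus-mass models
#'
#' Fits three phylogenetically controlled regressions of a bias statistic
#' on log10 body mass — intercept-only (no change in bias with mass),
#' linear, and a four-parameter logistic sigmoid (lower asymptote +
#' range / (1 + exp(-k (x - x0)))) — and selects among them by
#' small-sample-corrected quasi-AIC (QAICc). The overdispersion scale
#' \eqn{\hat c} is estimated from the richest (logistic) model's Pearson
#' statistic against the phylogenetic covariance, and every model's
#' quasi-deviance is its whitened residual sum of squares divided by
#' \eqn{\hat c}; parameter counts include one for \eqn{\hat c}.
#'
#' @param bias per-species bias statistic (e.g. held-out inclusion
#'   percentage, or proportional underestimation).
#' @param log10_mass per-species log10 body mass (kg).
#' @param C phylogenetic covariance across species (identity if NULL).
#' @param species optional species labels for covariance alignment.
#' @return An object of class \code{"bias_models"}: \code{fits} (per
#'   model: coefficients, predict function, RSS, QAICc), \code{selected}
#'   (name of the QAICc-best converged model), \code{table}, \code{c_hat}.
#' @export
fit_bias_models <- function(bias, log10_mass, C = NULL, species = NULL) {
  n <- length(bias)
  if (n < 8) stop("bias-model comparison needs at least 8 species")
  if (length(log10_mass) != n) stop("length mismatch")
  d <- data.frame(y = bias, x = log10_mass)
  if (!is.null(species)) { d$species <- species; rownames(d) <- species }
  Cm <- if (is.null(C)) diag(n) else {
    if (!is.null(species) && !is.null(rownames(C))) C[species, species]
    else C
  }
  U <- chol(Cm)
  f_int <- pgls(y ~ 1, d, Cm)
  f_lin <- pgls(y ~ x, d, Cm)
  f_log <- fit_logistic_gls(d$y, d$x, U)
  k <- c(intercept = 1, linear = 2, logistic = 4)
  rss <- c(intercept = f_int$rss, linear = f_lin$rss,
           logistic = if (is.null(f_log)) NA else f_log$rss)
  converged <- c(TRUE, TRUE, !is.null(f_log) && f_log$converged)
  c_hat <- if (!is.na(rss["logistic"]))
    max(rss["logistic"] / (n - k["logistic"]), .Machine$double.eps)
  else max(rss["linear"] / (n - k["linear"]), .Machine$double.eps)
  qaicc <- vapply(names(k), function(m) {
    if (is.na(rss[m]) || !converged[match(m, names(k))]) return(Inf)
    K <- k[m] + 1  # + c_hat
    rss[m] / c_hat + 2 * K + 2 * K * (K + 1) / max(n - K - 1, 0.5)
  }, 0)
  fits <- list(
    intercept = list(fit = f_int, coef = coef(f_int),
                     predict = local({ f <- f_int
                       function(x) predict(f, data.frame(x = x)) })),
    linear = list(fit = f_lin, coef = coef(f_lin),
                  predict = local({ f <- f_lin
                    function(x) predict(f, data.frame(x = x)) })),
    logistic = if (!is.null(f_log))
      list(fit = f_log, coef = f_log$par,
           predict = local({ p <- f_log$par
             function(x) logistic_curve(x, p[1], p[2], p[3], p[4]) })))
  for (m in names(qaicc)) if (!is.null(fits[[m]])) fits[[m]]$qaicc <- qaicc[m]
  sel <- names(qaicc)[which.min(qaicc)]
  structure(list(fits = fits, selected = sel,
                 table = data.frame(model = names(k), k = k, rss = rss,
                                    qaicc = qaicc,
                                    converged = converged),
                 c_hat = c_hat, n = n),
            class = "bias_models")
}

#' @export
print.bias_models <- function(x, ...) {
  cat("Bias-versus-mass model comparison (QAICc, c-hat =",
      signif(x$c_hat, 4), ")\n")
  tb <- x$table
  tb$delta <- tb$qaicc - min(tb$qaicc)
  print(tb, row.names = FALSE, digits = 4)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Predict the bias statistic at a body mass
#'
#' @param object a \code{"bias_models"} comparison.
#' @param mass_kg body mass in kg.
#' @param model which model to use (default the QAICc-selected one).
#' @return Predicted bias value(s).
#' @export
predict_bias <- function(object, mass_kg, model = object$selected) {
  stopifnot(inherits(object, "bias_models"))
  object$fits[[model]]$predict(log10(mass_kg))
}

#' Test for superlinear allometric scaling
#'
#' For a log-log power-law fit \eqn{\log H = \log B_0 + b \log M}, the
#' scaling is superlinear when the lower bound of the confidence interval
#' on the exponent \eqn{b} exceeds 1.
#'
#' @param fit a \code{\link{pgls}} fit on log-log scale whose slope is the
#'   scaling exponent.
#' @param term name or index of the exponent coefficient (default: the
#'   second coefficient).
#' @param level confidence level.
#' @return A list with \code{superlinear} (logical), \code{b},
#'   \code{excess} (\eqn{b - 1}) and its confidence interval.
#' @export
test_superlinearity <- function(fit, term = 2, level = 0.95) {
  stopifnot(inherits(fit, "pgls"))
  ci <- confint.pgls(fit, level = level)
  nm <- if (is.numeric(term)) names(coef(fit))[term] else term
  b <- coef(fit)[nm]
  list(superlinear = unname(ci[nm, 1] > 1), b = unname(b),
       excess = unname(b - 1),
       ci = unname(ci[nm, ]) , excess_ci = unname(ci[nm, ] - 1))
}

#' Mass-specific home-range correction factor (HRcorrect)
#'
#' Converts a predicted proportional underestimation \eqn{u(M) \in [0, 1)}
#' of conventional-KDE home-range areas into the multiplicative correction
#' \deqn{\mathrm{HRcorrect}(M) = \frac{1}{1 - u(M)},} so that a
#' conventional KDE area times the factor gives the bias-corrected area.
#' Negative predicted underestimation (no bias) is clamped to a factor of
#' 1; predictions at or above 1 are an error.
#'
#' @param mass_kg body mass in kg.
#' @param bias_fit a \code{"bias_models"} comparison (or single model fit
#'   via \code{model =}) whose response is proportional underestimation
#'   \code{u}; see [underestimation_from_ratio()].
#' @param model model name passed to [predict_bias()].
#' @return Correction factor(s) >= 1.
#' @examples
#' 1 / (1 - 0.136)  # a ~14% underestimate needs a ~1.16x correction
#' @export
hrcorrect_factor <- function(mass_kg, bias_fit,
                             model = bias_fit$selected) {
  u <- predict_bias(bias_fit, mass_kg, model = model)
  if (any(u >= 1))
    stop("predicted underestimation >= 1: correction undefined")
  1 / (1 - pmax(u, 0))
}

#' Proportional underestimation from the contour-ratio statistic
#'
#' A contour ratio r > 1 means the nominal area must grow by the factor r
#' to reach target coverage, i.e. the nominal area underestimates the
#' needed area by \eqn{u = 1 - 1/r}.
#'
#' @param ratio contour-ratio bias statistic(s) (> 0), from [bias_ratio()].
#' @return Proportional underestimation \code{u} (may be negative for
#'   overestimates).
#' @export
underestimation_from_ratio <- function(ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) stop("ratios must be positive")
  1 - 1 / ratio
}
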