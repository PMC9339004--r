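#' Base-10 logistic regression
#'
#' Maximum-likelihood Bernoulli regression with a base-10 logit link:
#' `P(y = 1) = 1 / (1 + 10^-Q)`, `Q = b0 + X b`. Coefficients on the
#' base-10 scale are the natural-log logistic coefficients divided by
#' `ln 10`, and standard errors (from the observed information) rescale
#' the same way. No regularization is applied: perfect separation and
#' rank deficiency raise errors rather than silently shrinking.
#'
#' @param X numeric design matrix, one row per trial, no intercept column
#'   (an intercept is always added)
#' @param y logical or 0/1 outcomes
#' @return An object of class `"logit10"` with `coefficients` (base-10),
#'   `se`, `vcov`, `loglik`, `n`, `fitted` (probabilities), `converged`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(2000), 1000, 2)
#' q <- 0.5 + x %*% c(1, -0.5)
#' y <- runif(1000) < 1 / (1 + 10^(-q))
#' coef(fit_logit10(x, y))
#' @export
fit_logit10 <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary")
  if (nrow(X) != length(y)) stop("design and outcomes disagree in length")
  if (length(unique(y)) < 2)
    stop("separation: all choices are identical; both outcome classes are required")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X1 <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) {
    dropped <- colnames(X1)[qr_x$pivot[(qr_x$rank + 1L):ncol(X1)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(dropped, collapse = ", ")))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X1, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  eps <- 1e-8
  perfect <- all(mu[y == 1] > 1 - eps) && all(mu[y == 0] < eps)
  if (perfect || (sep_warn && fit$deviance < eps))
    stop("separation: the outcome is perfectly predicted; coefficients diverge")
  # observed information of the natural-log fit, rescaled to base 10
  w <- mu * (1 - mu)
  info <- crossprod(X1 * sqrt(w))
  vcov_nat <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix; fit is not identified"))
  l10 <- log(10)
  coefficients <- fit$coefficients / l10
  vc <- vcov_nat / l10^2
  dimnames(vc) <- list(names(coefficients), names(coefficients))
  structure(list(coefficients = coefficients, se = sqrt(diag(vc)), vcov = vc,
                 loglik = -fit$deviance / 2, deviance = fit$deviance,
                 n = length(y), fitted = mu, converged = fit$converged,
                 df_residual = fit$df.residual),
            class = "logit10")
}

#' @export
coef.logit10 <- function(object, ...) object$coefficients

#' @export
vcov.logit10 <- function(object, ...) object$vcov

#' @export
logLik.logit10 <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.logit10 <- function(x, ...) {
  cat(sprintf("Base-10 logistic fit: %d trials, log-likelihood %.2f\n",
              x$n, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.logit10 <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(table = tab, n = object$n, loglik = object$loglik,
              converged = object$converged)
  class(out) <- "summary.logit10"
  out
}

#' @export
print.summary.logit10 <- function(x, ...) {
  cat(sprintf("Base-10 logistic fit (%d trials, logLik %.2f)\n", x$n, x$loglik))
  stats::printCoefmat(x$table, digits = 4)
  invisible(x)
}

#' @export
predict.logit10 <- function(object, newdata = NULL, type = c("response", "link"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    stop("link-scale prediction needs 'newdata'")
  }
  Q <- object$coefficients[1L] +
    as.numeric(as.matrix(newdata) %*% object$coefficients[-1L])
  if (type == "link") Q else 1 / (1 + 10^(-Q))
}

# shape-count difference design of the subjective-weight regression:
# column i = (# times shape i appeared red) - (# appeared green)
sw_design <- function(trials) {
  shp <- shape_mat(trials)
  col <- color_mat(trials)
  X <- matrix(vapply(1:6, function(i) rowSums((shp == i) * col),
                     numeric(nrow(trials))), nrow(trials), 6L)
  colnames(X) <- paste0("shape_", 1:6)
  X
}

#' Estimate subjective weights from choices
#'
#' Fits the base-10 logistic choice model whose leverage is
#' `Q = b0 + sum_i b_i (N_red_i - N_green_i)`, where `N_color_i` counts
#' how many times shape `i` appeared in that color in the trial. The
#' coefficients `b_1..6` are the shapes' subjective weights: the leverage
#' the subject actually assigns each shape, on the same base-10 log-odds
#' scale as the assigned weights.
#'
#' @param trials a `trial_table` with choices recorded
#' @return a `"subjective_weight_fit"` (a [fit_logit10()] object with a
#'   `sw` component: estimate, standard error and Wald p per shape)
#' @export
fit_subjective_weights <- function(trials) {
  stopifnot(inherits(trials, "trial_table"))
  if (any(is.na(trials$chosen_color))) stop("trials are missing choices")
  fit <- fit_logit10(sw_design(trials), trials$chosen_color == "red")
  est <- fit$coefficients[-1L]
  se <- fit$se[-1L]
  fit$sw <- data.frame(shape_id = 1:6, sw = unname(est), se = unname(se),
                       p = unname(2 * stats::pnorm(-abs(est / se))))
  class(fit) <- c("subjective_weight_fit", class(fit))
  fit
}

#' @export
print.subjective_weight_fit <- function(x, ...) {
  cat(sprintf("Subjective weights (base-10 logistic, %d trials; bias %.3f)\n",
              x$n, x$coefficients[1L]))
  print(transform(x$sw, sw = round(sw, 4), se = round(se, 4),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Epoch-leverage regression
#'
#' Asks whether stimuli in every serial position influence choice: the
#' leverage is `Q = b0 + sum_i b_i (SW_red_i - SW_green_i)` with one
#' coefficient per epoch `i`, where `SW_red_i` is the epoch-i stimulus's
#' subjective weight if that stimulus is red and 0 otherwise (and
#' symmetrically for green). An epoch the subject uses fully has a
#' coefficient near 1; an ignored epoch has a coefficient near 0.
#'
#' @param trials a `trial_table` with choices
#' @param sw six subjective weights (e.g. from
#'   [fit_subjective_weights()]`$sw$sw`, or ground truth)
#' @return an `"epoch_leverage_fit"` with an `epochs` data frame
#' @export
fit_epoch_leverage <- function(trials, sw) {
  stopifnot(inherits(trials, "trial_table"), length(sw) == 6,
            all(is.finite(sw)))
  if (any(is.na(trials$chosen_color))) stop("trials are missing choices")
  shp <- shape_mat(trials)
  col <- color_mat(trials)
  X <- matrix(sw[shp], nrow(trials), 6L) * col
  colnames(X) <- paste0("epoch_", 1:6)
  fit <- fit_logit10(X, trials$chosen_color == "red")
  est <- fit$coefficients[-1L]
  se <- fit$se[-1L]
  fit$epochs <- data.frame(epoch = 1:6, beta = unname(est), se = unname(se),
                           p = unname(2 * stats::pnorm(-abs(est / se))))
  class(fit) <- c("epoch_leverage_fit", class(fit))
  fit
}

#' @export
print.epoch_leverage_fit <- function(x, ...) {
  cat(sprintf("Epoch leverage (base-10 logistic, %d trials; bias %.3f)\n",
              x$n, x$coefficients[1L]))
  print(transform(x$epochs, beta = round(beta, 4), se = round(se, 4),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Psychometric curve over total weight difference
#'
#' Bins trials into equal-count groups of the assigned-weight evidence
#' for red, `sum W_red - sum W_green`, and reports the fraction of red
#' choices per bin with its binomial standard error.
#'
#' @param trials a `trial_table` with choices
#' @param shapes the [shape_set()] providing assigned weights
#' @param n_bins number of equal-count bins (default 9)
#' @return a data frame (class `"psychometric_curve"`) with columns
#'   `bin`, `n`, `evidence` (bin mean), `p_red`, `se`
#' @export
psychometric_curve <- function(trials, shapes = shape_set(), n_bins = 9L) {
  stopifnot(inherits(trials, "trial_table"))
  if (n_bins < 1) stop("'n_bins' must be >= 1")
  if (nrow(trials) < n_bins) stop("fewer trials than bins")
  if (any(is.na(trials$chosen_color))) stop("trials are missing choices")
  w <- matrix(shapes$weight[shape_mat(trials)], nrow(trials), 6L)
  x <- rowSums(w * color_mat(trials))
  g <- ceiling(rank(x, ties.method = "first") * n_bins / length(x))
  red <- trials$chosen_color == "red"
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    i <- g == b
    p <- mean(red[i])
    data.frame(bin = b, n = sum(i), evidence = mean(x[i]), p_red = p,
               se = sqrt(p * (1 - p) / sum(i)))
  }))
  class(out) <- c("psychometric_curve", "data.frame")
  out
}

#' @export
plot.psychometric_curve <- function(x, ...) {
  plot(x$evidence, x$p_red, ylim = c(0, 1), pch = 19,
       xlab = expression(sum(W[red]) - sum(W[green])),
       ylab = "P(choose red)", ...)
  graphics::arrows(x$evidence, x$p_red - x$se, x$evidence, x$p_red + x$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0.5, v = 0, lty = 3)
  curve(1 / (1 + 10^(-t)), xname = "t", add = TRUE, col = "grey40")
  invisible(x)
}
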