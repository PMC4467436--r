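# Survival toolkit: product-limit estimator with Greenwood variance,
# k-group log-rank test, and a Cox proportional-hazards fitter using the
# Efron tie approximation maximized by damped Newton-Raphson. Written here
# deliberately; the 'survival' package is the cross-check oracle in tests.

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod(1 - d_i / n_i)` over observed event times, with subjects
#' censored at an event time counted at risk for that time (the standard
#' convention). Standard errors by Greenwood's formula.
#'
#' @param time Nonnegative follow-up times (days).
#' @param event Event indicators (1 = death observed, 0 = censored).
#' @return Object of class `km_curve`: `time` (event times, ascending),
#'   `n_risk`, `n_event`, `surv`, `se`, plus `n` and `n_events`. With no
#'   events the curve is flat at 1 and a warning is raised.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))$surv  # 2/3, 0
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time < 0)) stop("times must be nonnegative")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) warning("no events observed; curve is flat at 1")
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  se <- surv * sqrt(gw)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 surv = surv, se = se,
                 n = length(time), n_events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " subjects, ", x$n_events, " events\n",
      sep = "")
  if (length(x$time))
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     surv = signif(x$surv, 4), se = signif(x$se, 4)),
          row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Days", ylab = "Survival probability",
                          col = 1, add = FALSE, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-length(x$surv) * 2])
  if (!add)
    graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab,
                   ylab = ylab, col = col, ...)
  else graphics::lines(tt, ss, col = col, ...)
  invisible(x)
}

#' Log-rank test for k groups
#'
#' Chi-square statistic from the summed observed-minus-expected event counts
#' with the multivariate hypergeometric variance at each event time;
#' `df = k - 1`.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Group labels (factor or character); every group must be
#'   non-empty.
#' @return Test-result object (class `htest`) with the chi-square statistic,
#'   df and p-value.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("need >= 2 non-empty groups")
  k <- nlevels(group)
  ut <- sort(unique(time[event == 1]))
  OE <- rep(0, k); V <- matrix(0, k, k)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    d <- sum(time == t & event == 1)
    dg <- vapply(levels(group), function(g)
      sum(time == t & event == 1 & group == g), numeric(1))
    OE <- OE + dg - d * ng / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      V <- V + mult * (diag(ng / n, k) - tcrossprod(ng / n))
    }
  }
  idx <- seq_len(k - 1L)
  stat <- as.numeric(t(OE[idx]) %*% solve(V[idx, idx, drop = FALSE],
                                          OE[idx]))
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  new_test_result(c(chisq = stat, df = k - 1), p,
                  n = table(group), method = "log-rank test")
}

# Partial log-likelihood, gradient and information (Efron ties) at beta.
# Data must be sorted by ascending time.
cox_lgh <- function(beta, time, event, X) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                      # guard exp overflow
  w <- exp(eta)
  ll <- 0; grad <- rep(0, p); info <- matrix(0, p, p)
  S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
  ut <- unique(time)
  for (t in rev(ut)) {                        # grow risk set downward in time
    idx <- which(time == t)
    for (i in idx) {
      S0 <- S0 + w[i]
      S1 <- S1 + w[i] * X[i, ]
      S2 <- S2 + w[i] * tcrossprod(X[i, ])
    }
    dset <- idx[event[idx] == 1]
    d <- length(dset)
    if (!d) next
    s0d <- sum(w[dset])
    s1d <- colSums(w[dset] * X[dset, , drop = FALSE])
    s2d <- matrix(0, p, p)
    for (i in dset) s2d <- s2d + w[i] * tcrossprod(X[i, ])
    ll <- ll + sum(eta[dset])
    grad <- grad + colSums(X[dset, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      fr <- l / d
      den <- S0 - fr * s0d
      z1 <- S1 - fr * s1d
      z2 <- S2 - fr * s2d
      ll <- ll - log(den)
      grad <- grad - z1 / den
      info <- info + z2 / den - tcrossprod(z1) / den^2
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model (Efron ties)
#'
#' Maximizes the Efron-approximated partial likelihood by Newton-Raphson
#' with step-halving whenever a step would decrease the likelihood.
#' Convergence is declared when the relative log-likelihood change falls
#' below `tol` (default 1e-9) within `max_iter` (default 50) iterations.
#' Monotone-likelihood divergence (any `|beta| > 15`) is detected and
#' flagged, as is non-convergence; neither is silent. Rows with missing
#' values in the used columns are dropped with a message. Wald 95%
#' confidence intervals come from the observed information.
#'
#' @param data data.frame with time/event columns and covariates.
#' @param covariates Character vector of covariate column names (numeric or
#'   binary).
#' @param time_col,event_col Column names (defaults `"time"`, `"event"`).
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `cox_fit` with elements `coef`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `p` (Wald), `loglik` (null, final), `iter`,
#'   `converged`, `diverged`, `var` (covariance of coef), `means`, `n`,
#'   `n_events`, and the sorted model frame for baseline-hazard prediction.
#' @export
cox_fit <- function(data, covariates, time_col = "time",
                    event_col = "event", max_iter = 50, tol = 1e-9) {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  need <- c(time_col, event_col, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[need]
  ok <- stats::complete.cases(d)
  if (any(!ok)) {
    message("dropping ", sum(!ok), " row(s) with missing values")
    d <- d[ok, , drop = FALSE]
  }
  time <- d[[time_col]]; event <- d[[event_col]]
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  if (sum(event) < 1) stop("need at least one event")
  X <- as.matrix(d[covariates])
  storage.mode(X) <- "double"
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant covariate(s): ",
         paste(covariates[const], collapse = ", "))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  means <- colMeans(X)
  Xc <- sweep(X, 2L, means)

  p <- ncol(Xc)
  beta <- rep(0, p)
  cur <- cox_lgh(beta, time, event, Xc)
  ll0 <- cur$ll
  converged <- FALSE; iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(cur$info, cur$grad),
                     error = function(e) cur$grad / (diag(cur$info) + 1e-10))
    fac <- 1
    repeat {
      cand <- beta + fac * step
      nxt <- cox_lgh(cand, time, event, Xc)
      if (nxt$ll >= cur$ll - 1e-12 || fac < 1e-4) break
      fac <- fac / 2                         # damping on likelihood decrease
    }
    rel <- abs(nxt$ll - cur$ll) / (abs(cur$ll) + 0.1)
    beta <- cand; cur <- nxt
    if (rel < tol) { converged <- TRUE; break }
  }
  diverged <- any(abs(beta) > 15)
  if (diverged)
    warning("monotone-likelihood divergence detected (|beta| > 15)")
  if (!converged)
    warning("Cox model did not converge in ", max_iter, " iterations")
  vcv <- tryCatch(solve(cur$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcv))
  zq <- stats::qnorm(0.975)
  names(beta) <- covariates
  structure(list(coef = beta, se = stats::setNames(se, covariates),
                 hr = exp(beta),
                 ci_lower = exp(beta - zq * se),
                 ci_upper = exp(beta + zq * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = c(null = ll0, final = cur$ll),
                 iter = iter, converged = converged, diverged = diverged,
                 var = vcv, means = means,
                 n = length(time), n_events = sum(event),
                 time = time, event = event, x = X,
                 covariates = covariates),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n = ", x$n, ", events = ",
      x$n_events, "\n", sep = "")
  print(data.frame(coef = signif(x$coef, 4), HR = signif(x$hr, 4),
                   `lower .95` = signif(x$ci_lower, 4),
                   `upper .95` = signif(x$ci_upper, 4),
                   p = signif(x$p, 3), check.names = FALSE))
  if (!x$converged) cat("WARNING: did not converge\n")
  if (x$diverged) cat("WARNING: monotone-likelihood divergence\n")
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  print(object)
  cat(sprintf("log-likelihood: %.4f (null %.4f), %d iterations\n",
              object$loglik["final"], object$loglik["null"], object$iter))
  invisible(object)
}

#' @export
coef.cox_fit <- function(object, ...) object$coef

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coef),
            class = "logLik")
}

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coef - zq * object$se, object$coef + zq * object$se)
  colnames(ci) <- paste(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.cox_fit <- function(object, newdata = NULL,
                            type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$x else
    as.matrix(newdata[object$covariates])
  lp <- drop(sweep(X, 2L, object$means) %*% object$coef)
  if (type == "risk") exp(lp) else lp
}

# Breslow baseline cumulative hazard at the covariate reference (zero
# centered covariates = dataset means), evaluated at each event time.
breslow_basehaz <- function(fit) {
  eta <- drop(sweep(fit$x, 2L, fit$means) %*% fit$coef)
  w <- exp(eta)
  ut <- sort(unique(fit$time[fit$event == 1]))
  h <- vapply(ut, function(t)
    sum(fit$event == 1 & fit$time == t) / sum(w[fit$time >= t]),
    numeric(1))
  list(time = ut, cumhaz = cumsum(h))
}

#' Predicted survival curves at a covariate profile
#'
#' `S(t | x) = S0(t)^exp(beta . (x - means))` with the Breslow baseline
#' cumulative hazard taken at the dataset covariate means; one curve per
#' level of the stratifying treatment, all other covariates held at their
#' means (or at the supplied `profile` values).
#'
#' @param fit A converged [cox_fit()].
#' @param treatment Name of the model covariate to stratify on.
#' @param levels Values of `treatment` to plot (default `c(0, 1)`).
#' @param profile Optional named list/vector fixing other covariates;
#'   anything not named stays at its dataset mean. Naming a covariate absent
#'   from the model is an error.
#' @return List of class `cox_curves`: per level, a list with `time` and
#'   `surv`.
#' @export
predicted_curves <- function(fit, treatment, levels = c(0, 1),
                             profile = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("model did not converge")
  if (!treatment %in% fit$covariates)
    stop("'", treatment, "' is not a model covariate")
  prof <- fit$means
  if (!is.null(profile)) {
    profile <- unlist(profile)
    bad <- setdiff(names(profile), fit$covariates)
    if (length(bad))
      stop("profile covariate(s) absent from the model: ",
           paste(bad, collapse = ", "))
    prof[names(profile)] <- profile
  }
  bh <- breslow_basehaz(fit)
  curves <- lapply(levels, function(v) {
    x <- prof; x[treatment] <- v
    risk <- exp(sum(fit$coef * (x - fit$means)))
    list(time = bh$time, surv = exp(-bh$cumhaz * risk))
  })
  names(curves) <- paste0(treatment, "=", levels)
  structure(curves, class = "cox_curves", treatment = treatment)
}

#' @export
plot.cox_curves <- function(x, xlab = "Days",
                            ylab = "Predicted survival", ...) {
  graphics::plot(NA, xlim = c(0, max(x[[1]]$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x)) {
    cv <- x[[i]]
    graphics::lines(c(0, rep(cv$time, each = 2)),
                    c(1, 1, rep(cv$surv, each = 2)[-2 * length(cv$surv)]),
                    col = i)
  }
  graphics::legend("topright", legend = names(x), col = seq_along(x),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Per-subtype Cox treatment analysis
#'
#' Fits one joint Cox model per subtype stratum over the supplied
#' covariates (default age, G-CIMP, radiotherapy, temozolomide) and emits a
#' per-(subtype, treatment) hazard-ratio table. A stratum with fewer than
#' 10 events is analyzed but flagged with a warning.
#'
#' @param clinical Clinical data.frame with `time`, `event`, the covariates,
#'   and a `sample` column.
#' @param calls Either a `subtype_call` data.frame (columns `sample`,
#'   `label`) or a named character vector of per-sample labels.
#' @param covariates Covariates of the per-stratum models.
#' @param treatments Which covariates are treatments to tabulate.
#' @return List with `fits` (named list of `cox_fit`) and `table`
#'   (data.frame: subtype, treatment, hr, ci_lower, ci_upper, p).
#' @export
subtype_treatment_analysis <- function(clinical, calls,
                                       covariates = c("age", "gcimp",
                                                      "radiotherapy",
                                                      "temozolomide"),
                                       treatments = c("radiotherapy",
                                                      "temozolomide")) {
  if (inherits(calls, "data.frame")) {
    labels <- stats::setNames(calls$label, calls$sample)
  } else labels <- calls
  clinical$`.subtype` <- labels[clinical$sample]
  if (anyNA(clinical$`.subtype`))
    stop("subtype call missing for some samples")
  fits <- list(); rows <- list()
  for (st in unique(clinical$`.subtype`)) {
    d <- clinical[clinical$`.subtype` == st, , drop = FALSE]
    if (sum(d$event) < 1) stop("subtype stratum '", st, "' has no events")
    if (sum(d$event) < 10)
      warning("subtype stratum '", st, "' has fewer than 10 events")
    fit <- cox_fit(d, covariates)
    fits[[st]] <- fit
    for (tr in intersect(treatments, covariates)) {
      rows[[length(rows) + 1L]] <-
        data.frame(subtype = st, treatment = tr,
                   hr = fit$hr[[tr]], ci_lower = fit$ci_lower[[tr]],
                   ci_upper = fit$ci_upper[[tr]], p = fit$p[[tr]],
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
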