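#' Ridge-penalized Cox proportional hazards fit
#'
#' Newton-Raphson maximization of the Breslow-ties partial likelihood
#' with an L2 penalty lambda * ||beta||^2. Convergence is declared when
#' the relative change in penalized log partial likelihood falls below
#' `tol`.
#'
#' @param time,event Survival times (> 0) and event indicators (0/1).
#' @param x Covariate matrix (patients x features), typically z-scored.
#' @param lambda L2 penalty.
#' @param max_iter Iteration cap; non-convergence is an error carrying
#'   the iteration trace.
#' @param tol Relative log-likelihood tolerance.
#' @return Named coefficient vector with attributes `loglik` and `iter`.
#' @export
fit_cox_ridge <- function(time, event, x, lambda = 0.1, max_iter = 100,
                          tol = 1e-8) {
  x <- as.matrix(x)
  if (sum(event) < 2) stop("need at least 2 events")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) stop("zero-variance feature(s): ",
                        paste(colnames(x)[v == 0], collapse = ", "))
  n <- nrow(x); p <- ncol(x)
  ord <- order(time, -event)   # increasing time; events before censorings
  x <- x[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]

  pll <- function(beta) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    # Breslow: risk set at each event time = all with time >= t
    rs <- rev(cumsum(rev(w)))
    # handle ties: all events at the same time share the same risk set
    first_at_time <- match(time, time)
    sum(eta[event == 1] - log(rs[first_at_time][event == 1])) -
      lambda * sum(beta^2)
  }

  beta <- rep(0, p)
  ll_old <- pll(beta)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    first_at_time <- match(time, time)
    S0 <- rev(cumsum(rev(w)))[first_at_time]
    S1 <- apply(x * w, 2, function(col) rev(cumsum(rev(col))))[first_at_time, ,
                                                               drop = FALSE]
    grad <- colSums(x[event == 1, , drop = FALSE] -
                      S1[event == 1, , drop = FALSE] /
                      S0[event == 1]) - 2 * lambda * beta
    # suffix-accumulated weighted second moments: S2[i] = sum_{j>=i} w_j x_j x_j'
    S2_suffix <- vector("list", n)
    acc <- matrix(0, p, p)
    for (i in n:1) {
      acc <- acc + w[i] * tcrossprod(x[i, ])
      S2_suffix[[i]] <- acc
    }
    H <- matrix(0, p, p)
    for (i in which(event == 1)) {
      fi <- first_at_time[i]
      xb <- S1[i, ] / S0[i]
      H <- H + S2_suffix[[fi]] / S0[i] - tcrossprod(xb)
    }
    H <- H + 2 * lambda * diag(p)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + 1e-8 * diag(p), grad)
    })
    beta_new <- beta + step
    ll_new <- pll(beta_new)
    # damped step if the penalized likelihood decreases
    halvings <- 0
    while (ll_new < ll_old && halvings < 20) {
      step <- step / 2
      beta_new <- beta + step
      ll_new <- pll(beta_new)
      halvings <- halvings + 1
    }
    trace <- c(trace, ll_new)
    rel <- abs(ll_new - ll_old) / (abs(ll_old) + 1e-12)
    beta <- beta_new; ll_old <- ll_new
    if (rel < tol) {
      names(beta) <- colnames(x)
      attr(beta, "loglik") <- ll_new
      attr(beta, "iter") <- it
      return(beta)
    }
  }
  stop("Cox ridge fit did not converge in ", max_iter,
       " iterations; log-likelihood trace: ",
       paste(sprintf("%.6f", utils::tail(trace, 5)), collapse = ", "))
}

#' Bootstrap a prognostic retro-miR signature
#'
#' Fits the ridge Cox model on `n_boot` bootstrap resamples; a feature
#' enters the signature when (i) its coefficient keeps one sign in at
#' least `keep_frac` of resamples and (ii) its bootstrap z-statistic
#' (mean / sd over resamples) is significant after Bonferroni correction
#' across the candidate features. The sign rule alone does not calibrate:
#' resamples of one dataset share its sampling noise, so a null feature
#' with a modest in-sample coefficient is sign-stable. Signature
#' coefficients are the bootstrap means; patient scores are
#' sum(beta_i * z_i) of standardized log1p expression.
#'
#' @param records Data frame with `time`, `event`, and feature columns.
#' @param features Feature (column) names to consider.
#' @param n_boot Number of bootstrap resamples.
#' @param keep_frac Sign-consistency fraction for feature selection.
#' @param alpha Family-wise level of the bootstrap z-test (Bonferroni
#'   over the candidate features).
#' @param lambda Ridge penalty passed to [fit_cox_ridge()].
#' @param seed Optional RNG seed (fixed seed gives an identical model).
#' @return A `signature_model`: `features`, `coefficients`,
#'   `consistency`, `boot_coefs`, and the standardization `center`/`scale`.
#' @export
bootstrap_signature <- function(records, features, n_boot = 100,
                                keep_frac = 0.8, lambda = 0.1, seed = NULL,
                                alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  z <- scale(log1p(as.matrix(records[, features, drop = FALSE])))
  center <- attr(z, "scaled:center"); scl <- attr(z, "scaled:scale")
  n <- nrow(records)
  coefs <- matrix(NA_real_, nrow = n_boot, ncol = length(features),
                  dimnames = list(NULL, features))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    zb <- z[idx, , drop = FALSE]
    ok <- apply(zb, 2, stats::var) > 0
    if (sum(records$event[idx]) < 2 || !any(ok)) next
    fit <- tryCatch(
      fit_cox_ridge(records$time[idx], records$event[idx],
                    zb[, ok, drop = FALSE], lambda = lambda),
      error = function(e) NULL)
    if (!is.null(fit)) coefs[b, names(fit)] <- fit
  }
  used <- stats::complete.cases(coefs)
  cf <- coefs[used, , drop = FALSE]
  pos_frac <- colMeans(cf > 0)
  consistency <- pmax(pos_frac, 1 - pos_frac)
  bmean <- colMeans(cf)
  bsd <- apply(cf, 2, stats::sd)
  zstat <- ifelse(bsd > 0, bmean / bsd, 0)
  pz <- 2 * stats::pnorm(-abs(zstat))
  keep <- consistency >= keep_frac & pz < alpha / length(features)
  structure(list(
    features = features[keep],
    coefficients = bmean[keep],
    consistency = consistency,
    z = zstat, p = pz,
    boot_coefs = cf,
    n_boot_used = sum(used),
    center = center, scale = scl,
    lambda = lambda, keep_frac = keep_frac
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("retro-miR survival signature (%d/%d bootstrap fits)\n",
              x$n_boot_used, nrow(x$boot_coefs)))
  if (length(x$features) == 0) {
    cat("  (empty signature: no sign-consistent feature)\n")
  } else {
    for (f in x$features) {
      cat(sprintf("  %s  beta = %+.3f  consistency = %.2f\n",
                  f, x$coefficients[[f]], x$consistency[[f]]))
    }
  }
  invisible(x)
}

#' Score patients with a signature model
#'
#' @param model A `signature_model`.
#' @param records Data frame with the model's feature columns.
#' @return Numeric score per patient (0 when the signature is empty).
#' @export
score_patients <- function(model, records) {
  if (length(model$features) == 0) return(rep(0, nrow(records)))
  x <- log1p(as.matrix(records[, model$features, drop = FALSE]))
  z <- sweep(sweep(x, 2, model$center[model$features]), 2,
             model$scale[model$features], "/")
  drop(z %*% model$coefficients)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event Survival data; censored observations at t do not
#'   count as events at t.
#' @return Data frame: `time`, `n_risk`, `n_event`, `surv` (one row per
#'   distinct event time, plus a t = 0 row with S = 1).
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = c(0, fit$time[keep]),
             n_risk = c(fit$n[1], fit$n.risk[keep]),
             n_event = c(0, fit$n.event[keep]),
             surv = c(1, fit$surv[keep]))
}

#' Two-group log-rank test
#'
#' @param timeA,eventA,timeB,eventB Survival data per group.
#' @return List: `chi2` (O-E statistic, 1 df) and `p`.
#' @export
logrank_test <- function(timeA, eventA, timeB, eventB) {
  if (length(timeA) == 0 || length(timeB) == 0) stop("empty group")
  time <- c(timeA, timeB); event <- c(eventA, eventB)
  grp <- c(rep("A", length(timeA)), rep("B", length(timeB)))
  if (sum(event) == 0) return(list(chi2 = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Evaluate a signature: median split, KM curves, log-rank p
#'
#' Patients are scored and split at the in-sample median score (ties go
#' to the low group); Kaplan-Meier curves are estimated per group and
#' compared by log-rank test.
#'
#' @param model A `signature_model`.
#' @param records Data frame with `time`, `event`, feature columns.
#' @return List: `scores`, `group` ("low"/"high"), `km` (list of two KM
#'   tables), `chi2`, `p`, `median_surv` (per group).
#' @export
evaluate_signature <- function(model, records) {
  scores <- score_patients(model, records)
  thr <- stats::median(scores)
  group <- ifelse(scores <= thr, "low", "high")
  if (length(unique(group)) < 2) {
    return(list(scores = scores, group = group, km = NULL,
                chi2 = NA_real_, p = NA_real_, median_surv = NULL))
  }
  lo <- group == "low"; hi <- group == "high"
  km <- list(low = km_estimate(records$time[lo], records$event[lo]),
             high = km_estimate(records$time[hi], records$event[hi]))
  lr <- logrank_test(records$time[lo], records$event[lo],
                     records$time[hi], records$event[hi])
  med_surv <- vapply(km, function(k) {
    below <- k$time[k$surv <= 0.5]
    if (length(below) == 0) NA_real_ else min(below)
  }, numeric(1))
  list(scores = scores, group = group, km = km, chi2 = lr$chi2, p = lr$p,
       median_surv = med_surv)
}
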