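#' Nelson-Aalen cumulative-hazard estimate on counting-process data
#'
#' Step-function estimate of the cumulative hazard from (start, stop,
#' status) records.  The increment at each distinct event time \eqn{t} is
#' the number of events at \eqn{t} divided by the number at risk there,
#' where a record is at risk at \eqn{t} iff \eqn{start < t \le stop}; holes
#' between a subject's records (risk-free intervals) therefore reduce the
#' denominator.
#'
#' @param table a counting-process \code{data.frame} with columns
#'   \code{start}, \code{stop}, \code{status} (0/1).
#' @return an object of class \code{"nelson_aalen"} with components
#'   \code{time}, \code{n_event}, \code{n_risk}, \code{increment},
#'   \code{cumhaz}.
#' @export
nelson_aalen <- function(table) {
  tab <- .check_cp(table)
  ev <- tab$stop[tab$status == 1]
  if (length(ev) == 0L) {
    out <- list(time = numeric(0), n_event = integer(0),
                n_risk = integer(0), increment = numeric(0),
                cumhaz = numeric(0))
    return(structure(out, class = "nelson_aalen"))
  }
  tt <- sort(unique(ev))
  n_event <- as.integer(tabulate(match(ev, tt), nbins = length(tt)))
  # at risk at t: start < t <= stop
  n_risk <- .count_atrisk(tab$start, tab$stop, tt)
  inc <- n_event / n_risk
  structure(list(time = tt, n_event = n_event, n_risk = n_risk,
                 increment = inc, cumhaz = cumsum(inc)),
            class = "nelson_aalen")
}

# number of records with start < t <= stop, vectorised over sorted-free t
.count_atrisk <- function(start, stop, t) {
  ss <- sort(start); es <- sort(stop)
  # #{start < t} - #{stop < t}
  findInterval(t, ss, left.open = TRUE) -
    findInterval(t, es, left.open = TRUE)
}

#' @export
print.nelson_aalen <- function(x, ...) {
  cat("Nelson-Aalen cumulative hazard estimate\n")
  cat(sprintf("  %d distinct event times", length(x$time)))
  if (length(x$time))
    cat(sprintf("; final estimate %.4f at t = %g",
                x$cumhaz[length(x$cumhaz)], x$time[length(x$time)]))
  cat("\n")
  invisible(x)
}

#' Evaluate a Nelson-Aalen estimate at given times
#'
#' @param object a \code{"nelson_aalen"} object.
#' @param times times at which to evaluate the step function.
#' @param ... unused.
#' @return the estimate at each time (0 before the first event).
#' @export
predict.nelson_aalen <- function(object, times, ...) {
  if (length(object$time) == 0L) return(rep(0, length(times)))
  c(0, object$cumhaz)[findInterval(times, object$time) + 1L]
}

#' @export
plot.nelson_aalen <- function(x, ..., xlab = "total time",
                              ylab = "cumulative hazard") {
  graphics::plot(c(0, x$time), c(0, x$cumhaz), type = "s",
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# validate a counting-process table
.check_cp <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("counting-process table must be a data.frame with >= 1 record",
         call. = FALSE)
  need <- c("start", "stop", "status")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(table$start >= table$stop))
    stop("records with start >= stop are invalid", call. = FALSE)
  if (!all(table$status %in% c(0, 1)))
    stop("status must be 0 or 1", call. = FALSE)
  table
}

# risk-set sums used by the partial likelihood.
# For weights w (per record), returns for each distinct event time t_k
#   sum_{start_i < t_k <= stop_i} w_i
# computed as prefix sums over records sorted by start and by stop.
.riskset_env <- function(start, stop, status) {
  ev <- which(status == 1)
  if (length(ev) == 0L) stop("no events in table", call. = FALSE)
  tt <- sort(unique(stop[ev]))
  list(
    tt = tt,
    ev = ev,
    kidx = match(stop[ev], tt),
    ord_s = order(start), ord_e = order(stop),
    cnt_s = findInterval(tt, sort(start), left.open = TRUE),
    cnt_e = findInterval(tt, sort(stop), left.open = TRUE)
  )
}

.riskset_sum <- function(rs, w) {
  cs <- c(0, cumsum(w[rs$ord_s]))
  ce <- c(0, cumsum(w[rs$ord_e]))
  cs[rs$cnt_s + 1L] - ce[rs$cnt_e + 1L]
}

#' Fit the Andersen-Gill model to counting-process data
#'
#' Maximises the start/stop partial likelihood of the Andersen-Gill
#' intensity \eqn{Y(t)\lambda_0(t)e^{\beta^\top x}} by Newton-Raphson with
#' Breslow handling of ties.  The risk set at an event time \eqn{t}
#' consists of records with \eqn{start < t \le stop}.  Reports the naive
#' variance (inverse observed information) and the robust clustered
#' sandwich variance
#' \eqn{I^{-1} (\sum_g s_g s_g^\top) I^{-1}} with \eqn{s_g} the summed
#' score residuals of subject \eqn{g}'s records — required for valid tests
#' when unobserved inter-patient heterogeneity (frailty) is ignored.
#'
#' Newton-Raphson starts at \eqn{\beta = 0}, declares convergence when the
#' log partial likelihood changes by less than 1e-9, uses step-halving on
#' likelihood decreases, and flags nonconvergence (including monotone
#' likelihood / separation) after 25 iterations or when a coefficient
#' diverges; a nonconverged fit is returned flagged, never silently.
#'
#' @param table counting-process \code{data.frame} with columns \code{id},
#'   \code{start}, \code{stop}, \code{status} and covariate columns.
#' @param covariates character vector of covariate column names; default
#'   all columns named \code{x1}, \code{x2}, ...
#' @return an object of class \code{"agfit"}: \code{coefficients},
#'   \code{naive_se}, \code{robust_se}, \code{var_naive}, \code{var_robust},
#'   \code{loglik}, \code{iter}, \code{converged}, \code{n}, \code{n_subjects},
#'   \code{n_events}, and a \code{wald} table with z and p for both SE
#'   flavours.
#' @examples
#' hm <- hazard_model("weibull", scale = 4 / sqrt(2), shape = 0.5)
#' eff <- effect_spec(beta = 1, covariates = list(cov_bernoulli(0.5)))
#' d <- simulate_recurrent(hm, eff, censoring = censoring_spec(2),
#'                         n = 100, seed = 7)
#' fit <- agfit(d)
#' summary(fit)
#' @export
agfit <- function(table, covariates = NULL) {
  tab <- .check_cp(table)
  if (!"id" %in% names(tab)) stop("table lacks an 'id' column", call. = FALSE)
  if (is.null(covariates)) {
    covariates <- grep("^x[0-9]+$", names(tab), value = TRUE)
  }
  if (length(covariates) == 0L)
    stop("no covariate columns found", call. = FALSE)
  if (!all(covariates %in% names(tab)))
    stop("unknown covariate column(s): ",
         paste(setdiff(covariates, names(tab)), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(tab[covariates])
  storage.mode(X) <- "double"
  if (any(apply(X, 2, function(v) max(v) - min(v)) == 0))
    stop("covariate(s) constant: no information about their effect",
         call. = FALSE)
  p <- ncol(X)
  rs <- .riskset_env(tab$start, tab$stop, tab$status)
  K <- length(rs$tt)
  # per-event-time event counts and covariate sums (Breslow ties)
  dtab <- rowsum(cbind(1, X[rs$ev, , drop = FALSE]), rs$kidx)
  d_k <- dtab[, 1]
  sx_k <- dtab[, -1, drop = FALSE]
  sum_dx <- colSums(sx_k)

  pl_parts <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    S0 <- .riskset_sum(rs, w)
    S1 <- matrix(0, K, p)
    for (j in seq_len(p)) S1[, j] <- .riskset_sum(rs, w * X[, j])
    logpl <- sum(eta[rs$ev]) - sum(d_k * log(S0))
    xbar <- S1 / S0
    U <- sum_dx - colSums(d_k * xbar)
    I <- matrix(0, p, p)
    for (j in seq_len(p)) {
      for (l in j:p) {
        S2jl <- .riskset_sum(rs, w * X[, j] * X[, l])
        I[j, l] <- I[l, j] <- sum(d_k * (S2jl / S0 - xbar[, j] * xbar[, l]))
      }
    }
    list(logpl = logpl, U = U, I = I, w = w, S0 = S0, xbar = xbar)
  }

  beta <- rep(0, p)
  parts <- pl_parts(beta)
  converged <- FALSE
  iter <- 0L
  diverged <- FALSE
  while (iter < 25L) {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$I, parts$U), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    new_beta <- beta + step
    new_parts <- pl_parts(new_beta)
    halves <- 0L
    while (is.finite(new_parts$logpl) == FALSE ||
           new_parts$logpl < parts$logpl - 1e-12) {
      if (halves >= 20L) break
      halves <- halves + 1L
      new_beta <- beta + (new_beta - beta) / 2
      new_parts <- pl_parts(new_beta)
    }
    delta <- new_parts$logpl - parts$logpl
    beta <- new_beta
    parts <- new_parts
    if (any(abs(beta) > 20) || !is.finite(parts$logpl)) {
      diverged <- TRUE  # monotone likelihood / separation
      break
    }
    if (abs(delta) < 1e-9) { converged <- TRUE; break }
  }

  var_naive <- tryCatch(solve(parts$I), error = function(e) {
    matrix(NA_real_, p, p)
  })

  # score residuals per record (Breslow), then summed per subject
  dL <- d_k / parts$S0
  cumH <- c(0, cumsum(dL))
  a_e <- findInterval(tab$stop, rs$tt)
  a_s <- findInterval(tab$start, rs$tt)
  score <- matrix(0, nrow(tab), p)
  for (j in seq_len(p)) {
    cumHX <- c(0, cumsum(dL * parts$xbar[, j]))
    expect <- parts$w * (X[, j] * (cumH[a_e + 1L] - cumH[a_s + 1L]) -
                           (cumHX[a_e + 1L] - cumHX[a_s + 1L]))
    obs <- numeric(nrow(tab))
    obs[rs$ev] <- X[rs$ev, j] - parts$xbar[rs$kidx, j]
    score[, j] <- obs - expect
  }
  sg <- rowsum(score, tab$id)
  var_robust <- var_naive %*% crossprod(sg) %*% var_naive

  naive_se <- sqrt(diag(var_naive))
  robust_se <- sqrt(diag(var_robust))
  names(beta) <- covariates
  z_n <- beta / naive_se
  z_r <- beta / robust_se
  wald <- data.frame(
    coef = beta,
    naive_se = naive_se, z_naive = z_n,
    p_naive = 2 * stats::pnorm(-abs(z_n)),
    robust_se = robust_se, z_robust = z_r,
    p_robust = 2 * stats::pnorm(-abs(z_r)),
    row.names = covariates
  )
  structure(list(coefficients = beta, naive_se = naive_se,
                 robust_se = robust_se, var_naive = var_naive,
                 var_robust = var_robust, loglik = parts$logpl,
                 iter = iter, converged = converged && !diverged,
                 n = nrow(tab), n_subjects = length(unique(tab$id)),
                 n_events = sum(tab$status == 1), wald = wald,
                 score_cluster = sg, covariates = covariates),
            class = "agfit")
}

#' @export
print.agfit <- function(x, ...) {
  cat("Andersen-Gill fit (Breslow ties, clustered sandwich variance)\n")
  cat(sprintf("  %d subjects, %d records, %d events; logPL = %.4f\n",
              x$n_subjects, x$n, x$n_events, x$loglik))
  if (!x$converged)
    cat("  WARNING: Newton-Raphson did not converge",
        "(possible monotone likelihood)\n")
  print(round(x$wald[c("coef", "naive_se", "robust_se", "p_robust")], 5))
  invisible(x)
}

#' @export
summary.agfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.agfit")
}

#' @export
print.summary.agfit <- function(x, ...) {
  f <- x$fit
  print(f)
  ci <- cbind(f$coefficients - 1.96 * f$robust_se,
              f$coefficients + 1.96 * f$robust_se)
  colnames(ci) <- c("lower .95", "upper .95")
  cat("Hazard ratios with robust 95% CIs:\n")
  print(round(cbind(HR = exp(f$coefficients), exp(ci)), 4))
  invisible(x)
}

#' @export
coef.agfit <- function(object, ...) object$coefficients

#' Variance matrix of an Andersen-Gill fit
#' @param object an \code{"agfit"} object.
#' @param type \code{"robust"} (clustered sandwich, default) or
#'   \code{"naive"} (inverse observed information).
#' @param ... unused.
#' @export
vcov.agfit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$var_robust else object$var_naive
}

#' Per-subject score residuals of an Andersen-Gill fit
#' @param object an \code{"agfit"} object.
#' @param ... unused.
#' @return matrix of score residuals summed per subject (the clustered
#'   sandwich building block).
#' @export
residuals.agfit <- function(object, ...) object$score_cluster

#' Wald test of a single Andersen-Gill coefficient
#'
#' Two-sided test of \eqn{H_0: \beta_j = 0} using either the robust
#' (clustered sandwich) or naive standard error; rejects iff
#' \eqn{|\hat\beta_j / se| > z_{1-\alpha/2}}.
#'
#' @param fit a converged \code{"agfit"}.
#' @param coef coefficient index or name (default first).
#' @param level significance level \eqn{\alpha}.
#' @param robust use the robust SE (default) or the naive SE.
#' @return list with \code{z}, \code{p}, \code{reject}, \code{se},
#'   \code{se_type}.
#' @export
wald_test <- function(fit, coef = 1L, level = 0.05, robust = TRUE) {
  stopifnot(inherits(fit, "agfit"))
  if (!fit$converged)
    stop("Wald test requires a converged fit", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  b <- fit$coefficients[coef]
  se <- if (robust) fit$robust_se[coef] else fit$naive_se[coef]
  z <- unname(b / se)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p,
       reject = abs(z) > stats::qnorm(1 - level / 2),
       se = unname(se), se_type = if (robust) "robust" else "naive")
}
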