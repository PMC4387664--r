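#' Weibull scale from a cumulative incidence
#'
#' For a Weibull cumulative hazard \eqn{\Lambda(t) = \lambda t^\nu}, the
#' scale consistent with an expected number of events (cumulative
#' incidence) over a planning horizon is
#' \eqn{\lambda = incidence / horizon^\nu}, so that
#' \eqn{\Lambda(horizon) = incidence}.
#'
#' @param incidence expected events per subject over the horizon (> 0).
#' @param horizon planning horizon in study time units (> 0).
#' @param shape Weibull shape \eqn{\nu > 0}.
#' @return the scale \eqn{\lambda}.
#' @examples
#' weibull_scale_from_incidence(3.72, 2, 2)  # 0.93
#' weibull_scale_from_incidence(2.74, 2, 2)  # 0.685, ~0.69
#' @export
weibull_scale_from_incidence <- function(incidence, horizon, shape) {
  if (any(incidence <= 0) || any(horizon <= 0) || any(shape <= 0))
    stop("incidence, horizon and shape must all be > 0", call. = FALSE)
  incidence / horizon^shape
}

#' Hazard ratio of two Weibull scales with common shape
#'
#' Weibull hazards with a common shape are proportional at all times; the
#' ratio of their scales is the (time-constant) hazard ratio.
#'
#' @param scale_treat,scale_control positive scales.
#' @export
hazard_ratio <- function(scale_treat, scale_control) {
  if (any(scale_treat <= 0) || any(scale_control <= 0))
    stop("scales must be > 0", call. = FALSE)
  scale_treat / scale_control
}

#' Two-arm recurrent-event trial design
#'
#' A balanced randomised trial analysed with the Andersen-Gill model and a
#' (by default robust) two-sided Wald test of the intervention effect.
#' Subjects are followed for \code{followup} time units; a fraction
#' \code{dropout_prob} drop out at a uniform time before then.  The
#' control-arm baseline is Weibull with the given scale and shape; the
#' intervention is a single balanced-binary covariate with log hazard
#' ratio \code{log_hr}.  Optional gamma frailty (\code{frailty_variance})
#' and risk-free intervals make the design "complex" in the sense that no
#' closed-form sample-size formula applies.
#'
#' Defaults encode a falls-prevention trial: two-year incidences 3.72
#' (control) vs 2.74 (intervention) with shape 2 give scales 0.93 and 0.69
#' and hazard ratio 0.74; follow-up 2 years; 50% uniform dropout; 5%
#' two-sided level.
#'
#' @param control_scale,shape Weibull baseline of the control arm.
#' @param log_hr intervention log hazard ratio \eqn{\beta}.
#' @param frailty_variance gamma frailty variance \eqn{\theta \ge 0}.
#' @param riskfree a \code{\link{riskfree_spec}} (duration in study time
#'   units; weeks convert as \code{weeks / 52}).
#' @param followup end of follow-up \eqn{\tau}.
#' @param dropout_prob probability of uniform early dropout.
#' @param alpha two-sided significance level.
#' @param robust use robust (sandwich) SEs in the Wald test.
#' @return an object of class \code{"trial_design"}.
#' @export
trial_design <- function(control_scale = 0.93, shape = 2,
                         log_hr = log(0.74), frailty_variance = 0,
                         riskfree = riskfree_spec(), followup = 2,
                         dropout_prob = 0.5, alpha = 0.05, robust = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  model <- hazard_model("weibull", scale = control_scale, shape = shape)
  structure(list(model = model, control_scale = control_scale,
                 shape = shape, log_hr = log_hr,
                 frailty_variance = frailty_variance, riskfree = riskfree,
                 followup = followup, dropout_prob = dropout_prob,
                 alpha = alpha, robust = robust),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Two-arm recurrent-event trial design\n")
  cat(sprintf("  control baseline: weibull(scale = %g, shape = %g)\n",
              x$control_scale, x$shape))
  cat(sprintf("  hazard ratio: %.4f (beta = %.4f); frailty variance: %g\n",
              exp(x$log_hr), x$log_hr, x$frailty_variance))
  cat(sprintf("  risk-free: d = %g, p = %g; follow-up: %g; dropout: %g\n",
              x$riskfree$duration, x$riskfree$prob, x$followup,
              x$dropout_prob))
  cat(sprintf("  %s two-sided Wald test at level %g\n",
              if (x$robust) "robust" else "naive", x$alpha))
  invisible(x)
}

#' Simulate one trial dataset from a design
#'
#' @param design a \code{\link{trial_design}}.
#' @param n total (balanced) sample size, even.
#' @param seed optional integer seed.
#' @return a counting-process table with the intervention indicator
#'   \code{x1}.
#' @export
simulate_trial <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (n < 2 || n %% 2 != 0)
    stop("n must be even (balanced allocation) and >= 2", call. = FALSE)
  simulate_recurrent(
    design$model,
    effects = effect_spec(beta = design$log_hr,
                          covariates = list(cov_balanced()),
                          frailty_variance = design$frailty_variance),
    riskfree = design$riskfree,
    censoring = censoring_spec(design$followup, design$dropout_prob),
    n = n, seed = seed)
}

#' Monte-Carlo power of a trial design
#'
#' Simulates \code{nsim} trials of total size \code{n}, fits the
#' Andersen-Gill model to each and applies the design's Wald test; the
#' power is the rejection fraction among converged fits.  Nonconverged
#' replicates are dropped and counted, never silently included.
#' Per-replicate seeds are derived as \code{seed + k}, so the same
#' \code{seed} across different \code{n} gives (partially) common random
#' numbers.
#'
#' @param design a \code{\link{trial_design}}.
#' @param n total sample size (even).
#' @param nsim number of simulated trials.
#' @param seed integer base seed.
#' @return an object of class \code{"power_estimate"}: \code{power},
#'   \code{mc_se} (\eqn{\sqrt{power(1-power)/nsim}} over converged
#'   replicates), \code{nsim}, \code{n}, \code{nonconverged}, \code{seed}.
#' @export
estimate_power <- function(design, n, nsim = 1000, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (nsim < 1) stop("nsim must be >= 1", call. = FALSE)
  rej <- 0L
  bad <- 0L
  for (k in seq_len(nsim)) {
    sk <- if (is.null(seed)) NULL else (seed + k) %% 2147483647L
    dat <- simulate_trial(design, n, seed = sk)
    fit <- tryCatch(agfit(dat), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { bad <- bad + 1L; next }
    wt <- wald_test(fit, 1L, level = design$alpha, robust = design$robust)
    if (wt$reject) rej <- rej + 1L
  }
  m <- nsim - bad
  if (m == 0L) stop("no converged replicates", call. = FALSE)
  pw <- rej / m
  structure(list(power = pw, mc_se = sqrt(pw * (1 - pw) / m),
                 nsim = nsim, converged = m, nonconverged = bad,
                 n = n, seed = seed),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power %.4f (MC SE %.4f) at N = %d [%d/%d converged replicates]\n",
              x$power, x$mc_se, x$n, x$converged, x$nsim))
  invisible(x)
}

#' Simulation-based sample-size search
#'
#' Finds the smallest (even) total sample size on a step grid whose
#' Monte-Carlo power reaches the target: geometric bracketing by doubling
#' from \code{n_start}, bisection on the \code{step} grid, then a final
#' refinement on the \code{refine_step} grid; ties break toward smaller
#' N.  The full power profile of every evaluated N is returned.
#'
#' @param design a \code{\link{trial_design}}.
#' @param target_power target power in (0, 1).
#' @param nsim simulated trials per evaluated N.
#' @param seed integer base seed (shared across N: common random numbers).
#' @param step coarse grid step (even).
#' @param refine_step final grid step (even, divides \code{step}).
#' @param n_start lower search bound (even).
#' @param n_max upper search bound.
#' @return an object of class \code{"samplesize_search"}: \code{n0},
#'   \code{profile} (data.frame of n, power, mc_se, nonconverged),
#'   \code{target_power}, \code{nsim}, \code{seed}.
#' @export
find_sample_size <- function(design, target_power = 0.8, nsim = 1000,
                             seed = NULL, step = 4, refine_step = 2,
                             n_start = 32, n_max = 8192) {
  stopifnot(inherits(design, "trial_design"))
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must be in (0, 1)", call. = FALSE)
  if (step %% 2 != 0 || refine_step %% 2 != 0 || step < refine_step)
    stop("step and refine_step must be even with step >= refine_step",
         call. = FALSE)
  cache <- new.env(parent = emptyenv())
  profile <- list()
  pw <- function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]]$power)
    est <- estimate_power(design, n, nsim = nsim, seed = seed)
    cache[[key]] <- est
    profile[[length(profile) + 1L]] <<- est
    est$power
  }
  lo <- NULL
  n <- n_start
  while (pw(n) < target_power) {
    lo <- n
    n <- n * 2L
    if (n > n_max)
      stop("search bounds exhausted: power below target at n_max",
           call. = FALSE)
  }
  hi <- n
  if (is.null(lo)) {
    n0 <- n_start  # target already met at the lower search bound
  } else {
    while (hi - lo > step) {
      mid <- lo + step * max(1L, ((hi - lo) %/% 2L) %/% step)
      if (mid >= hi) mid <- hi - step
      if (pw(mid) >= target_power) hi <- mid else lo <- mid
    }
    n0 <- hi
    if (refine_step < step) {
      cand <- seq(lo + refine_step, hi, by = refine_step)
      for (m in cand) {
        if (pw(m) >= target_power) { n0 <- m; break }
      }
    }
  }
  prof <- do.call(rbind, lapply(profile, function(e) {
    data.frame(n = e$n, power = e$power, mc_se = e$mc_se,
               nonconverged = e$nonconverged)
  }))
  prof <- prof[order(prof$n), , drop = FALSE]
  rownames(prof) <- NULL
  structure(list(n0 = n0, profile = prof, target_power = target_power,
                 nsim = nsim, seed = seed),
            class = "samplesize_search")
}

#' @export
print.samplesize_search <- function(x, ...) {
  cat(sprintf("Required sample size N0 = %d for target power %.2f (nsim = %d per N)\n",
              x$n0, x$target_power, x$nsim))
  cat("Power profile:\n")
  print(transform(x$profile, power = round(power, 4),
                  mc_se = round(mc_se, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.samplesize_search <- function(x, ..., xlab = "total sample size N",
                                   ylab = "estimated power") {
  graphics::plot(x$profile$n, x$profile$power, type = "b",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$target_power, lty = 2)
  graphics::abline(v = x$n0, lty = 3)
  invisible(x)
}
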