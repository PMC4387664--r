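#' Draw gamma frailties with mean 1 and variance theta
#'
#' Subject-level frailty \eqn{Z} multiplies the hazard and induces
#' intra-patient correlation; it is gamma with shape \eqn{1/\theta} and
#' scale \eqn{\theta} so that \eqn{E(Z) = 1}, \eqn{Var(Z) = \theta}.
#' \code{theta = 0} is the degenerate frailty \eqn{Z \equiv 1} and consumes
#' no random numbers.
#'
#' @param theta frailty variance \eqn{\theta \ge 0}.
#' @param n number of draws.
#' @return a vector of \code{n} positive frailties.
#' @export
draw_frailty <- function(theta, n = 1) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("frailty variance theta must be a single number >= 0", call. = FALSE)
  if (theta == 0) return(rep(1, n))
  stats::rgamma(n, shape = 1 / theta, scale = theta)
}

#' Covariate generators
#'
#' Specifications for how each fixed covariate is drawn per subject:
#' \code{cov_bernoulli(prob)} draws 0/1 with success probability
#' \code{prob}; \code{cov_normal(mean, sd)} draws a Gaussian value;
#' \code{cov_balanced()} assigns exactly \code{floor(n/2)} subjects the
#' value 1 via a seeded permutation (trial randomisation); and
#' \code{cov_fixed(value)} sets a constant.
#'
#' @param prob success probability in \[0, 1\].
#' @param mean,sd Gaussian mean and standard deviation (\code{sd >= 0}).
#' @param value the constant value.
#' @return a covariate specification usable in \code{\link{effect_spec}}.
#' @name covariate_spec
NULL

#' @rdname covariate_spec
#' @export
cov_bernoulli <- function(prob) {
  if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
      prob < 0 || prob > 1)
    stop("bernoulli prob must be in [0, 1]", call. = FALSE)
  structure(list(type = "bernoulli", prob = as.numeric(prob)),
            class = "covariate_spec")
}

#' @rdname covariate_spec
#' @export
cov_normal <- function(mean = 0, sd = 1) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("normal sd must be >= 0", call. = FALSE)
  structure(list(type = "normal", mean = as.numeric(mean),
                 sd = as.numeric(sd)), class = "covariate_spec")
}

#' @rdname covariate_spec
#' @export
cov_balanced <- function() {
  structure(list(type = "balanced"), class = "covariate_spec")
}

#' @rdname covariate_spec
#' @export
cov_fixed <- function(value) {
  structure(list(type = "fixed", value = as.numeric(value)),
            class = "covariate_spec")
}

#' Covariate and frailty specification
#'
#' Bundles the regression coefficients \eqn{\beta}, one covariate generator
#' per coefficient, and the frailty variance \eqn{\theta}.  A subject with
#' covariates \eqn{x} and frailty \eqn{z} has hazard
#' \eqn{\lambda_0(t)\, z\, e^{\beta^\top x}}.
#'
#' @param beta numeric vector of log hazard ratios (may be empty).
#' @param covariates list of \code{\link{covariate_spec}} objects, same
#'   length as \code{beta}.
#' @param frailty_variance \eqn{\theta \ge 0}.
#' @export
effect_spec <- function(beta = numeric(0), covariates = list(),
                        frailty_variance = 0) {
  if (!is.numeric(beta)) stop("beta must be numeric", call. = FALSE)
  if (length(beta) != length(covariates))
    stop("beta and covariates must have the same length", call. = FALSE)
  if (length(covariates) &&
      !all(vapply(covariates, inherits, TRUE, "covariate_spec")))
    stop("covariates must be built with cov_bernoulli()/cov_normal()/",
         "cov_balanced()/cov_fixed()", call. = FALSE)
  if (!is.numeric(frailty_variance) || length(frailty_variance) != 1L ||
      is.na(frailty_variance) || frailty_variance < 0)
    stop("frailty_variance must be a single number >= 0", call. = FALSE)
  structure(list(beta = as.numeric(beta), covariates = covariates,
                 frailty_variance = as.numeric(frailty_variance)),
            class = "effect_spec")
}

#' Risk-free interval specification
#'
#' After each event, with probability \code{prob} the subject is
#' insusceptible for \code{duration} time units: the hazard is zero on
#' \eqn{[T_i, T_i + d]} and the subject leaves the risk set
#' (\eqn{Y(t) = 0}), so the next recursion starts from \eqn{T_i + d}.
#'
#' @param duration risk-free length \eqn{d \ge 0} in study time units.
#' @param prob probability \eqn{p \in [0, 1]} that an event is followed by
#'   a risk-free interval.
#' @export
riskfree_spec <- function(duration = 0, prob = 0) {
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration < 0)
    stop("risk-free duration must be a single number >= 0", call. = FALSE)
  if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
      prob < 0 || prob > 1)
    stop("risk-free prob must be in [0, 1]", call. = FALSE)
  structure(list(duration = as.numeric(duration), prob = as.numeric(prob)),
            class = "riskfree_spec")
}

#' Censoring specification
#'
#' Administrative censoring at the end of planned follow-up
#' \code{admin_time} \eqn{\tau}, with optional early dropout: each subject
#' independently is a dropout candidate with probability
#' \code{dropout_prob}, and candidates are censored at a uniform time on
#' \eqn{[0, \tau]}.
#'
#' @param admin_time end of follow-up \eqn{\tau > 0}.
#' @param dropout_prob dropout probability \eqn{q \in [0, 1]}.
#' @export
censoring_spec <- function(admin_time, dropout_prob = 0) {
  if (!is.numeric(admin_time) || length(admin_time) != 1L ||
      is.na(admin_time) || admin_time <= 0)
    stop("admin_time must be a single number > 0", call. = FALSE)
  if (!is.numeric(dropout_prob) || length(dropout_prob) != 1L ||
      is.na(dropout_prob) || dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must be in [0, 1]", call. = FALSE)
  structure(list(admin_time = as.numeric(admin_time),
                 dropout_prob = as.numeric(dropout_prob)),
            class = "censoring_spec")
}

#' Simulate one subject's recurrent-event path
#'
#' The recursive inversion algorithm on the total time scale: with
#' independent uniforms \eqn{a_i},
#' \eqn{t_1 = \Lambda^{-1}(-\log a_1)} and
#' \eqn{t_{i+1} = t_i + \tilde\Lambda_{t_i}^{-1}(-\log a_{i+1})}, all
#' inversions scaled by the subject's hazard factor
#' \eqn{c = z e^{\beta^\top x}}.  When an event is followed by a risk-free
#' interval of length \eqn{d}, the next recursion starts from
#' \eqn{t_i + d}:
#' \eqn{t_{i+1} = t_i + d + \tilde\Lambda_{t_i + d}^{-1}(-\log a_{i+1})}.
#' Recursion stops at the first candidate beyond the censoring time
#' (candidate discarded) or at a non-finite candidate (bounded cumulative
#' hazard exhausted).  A candidate exactly at the censoring time counts as
#' an event.
#'
#' @param model a \code{\link{hazard_model}} for the baseline.
#' @param effect_factor positive multiplicative hazard factor
#'   \eqn{z e^{\beta^\top x}}.
#' @param riskfree a \code{\link{riskfree_spec}}.
#' @param censor_time the subject's censoring time \eqn{C > 0}.
#' @param uniforms optional vector of uniforms to use for event draws
#'   (deterministic replay); drawn from the session RNG when \code{NULL}.
#' @param riskfree_uniforms optional vector of uniforms deciding risk-free
#'   intervals (compared against \code{riskfree$prob}).
#' @return list with \code{times} (strictly increasing event times
#'   \eqn{\le C}) and \code{riskfree} (logical flags, one per event).
#' @export
simulate_subject <- function(model, effect_factor = 1,
                             riskfree = riskfree_spec(),
                             censor_time,
                             uniforms = NULL, riskfree_uniforms = NULL) {
  if (!is.numeric(effect_factor) || length(effect_factor) != 1L ||
      is.na(effect_factor) || effect_factor <= 0)
    stop("effect_factor must be a single number > 0", call. = FALSE)
  if (!is.numeric(censor_time) || length(censor_time) != 1L ||
      is.na(censor_time) || censor_time <= 0)
    stop("censor_time must be a single number > 0", call. = FALSE)
  use_rf <- riskfree$prob > 0 && riskfree$duration > 0
  gap_fn <- .make_gap_fn(model, effect_factor)
  next_u <- local({
    i <- 0L
    function() {
      if (is.null(uniforms)) return(stats::runif(1))
      i <<- i + 1L
      if (i > length(uniforms)) stop("ran out of supplied uniforms")
      uniforms[i]
    }
  })
  next_rf <- local({
    j <- 0L
    function() {
      if (is.null(riskfree_uniforms)) return(stats::runif(1))
      j <<- j + 1L
      if (j > length(riskfree_uniforms))
        stop("ran out of supplied risk-free uniforms")
      riskfree_uniforms[j]
    }
  })
  times <- numeric(0)
  flags <- logical(0)
  base <- 0
  repeat {
    gap <- gap_fn(base, -log(next_u()))
    cand <- base + gap
    if (!is.finite(cand) || cand > censor_time) break
    times <- c(times, cand)
    rf <- if (use_rf) next_rf() < riskfree$prob else FALSE
    flags <- c(flags, rf)
    base <- cand + if (rf) riskfree$duration else 0
  }
  list(times = times, riskfree = flags)
}

# scalar gap computation g = inv_cond_cum_hazard(model, t, u / factor),
# inlined per family: the recursion calls this once per candidate event,
# so the generic dispatch/validation path would dominate simulation cost
.make_gap_fn <- function(model, factor) {
  p <- model$params
  switch(model$family,
    weibull = function(t, u) {
      ((u / factor + p$scale * t^p$shape) / p$scale)^(1 / p$shape) - t
    },
    gompertz = if (abs(p$shape) < .gompertz_alpha_eps) {
      function(t, u) u / factor / p$scale
    } else {
      function(t, u) {
        arg <- p$shape / p$scale * (u / factor) + exp(p$shape * t)
        if (arg <= 0) return(Inf)
        log(arg) / p$shape - t
      }
    },
    lognormal = function(t, u) {
      logS_t <- if (t == 0) 0 else
        stats::pnorm((log(t) - p$meanlog) / p$sdlog,
                     lower.tail = FALSE, log.p = TRUE)
      q <- stats::qnorm(logS_t - u / factor, lower.tail = FALSE, log.p = TRUE)
      exp(p$meanlog + p$sdlog * q) - t
    },
    custom = function(t, u) .invert_custom(t, u / factor, p$Lambda))
}

# one subject's counting-process records; risk-free gaps become holes
.path_records <- function(id, path, censor_time, duration) {
  times <- path$times
  k <- length(times)
  if (k == 0L)
    return(list(id = id, start = 0, stop = censor_time, status = 0L))
  start <- numeric(0); stop_ <- numeric(0); status <- integer(0)
  prev <- 0
  for (i in seq_len(k)) {
    start <- c(start, prev); stop_ <- c(stop_, times[i])
    status <- c(status, 1L)
    prev <- times[i] + if (path$riskfree[i]) duration else 0
  }
  if (prev < censor_time) {
    start <- c(start, prev); stop_ <- c(stop_, censor_time)
    status <- c(status, 0L)
  }
  list(id = rep(id, length(start)), start = start, stop = stop_,
       status = status)
}

#' Simulate a recurrent-event dataset in counting-process form
#'
#' Draws per-subject covariates, a gamma frailty, a censoring time
#' (administrative or uniform dropout) and the event path by the recursive
#' total-time inversion algorithm, then converts each path into
#' (start, stop, status) at-risk records.  Risk-free intervals appear as
#' holes between consecutive records: the subject is absent from the risk
#' set there.
#'
#' The random-number discipline is one seeded stream per dataset.  Any
#' balanced-binary assignment permutation is drawn first; then subjects
#' consume draws in id order: covariate values, frailty, dropout indicator
#' and time, then event uniforms (with a risk-free Bernoulli draw after
#' each event when \eqn{0 < p}).  Identical \code{(arguments, seed)} give
#' a bit-identical table.
#'
#' @param model baseline \code{\link{hazard_model}}.
#' @param effects an \code{\link{effect_spec}}.
#' @param riskfree a \code{\link{riskfree_spec}}.
#' @param censoring a \code{\link{censoring_spec}}.
#' @param n number of subjects (\eqn{\ge 1}).
#' @param seed optional integer seed; when supplied the caller's RNG state
#'   is left untouched.
#' @param keep_frailty if \code{TRUE}, append the (normally unobservable)
#'   frailty as column \code{z}.
#' @return a \code{data.frame} of class \code{"cp_table"} with columns
#'   \code{id, start, stop, status}, one column per covariate
#'   (\code{x1}, ..., \code{xp}) and optionally \code{z}.
#' @examples
#' hm <- hazard_model("weibull", scale = 4 / sqrt(2), shape = 0.5)
#' d <- simulate_recurrent(hm, censoring = censoring_spec(2), n = 5, seed = 1)
#' head(d)
#' @export
simulate_recurrent <- function(model, effects = effect_spec(),
                               riskfree = riskfree_spec(),
                               censoring, n, seed = NULL,
                               keep_frailty = FALSE) {
  stopifnot(inherits(model, "hazard_model"), inherits(effects, "effect_spec"),
            inherits(riskfree, "riskfree_spec"),
            inherits(censoring, "censoring_spec"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p <- length(effects$beta)
  tau <- censoring$admin_time
  q <- censoring$dropout_prob

  balanced <- matrix(0, n, max(p, 1L))
  for (j in seq_len(p)) {
    if (effects$covariates[[j]]$type == "balanced") {
      perm <- sample.int(n)
      balanced[perm[seq_len(n %/% 2L)], j] <- 1
    }
  }

  recs <- vector("list", n)
  X <- matrix(0, n, p)
  z_all <- numeric(n)
  C_all <- numeric(n)
  for (i in seq_len(n)) {
    x <- numeric(p)
    for (j in seq_len(p)) {
      g <- effects$covariates[[j]]
      x[j] <- switch(g$type,
        bernoulli = stats::rbinom(1, 1, g$prob),
        normal = stats::rnorm(1, g$mean, g$sd),
        balanced = balanced[i, j],
        fixed = g$value)
    }
    z <- draw_frailty(effects$frailty_variance, 1)
    C <- tau
    if (q > 0 && stats::runif(1) < q) C <- stats::runif(1) * tau
    fac <- z * exp(sum(effects$beta * x))
    path <- simulate_subject(model, fac, riskfree, C)
    recs[[i]] <- .path_records(i, path, C, riskfree$duration)
    X[i, ] <- x
    z_all[i] <- z
    C_all[i] <- C
  }
  id <- unlist(lapply(recs, `[[`, "id"))
  tab <- data.frame(
    id = id,
    start = unlist(lapply(recs, `[[`, "start")),
    stop = unlist(lapply(recs, `[[`, "stop")),
    status = unlist(lapply(recs, `[[`, "status"))
  )
  for (j in seq_len(p)) tab[[paste0("x", j)]] <- X[id, j]
  if (keep_frailty) tab$z <- z_all[id]
  class(tab) <- c("cp_table", "data.frame")
  tab
}
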