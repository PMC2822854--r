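# Gaussian mixture on log speed, fitted by expectation-maximisation.
#
# Speeds at sea are bimodal: a slow peak (sitting on the water and drifting
# with the current, ~0.8 m/s) and a fast peak (flight, ~10 m/s with large
# variance). The mixture is fitted in log space — a Gaussian on raw speed
# would put positive probability on negative speeds — and reported on the
# natural scale through the exact log-normal moment map. Fitting on the
# near-complete high-resolution tracks and *transferring* the model to
# sparse duty-cycled tracks avoids the acquisition bias that refitting on
# the sparse data would inherit (fix success can depend on behaviour).

#' Construct a speed mixture model from known parameters
#'
#' Builds the model object directly from log-scale parameters, e.g. to
#' classify with a previously fitted or published model. Components are
#' stored in increasing order of mean log speed; with `K = 2` the first
#' component is the slow (drift) mode and the second the fast (flight)
#' mode.
#'
#' @param weights Mixing proportions, summing to 1.
#' @param mu Component means of log speed (log m s^-1).
#' @param sigma2 Component variances of log speed; all > 0.
#' @param n_obs Sample size behind the fit, if any.
#' @param loglik_trace Per-iteration log-likelihoods, if fitted.
#' @param n_zero_dropped Count of exact-zero speeds dropped before the fit.
#' @return An object of class `"sb_mixture"`.
#' @export
speed_mixture <- function(weights, mu, sigma2, n_obs = NA_integer_,
                          loglik_trace = numeric(), n_zero_dropped = 0L) {
  K <- length(mu)
  stopifnot(length(weights) == K, length(sigma2) == K, K >= 1)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  o <- order(mu)
  structure(
    list(K = K, weights = weights[o], mu = mu[o], sigma2 = sigma2[o],
         n_obs = n_obs, loglik_trace = loglik_trace,
         n_zero_dropped = n_zero_dropped),
    class = "sb_mixture"
  )
}

#' @export
print.sb_mixture <- function(x, ...) {
  cat(sprintf("<sb_mixture> K = %d, n_obs = %s\n", x$K,
              format(x$n_obs)))
  s <- natural_scale_summary(x)
  for (k in seq_len(x$K)) {
    cat(sprintf("  [%d] w = %.3f  log: mu = %.3f, s2 = %.3f  natural: mean = %.3f m/s, var = %.3f\n",
                k, x$weights[k], x$mu[k], x$sigma2[k],
                s$mean[k], s$variance[k]))
  }
  if (length(x$loglik_trace) > 0) {
    cat(sprintf("  EM: %d iterations, loglik %.4f\n",
                length(x$loglik_trace), tail(x$loglik_trace, 1)))
  }
  invisible(x)
}

#' Fit a Gaussian mixture to log speeds by expectation-maximisation
#'
#' Speeds of exactly zero — an artefact of the receiver reporting a null
#' velocity — are dropped (and counted) before the log transform.
#' Initialisation is a deterministic K-quantile split of the sorted log
#' speeds, so the default fit is reproducible without randomness; `seed`
#' only perturbs the optional random restarts. Each EM iteration can only
#' increase the log-likelihood; the trace is recorded and checked.
#'
#' @param speeds Speeds, m s^-1; non-negative (zeros dropped, negatives are
#'   an error). Needs at least `2 * K` positive values.
#' @param K Number of components (default 2: drift + flight).
#' @param seed Integer seed for random restarts; unused when
#'   `n_restarts = 0`.
#' @param tol Relative log-likelihood change at which EM stops.
#' @param max_iter Iteration cap.
#' @param n_restarts Extra EM runs from jittered initialisations; the best
#'   log-likelihood wins. Default 0 (deterministic quantile start).
#' @return An [speed_mixture()] object with components sorted by mean.
#' @export
fit_mixture_em <- function(speeds, K = 2, seed = NULL, tol = 1e-8,
                           max_iter = 500, n_restarts = 0) {
  if (K < 1) stop("K must be >= 1")
  speeds <- speeds[!is.na(speeds)]
  if (any(speeds < 0)) stop("negative speeds are not valid")
  n_zero <- sum(speeds == 0)
  speeds <- speeds[speeds > 0]
  n <- length(speeds)
  if (n < 2 * K) {
    stop("need at least ", 2 * K, " positive speeds to fit K = ", K,
         " components (have ", n, ")")
  }
  x <- log(speeds)
  if (var(x) == 0) stop("all speeds equal: mixture variance is degenerate")
  init <- .quantile_split_init(x, K)
  best <- .em_gaussian(x, init$w, init$mu, init$s2, tol, max_iter)
  if (n_restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(n_restarts)) {
      mu_j <- init$mu + rnorm(K, 0, sd(x) / 2)
      fit <- .em_gaussian(x, init$w, mu_j, init$s2, tol, max_iter)
      if (tail(fit$loglik, 1) > tail(best$loglik, 1)) best <- fit
    }
  }
  speed_mixture(best$w, best$mu, best$s2, n_obs = n,
                loglik_trace = best$loglik, n_zero_dropped = n_zero)
}

.quantile_split_init <- function(x, K) {
  o <- sort(x)
  grp <- if (K == 1) rep(1L, length(o)) else cut(seq_along(o), K,
                                                 labels = FALSE)
  mu <- tapply(o, grp, mean)
  s2 <- tapply(o, grp, function(g) if (length(g) > 1) var(g) else NA_real_)
  floor_s2 <- max(var(x) * 1e-4, 1e-10)
  s2[is.na(s2) | s2 < floor_s2] <- floor_s2
  list(w = as.numeric(table(grp)) / length(x), mu = as.numeric(mu),
       s2 = as.numeric(s2))
}

.em_gaussian <- function(x, w, mu, s2, tol, max_iter) {
  n <- length(x)
  K <- length(mu)
  loglik <- numeric(0)
  ll_prev <- -Inf
  s2_floor <- max(var(x) * 1e-8, 1e-12)
  for (iter in seq_len(max_iter)) {
    # E step in log space for numerical safety
    logd <- vapply(seq_len(K), function(k) {
      log(w[k]) + dnorm(x, mu[k], sqrt(s2[k]), log = TRUE)
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    r <- exp(logd - lse)
    # M step
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    s2 <- vapply(seq_len(K), function(k) {
      sum(r[, k] * (x - mu[k])^2) / nk[k]
    }, numeric(1))
    s2 <- pmax(s2, s2_floor)
    if (is.finite(ll_prev) &&
        (ll - ll_prev) <= tol * abs(ll_prev)) break
    ll_prev <- ll
  }
  list(w = w, mu = mu, s2 = s2, loglik = loglik)
}

#' Classify speeds into behavioural modes
#'
#' Assigns each speed to the mixture component from which it was most
#' likely generated: posterior_k proportional to
#' `weight_k * Normal(log speed; mu_k, sigma2_k)`, label = argmax. An exact
#' posterior tie goes to the slower component, because misclassifying rest
#' as flight inflates apparent foraging range. With `K = 2` labels are
#' `"SLOW"` and `"FAST"`; for general K, `"C1" .. "CK"` in increasing
#' order of mean.
#'
#' @param model An [speed_mixture()].
#' @param speed Speeds, m s^-1; strictly positive (log undefined at 0).
#' @return Data frame with `speed`, `label`, and one posterior column per
#'   component (`p_slow`/`p_fast` for K = 2, else `p_C1` ...).
#' @export
classify <- function(model, speed) {
  stopifnot(inherits(model, "sb_mixture"))
  if (any(is.na(speed)) || any(speed <= 0)) {
    stop("speeds must be positive to classify (log undefined at 0)")
  }
  x <- log(speed)
  K <- model$K
  logd <- vapply(seq_len(K), function(k) {
    log(model$weights[k]) +
      dnorm(x, model$mu[k], sqrt(model$sigma2[k]), log = TRUE)
  }, numeric(length(x)))
  logd <- matrix(logd, ncol = K)
  m <- apply(logd, 1, max)
  post <- exp(logd - m)
  post <- post / rowSums(post)
  labels <- .component_labels(K)
  # which.max returns the first maximum: components are mean-ordered, so
  # exact ties resolve to the slower mode
  lab <- labels[apply(post, 1, which.max)]
  out <- data.frame(speed = speed, label = lab, stringsAsFactors = FALSE)
  colnames(post) <- paste0("p_", tolower(labels))
  cbind(out, as.data.frame(post))
}

.component_labels <- function(K) {
  if (K == 2) c("SLOW", "FAST") else paste0("C", seq_len(K))
}

#' Classify duty-cycled burst clusters
#'
#' Applies [classify()] to each cluster's representative speed, labelling
#' every two-hour burst as sitting (slow peak) or flying (fast peak).
#' Flagged clusters (fewer than 2 fixes, no defined speed) receive no
#' label and are excluded from any downstream proportions.
#'
#' @param model An [speed_mixture()].
#' @param clusters Data frame from [segment_clusters()].
#' @return `clusters` with `label` and posterior columns appended (`NA`
#'   rows for flagged clusters).
#' @export
classify_cluster <- function(model, clusters) {
  stopifnot(is.data.frame(clusters), "speed" %in% names(clusters))
  ok <- !is.na(clusters$speed) & clusters$speed > 0
  labels <- .component_labels(model$K)
  pcols <- paste0("p_", tolower(labels))
  out <- clusters
  out$label <- NA_character_
  for (pc in pcols) out[[pc]] <- NA_real_
  if (any(ok)) {
    cl <- classify(model, clusters$speed[ok])
    out$label[ok] <- cl$label
    for (pc in pcols) out[[pc]][ok] <- cl[[pc]]
  }
  out
}

#' Share of classified locations per behavioural mode
#'
#' @param labels Character vector of mode labels (`NA`s, e.g. flagged
#'   clusters, are excluded).
#' @param model Optional [speed_mixture()] fixing the component order.
#' @return Named numeric vector of proportions summing to 1.
#' @export
classification_proportions <- function(labels, model = NULL) {
  labels <- labels[!is.na(labels)]
  lev <- if (!is.null(model)) .component_labels(model$K) else sort(unique(labels))
  tab <- table(factor(labels, levels = lev))
  setNames(as.numeric(tab) / sum(tab), lev)
}

#' Natural-scale moments of the fitted modes
#'
#' Maps each component's log-scale parameters to the implied log-normal
#' moments on the m s^-1 scale: mean `exp(mu + sigma2/2)`, variance
#' `(exp(sigma2) - 1) * exp(2*mu + sigma2)`.
#'
#' @param model An [speed_mixture()].
#' @return Data frame with one row per component: `component`, `weight`,
#'   `mean` (m s^-1), `variance` ((m s^-1)^2).
#' @export
natural_scale_summary <- function(model) {
  stopifnot(inherits(model, "sb_mixture"))
  data.frame(
    component = .component_labels(model$K),
    weight = model$weights,
    mean = exp(model$mu + model$sigma2 / 2),
    variance = (exp(model$sigma2) - 1) * exp(2 * model$mu + model$sigma2),
    stringsAsFactors = FALSE
  )
}

#' Log-normal parameters from natural-scale moments
#'
#' Inverse of the moment map in [natural_scale_summary()]: given a
#' natural-scale mean and variance, returns the log-scale `mu` and
#' `sigma2` of the log-normal with those moments.
#'
#' @param mean Natural-scale mean, > 0.
#' @param variance Natural-scale variance, >= 0.
#' @return List with `mu` and `sigma2` (vectorised).
#' @export
lognormal_params <- function(mean, variance) {
  stopifnot(all(mean > 0), all(variance >= 0))
  sigma2 <- log(1 + variance / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma2 = sigma2)
}

#' Mixture probability density
#'
#' On the natural scale the fitted model is a mixture of log-normals; on
#' the log scale a mixture of Gaussians. Either density integrates to 1
#' over its support.
#'
#' @param model An [speed_mixture()].
#' @param x Evaluation points (speeds in m s^-1 for `"natural"`, log
#'   speeds for `"log"`).
#' @param scale `"natural"` or `"log"`.
#' @return Density values.
#' @export
mixture_density <- function(model, x, scale = c("natural", "log")) {
  stopifnot(inherits(model, "sb_mixture"))
  scale <- match.arg(scale)
  dens <- 0
  for (k in seq_len(model$K)) {
    dens <- dens + model$weights[k] * switch(scale,
      natural = dlnorm(x, model$mu[k], sqrt(model$sigma2[k])),
      log = dnorm(x, model$mu[k], sqrt(model$sigma2[k]))
    )
  }
  dens
}
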