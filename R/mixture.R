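#' Bundle fluorescence events with their sample metadata
#'
#' A fluorescence sample is the per-sample unit of the pipeline: the exported
#' single-parameter fluorescence-area values (one number per gated event) of
#' a pooled male sample co-stained with diploid females of the same clone,
#' plus the metadata needed downstream — which clone, which developmental
#' stage the males came from, how many individuals went into the tube, and
#' where the female internal-standard peak sits.
#'
#' @param events Numeric vector of fluorescence area values, all positive.
#' @param clone_id Clone label.
#' @param stage One of `"sync"`, `"accum"`, `"hatched"` (synchronized male
#'   eggs, accumulated eggs, hatched males) or another label.
#' @param female_peak Fluorescence position of the diploid female peak
#'   (internal standard); may be `NA` if it is to be located later.
#' @param n_individuals Number of males pooled into the sample (used to
#'   reconstruct class counts).
#' @return An object of class `fluorescence_sample`.
#' @export
fluorescence_sample <- function(events, clone_id = NA_character_,
                                stage = NA_character_,
                                female_peak = NA_real_,
                                n_individuals = NA_integer_) {
  events <- as.numeric(events)
  if (any(!is.finite(events)) || any(events <= 0)) {
    abort("`events` must be finite and strictly positive.")
  }
  structure(
    list(events = events, clone_id = clone_id, stage = stage,
         female_peak = female_peak, n_individuals = n_individuals),
    class = "fluorescence_sample"
  )
}

#' @export
print.fluorescence_sample <- function(x, ...) {
  cat(sprintf("<fluorescence_sample> %s / %s: %d events\n",
              x$clone_id, x$stage, length(x$events)))
  cat(sprintf("  female peak: %s | individuals: %s\n",
              format(x$female_peak), format(x$n_individuals)))
  invisible(x)
}

sample_events <- function(x) {
  if (inherits(x, "fluorescence_sample")) x$events else as.numeric(x)
}

# log density of the skew-normal: 2/omega phi(z) Phi(alpha z), z = (x-xi)/omega
dsn_log <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  log(2) - log(omega) + dnorm(z, log = TRUE) + pnorm(alpha * z, log.p = TRUE)
}

# inverse Mills ratio phi(u)/Phi(u), stable far into the left tail
zeta1 <- function(u) exp(dnorm(u, log = TRUE) - pnorm(u, log.p = TRUE))

# deterministic quantile-based initialisation: split the sorted events into g
# equal-count blocks; skewness sign of each block seeds the shape parameter
init_components <- function(x, g, family, jitter_sd = 0, rng = NULL) {
  qs <- quantile(x, probs = seq(0, 1, length.out = g + 1), names = FALSE)
  block <- cut(x, breaks = unique(c(-Inf, qs[-c(1, g + 1)], Inf)), labels = FALSE)
  if (length(unique(block)) < g) {
    # heavy ties: fall back to evenly spaced centres over the data range
    centres <- seq(min(x), max(x), length.out = g + 2)[2:(g + 1)]
    block <- apply(abs(outer(x, centres, "-")), 1, which.min)
  }
  xi <- vapply(1:g, function(j) mean(x[block == j]), numeric(1))
  omega <- vapply(1:g, function(j) {
    s <- sd(x[block == j])
    if (!is.finite(s) || s <= 0) sd(x) / g else s
  }, numeric(1))
  alpha <- if (family == "normal") rep(0, g) else vapply(1:g, function(j) {
    xs <- x[block == j]
    m3 <- mean((xs - mean(xs))^3)
    if (is.finite(m3) && m3 < 0) -1 else 1
  }, numeric(1))
  if (jitter_sd > 0) xi <- xi + rng(g) * jitter_sd
  list(w = rep(1 / g, g), xi = xi, omega = omega, alpha = alpha)
}

# one EM run at fixed g; x is standardised by the caller. The iteration
# itself lives in compiled code (src/em_smsn.cpp); NULL signals degeneracy
# (scale collapse or an emptied component) so the caller can restart.
em_smsn <- function(x, g, family, tol, max_iter, init) {
  fit <- em_smsn_cpp(x, as.integer(g), family != "normal", tol,
                     as.integer(max_iter),
                     init$w, init$xi, init$omega, init$alpha)
  if (isTRUE(fit$failed)) return(NULL)
  npar <- (g - 1) + g * (if (family == "normal") 2 else 3)
  c(fit[c("w", "xi", "omega", "alpha", "loglik", "converged", "iter")],
    list(bic = -2 * fit$loglik + npar * log(length(x)), npar = npar))
}

#' Finite-mixture decomposition of a fluorescence histogram
#'
#' Fits finite mixtures of skew-normal (or normal) components to the
#' one-dimensional fluorescence events by expectation-maximisation, for every
#' component count `g` in `[g_min, g_max]`, and keeps the fit with the lowest
#' Bayesian information criterion. This mirrors the `smsn.search`-style
#' procedure used for genome-size class quantification: `g_max` may
#' deliberately exceed the number of genome-size classes, because extra
#' components absorb background fluorescence and instrument asymmetry and are
#' merged or discarded later by [assign_components_to_classes()].
#'
#' Initialisation is a deterministic quantile split of the sorted events, so
#' repeated runs give identical fits; if a component degenerates (scale
#' collapse or emptied weight) the run is restarted a bounded number of times
#' from a seeded, jittered initialisation.
#'
#' @param sample A [fluorescence_sample()] or bare numeric event vector with
#'   at least 200 events.
#' @param g_min,g_max Range of component counts to try (defaults 3 and 8).
#' @param family `"skew_normal"` (default) or `"normal"`.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-5).
#' @param max_iter Maximum EM iterations per `g` (default 1000).
#' @param seed Seed for the (rarely needed) degeneracy restarts.
#' @param max_restarts Restarts allowed per `g` on degeneracy.
#' @return An object of class `ise_mixture`: `components` tibble
#'   (`component`, `weight`, `xi`, `omega`, `alpha`, `mean`), `g`, `family`,
#'   `loglik`, `bic`, `converged`, `n_events`, `events`, and `all_bic` (the
#'   BIC per candidate `g`). `mean` is the component mean
#'   `xi + omega * delta * sqrt(2/pi)`, the quantity compared against
#'   expected class positions.
#' @export
fit_finite_mixture <- function(sample, g_min = 3, g_max = 8,
                               family = c("skew_normal", "normal"),
                               tol = 1e-5, max_iter = 1000, seed = 1,
                               max_restarts = 3) {
  family <- match.arg(family)
  x <- sample_events(sample)
  if (length(x) < 200) {
    abort(sprintf("Need >= 200 events to fit a mixture (got %d).", length(x)))
  }
  stopifnot(g_min >= 1, g_min <= g_max)

  # standardise for numerical stability; map parameters back afterwards
  mu0 <- mean(x); s0 <- sd(x)
  if (s0 <= 0) abort("Events are constant; nothing to decompose.")
  xs <- (x - mu0) / s0

  fits <- vector("list", g_max - g_min + 1)
  diagnostics <- character(0)
  for (g in g_min:g_max) {
    fit <- em_smsn(xs, g, family, tol, max_iter, init_components(xs, g, family))
    restart <- 0
    while (is.null(fit) && restart < max_restarts) {
      restart <- restart + 1
      rng <- function(k) withr_seed(seed + 1000 * g + restart, rnorm(k))
      fit <- em_smsn(xs, g, family, tol, max_iter,
                     init_components(xs, g, family, jitter_sd = 0.2, rng = rng))
    }
    if (is.null(fit)) {
      diagnostics <- c(diagnostics, sprintf("g = %d: degenerate after %d restarts",
                                            g, max_restarts))
    }
    fits[[g - g_min + 1]] <- fit
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort(paste0("Mixture fitting failed for every g in [", g_min, ", ", g_max,
                 "]: ", paste(diagnostics, collapse = "; ")))
  }
  bics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, numeric(1))
  best <- fits[[which.min(bics)]]

  # report likelihood and BIC on the original data scale
  ll <- best$loglik - length(x) * log(s0)
  bic_raw <- -2 * ll + best$npar * log(length(x))
  all_bic <- bics + 2 * length(x) * log(s0)

  delta <- best$alpha / sqrt(1 + best$alpha^2)
  comp <- tibble(
    component = seq_along(best$w),
    weight = best$w,
    xi = best$xi * s0 + mu0,
    omega = best$omega * s0,
    alpha = best$alpha,
    mean = (best$xi + best$omega * delta * sqrt(2 / pi)) * s0 + mu0
  ) %>% arrange(mean) %>% mutate(component = row_number())

  structure(
    list(components = comp, g = length(best$w), family = family,
         loglik = ll, bic = bic_raw, converged = best$converged,
         n_events = length(x), events = x,
         all_bic = setNames(all_bic, g_min:g_max)),
    class = "ise_mixture"
  )
}

#' @export
print.ise_mixture <- function(x, ...) {
  cat(sprintf("<ise_mixture> %s, g = %d (BIC-selected), %d events, %s\n",
              x$family, x$g, x$n_events,
              if (x$converged) "converged" else "iteration limit reached"))
  print(x$components, ...)
  invisible(x)
}

#' @rdname fit_finite_mixture
#' @param x,object An `ise_mixture`.
#' @param ... Unused.
#' @export
tidy.ise_mixture <- function(x, ...) x$components

#' @rdname fit_finite_mixture
#' @export
glance.ise_mixture <- function(x, ...) {
  tibble(g = x$g, family = x$family, loglik = x$loglik, bic = x$bic,
         converged = x$converged, n_events = x$n_events)
}

# mixture density on the original scale
mixture_density <- function(fit, at) {
  rowSums(vapply(seq_len(nrow(fit$components)), function(j) {
    with(fit$components[j, ],
         weight * exp(dsn_log(at, xi, omega, alpha)))
  }, numeric(length(at))))
}

#' @rdname fit_finite_mixture
#' @param bins Number of histogram bins in the plot.
#' @export
autoplot.ise_mixture <- function(object, bins = 120, ...) {
  at <- seq(min(object$events), max(object$events), length.out = 512)
  dens <- tibble(events = at, density = mixture_density(object, at))
  ggplot2::ggplot(tibble(events = object$events), ggplot2::aes(events)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = NA) +
    ggplot2::geom_line(data = dens, ggplot2::aes(events, density),
                       colour = "red") +
    ggplot2::labs(x = "fluorescence (area)", y = "density")
}

#' Locate the female internal-standard peak
#'
#' Estimates the fluorescence position of the diploid female peak as the
#' rightmost substantial mode of the event density. Haploid males of the same
#' clone span roughly 30-70% of the female signal, so the female peak is the
#' highest-fluorescence mode that still carries appreciable density.
#'
#' @param sample A [fluorescence_sample()] or numeric event vector.
#' @param min_height Minimum mode height as a fraction of the tallest mode
#'   (default 0.1).
#' @return Estimated peak position (scalar).
#' @export
estimate_female_peak <- function(sample, min_height = 0.1) {
  x <- sample_events(sample)
  d <- stats::density(x, n = 1024)
  is_peak <- c(FALSE, diff(sign(diff(d$y))) < 0, FALSE)
  keep <- is_peak & d$y >= min_height * max(d$y)
  if (!any(keep)) abort("No substantial density mode found.")
  max(d$x[keep])
}

#' Coefficient of variation of a fluorescence peak
#'
#' Quality control of a sample via the spread of a reference peak (typically
#' the diploid female internal standard): events within `window` of the peak
#' position are taken as the peak, and the CV is `100 * sd / mean` of those
#' events. Samples whose female-peak CV exceeds the cutoff are flagged for
#' exclusion (cutoff 3.5% by default; instrument-quality runs show CVs of
#' roughly 1.7-4%).
#'
#' @param sample A [fluorescence_sample()] or numeric event vector.
#' @param peak Fluorescence position of the peak to assess; defaults to the
#'   sample's recorded female peak.
#' @param window Half-width of the peak window as a fraction of `peak`
#'   (default 0.12).
#' @param cutoff Exclusion threshold in percent (default 3.5).
#' @return A tibble with `peak`, `n_peak_events`, `cv_percent`, `excluded`.
#' @export
qc_cv <- function(sample, peak = NULL, window = 0.12, cutoff = 3.5) {
  x <- sample_events(sample)
  if (is.null(peak)) {
    if (!inherits(sample, "fluorescence_sample") || !is.finite(sample$female_peak)) {
      abort("Give `peak` or a sample with a recorded female peak.")
    }
    peak <- sample$female_peak
  }
  inside <- x[x >= peak * (1 - window) & x <= peak * (1 + window)]
  if (length(inside) < 100) {
    abort(sprintf("Only %d events within the peak window; need >= 100.",
                  length(inside)))
  }
  cv <- 100 * sd(inside) / mean(inside)
  tibble(peak = peak, n_peak_events = length(inside),
         cv_percent = cv, excluded = cv > cutoff)
}
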