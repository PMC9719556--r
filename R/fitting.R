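#' Root-mean-square error between two class-frequency distributions
#'
#' The least-squares objective of the grid search:
#' `sqrt(mean((predicted - observed)^2))` over genome-size classes.
#'
#' @param predicted,observed Class distributions over the same classes
#'   (tibbles with `class_k`/`frequency`, or bare frequency vectors).
#' @return A single non-negative value.
#' @examples
#' class_rmse(unbiased_distribution(2), class_distribution(2, cb = -0.3))
#' @export
class_rmse <- function(predicted, observed) {
  p <- class_freq_vector(predicted, check_normalised = FALSE)
  o <- class_freq_vector(observed, check_normalised = FALSE)
  if (length(p) != length(o)) abort("Class counts differ between inputs.")
  sqrt(mean((p - o)^2))
}

#' Grid-search least-squares fit of the segregation parameters
#'
#' Evaluates the exact segregation model over every combination of
#' transmission bias and cosegregation bias on a regular grid spanning
#' -0.95 to 0.95 in both parameters, and returns the combination whose
#' predicted class frequencies have the lowest root-mean-square error against
#' the observed frequencies, together with the full error surface. Ties are
#' broken towards the most parsimonious deviation from unbiased segregation
#' (smallest `|tb| + |cb|`, then lexicographically by `(tb, cb)`).
#'
#' With a single ISE the model does not involve pair interactions, so the
#' cosegregation bias is not identifiable: the fit is performed over `tb`
#' only and `cb` is reported as `NA`.
#'
#' @param observed Observed class-frequency distribution (normalised):
#'   an `ise_class_distribution`, a data frame with `class_k`/`frequency`,
#'   or a bare frequency vector for classes `0..n`.
#' @param grid_step Grid spacing for both parameters (default 0.05, a
#'   39 x 39 grid).
#' @return An object of class `ise_fit`: list with `best_tb`, `best_cb`,
#'   `best_rmse`, `surface` (tibble `tb`, `cb`, `rmse`), `grid_step`,
#'   `n_ise`, `observed`. Use [tidy()][generics::tidy] for the surface,
#'   [glance()][generics::glance] for a one-row summary, and
#'   [ggplot2::autoplot()] for the surface heat map.
#' @examples
#' fit <- grid_fit(class_distribution(3, tb = 0.15, cb = -0.35))
#' glance(fit)
#' @export
grid_fit <- function(observed, grid_step = 0.05) {
  obs <- class_freq_vector(observed)
  n_ise <- length(obs) - 1L
  if (n_ise < 1) abort("Need at least two classes (n_ise >= 1) to fit.")
  stopifnot(grid_step > 0, grid_step <= 1.9)

  grid_vals <- round(seq(-0.95, 0.95, by = grid_step), 10)
  if (length(grid_vals) == 0) abort("Empty parameter grid.")
  cb_vals <- if (n_ise == 1) 0 else grid_vals

  surface <- tidyr::expand_grid(tb = grid_vals, cb = cb_vals)
  surface$rmse <- purrr::map2_dbl(surface$tb, surface$cb, function(tb, cb) {
    w <- class_weights(n_ise, list(tb = tb, cb = cb))
    sqrt(mean((w / sum(w) - obs)^2))
  })

  # lowest rmse; ties -> smallest |tb|+|cb|, then lexicographic (tb, cb)
  ord <- order(surface$rmse, abs(surface$tb) + abs(surface$cb),
               surface$tb, surface$cb)
  best <- surface[ord[1], ]

  structure(
    list(
      best_tb = best$tb,
      best_cb = if (n_ise == 1) NA_real_ else best$cb,
      best_rmse = best$rmse,
      surface = if (n_ise == 1) dplyr::select(surface, tb, rmse) else surface,
      grid_step = grid_step,
      n_ise = n_ise,
      observed = obs
    ),
    class = "ise_fit"
  )
}

#' @export
print.ise_fit <- function(x, ...) {
  cat(sprintf("<ise_fit> n_ise = %d, grid step = %g\n", x$n_ise, x$grid_step))
  cat(sprintf("  transmission bias: %s\n", format(x$best_tb)))
  cat(sprintf("  cosegregation bias: %s%s\n", format(x$best_cb),
              if (is.na(x$best_cb)) " (not identifiable with one ISE)" else ""))
  cat(sprintf("  RMSE: %.6g over %d grid points\n", x$best_rmse, nrow(x$surface)))
  invisible(x)
}

#' @rdname grid_fit
#' @param x,object An `ise_fit`.
#' @param ... Unused.
#' @export
tidy.ise_fit <- function(x, ...) as_tibble(x$surface)

#' @rdname grid_fit
#' @export
glance.ise_fit <- function(x, ...) {
  tibble(n_ise = x$n_ise, best_tb = x$best_tb, best_cb = x$best_cb,
         best_rmse = x$best_rmse, grid_step = x$grid_step,
         n_grid = nrow(x$surface))
}

#' @rdname grid_fit
#' @export
autoplot.ise_fit <- function(object, ...) {
  if (object$n_ise == 1) {
    return(
      ggplot2::ggplot(object$surface, ggplot2::aes(tb, rmse)) +
        ggplot2::geom_line() +
        ggplot2::geom_point(data = tibble(tb = object$best_tb,
                                          rmse = object$best_rmse),
                            colour = "red") +
        ggplot2::labs(x = "transmission bias", y = "RMSE")
    )
  }
  ggplot2::ggplot(object$surface, ggplot2::aes(tb, cb, fill = rmse)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tibble(tb = object$best_tb, cb = object$best_cb),
                        ggplot2::aes(tb, cb), inherit.aes = FALSE,
                        colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "transmission bias", y = "cosegregation bias",
                  fill = "RMSE")
}

#' Fit segregation parameters for many clones at once
#'
#' Runs [grid_fit()] per clone on a long table of observed class frequencies,
#' as used to compare inbred and outbred clones on the (tb, cb) plane.
#'
#' @param observations A data frame with columns `clone_id`, `class_k`,
#'   `frequency` — one normalised class distribution per clone.
#' @param grid_step Passed to [grid_fit()].
#' @return A tibble with one row per clone: `clone_id`, `n_ise`, `best_tb`,
#'   `best_cb`, `best_rmse`.
#' @export
fit_many <- function(observations, grid_step = 0.05) {
  stopifnot(is.data.frame(observations),
            all(c("clone_id", "class_k", "frequency") %in% names(observations)))
  ids <- unique(observations$clone_id)
  per_clone <- split(observations, observations$clone_id)
  if (anyDuplicated(vapply(per_clone, function(d) d$clone_id[1], character(1))) > 0) {
    abort("Duplicate clone ids.")  # unreachable via split; guards future edits
  }
  purrr::map_dfr(ids, function(id) {
    d <- per_clone[[as.character(id)]]
    if (anyDuplicated(d$class_k) > 0) {
      abort(sprintf("Clone %s has duplicated class rows.", id))
    }
    fit <- grid_fit(d[, c("class_k", "frequency")], grid_step = grid_step)
    tibble(clone_id = id, n_ise = fit$n_ise, best_tb = fit$best_tb,
           best_cb = fit$best_cb, best_rmse = fit$best_rmse)
  })
}
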