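#' Map fitted mixture components onto genome-size classes
#'
#' The BIC-selected mixture usually has more components than there are male
#' genome-size classes: the surplus absorbs background debris and instrument
#' asymmetry. Each component is therefore assigned to the nearest expected
#' class position (from [expected_peak_positions()]) if its mean lies within
#' `window` of it; components mapping to the same class are merged (weights
#' summed, position the weight-weighted mean of the component means), and
#' components matching no class are labelled background. A low-weight, very
#' broad component (weight below `min_weight` with scale above three times
#' the median in-class scale) is also treated as background even when its
#' mean happens to fall inside a class window.
#'
#' @param fit An `ise_mixture` from [fit_finite_mixture()].
#' @param expected_positions Strictly increasing vector of expected
#'   fluorescence positions for classes `0..n`.
#' @param window Matching half-width as a fraction of the expected position
#'   (default 0.05). Two expected positions closer than twice the window are
#'   unresolvable and raise an error (the continuous-distribution case of
#'   high-ISE clones).
#' @param min_weight Weight below which a broad component is considered
#'   background (default 0.02).
#' @return A tibble with one row per genome-size class and one per background
#'   component pool: `class_k` (`NA` for background), `proportion`,
#'   `mean_fluorescence`, `member_components` (list column), `is_background`.
#'   Classes with no matching component appear with proportion 0.
#' @export
assign_components_to_classes <- function(fit, expected_positions,
                                         window = 0.05, min_weight = 0.02) {
  stopifnot(inherits(fit, "ise_mixture"))
  pos <- as.numeric(expected_positions)
  if (length(pos) < 1 || any(diff(pos) <= 0)) {
    abort("`expected_positions` must be strictly increasing.")
  }
  gaps <- diff(pos) / pos[-length(pos)]
  if (length(gaps) && any(gaps < 2 * window)) {
    abort(paste("Adjacent expected class positions are closer than twice the",
                "matching window: classes are not resolvable for this clone;",
                "use density summaries instead."))
  }

  comp <- fit$components
  nearest <- apply(abs(outer(comp$mean, pos, "-")), 1, which.min)
  rel_dist <- abs(comp$mean - pos[nearest]) / pos[nearest]
  assigned <- ifelse(rel_dist <= window, nearest - 1L, NA_integer_)

  # broad trace components are debris even when inside a window
  in_class_scales <- comp$omega[!is.na(assigned)]
  if (length(in_class_scales)) {
    broad <- comp$weight < min_weight & comp$omega > 3 * median(in_class_scales)
    assigned[broad] <- NA_integer_
  }

  classes <- purrr::map_dfr(seq_along(pos) - 1L, function(k) {
    members <- which(!is.na(assigned) & assigned == k)
    if (length(members) == 0) {
      return(tibble(class_k = k, proportion = 0,
                    mean_fluorescence = NA_real_,
                    member_components = list(integer(0)),
                    is_background = FALSE))
    }
    w <- comp$weight[members]
    tibble(class_k = k, proportion = sum(w),
           mean_fluorescence = sum(w * comp$mean[members]) / sum(w),
           member_components = list(comp$component[members]),
           is_background = FALSE)
  })

  bg <- which(is.na(assigned))
  if (length(bg)) {
    w <- comp$weight[bg]
    classes <- bind_rows(classes, tibble(
      class_k = NA_integer_, proportion = sum(w),
      mean_fluorescence = sum(w * comp$mean[bg]) / sum(w),
      member_components = list(comp$component[bg]),
      is_background = TRUE))
  }
  classes
}

#' Renormalise class proportions after background exclusion
#'
#' Drops background rows and rescales the remaining genome-size class
#' proportions so they sum to one, the convention used before comparing
#' observed class frequencies with model predictions.
#'
#' @param estimates Output of [assign_components_to_classes()].
#' @return The same tibble without background rows and with `proportion`
#'   summing to 1.
#' @export
renormalize_classes <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("class_k", "proportion", "is_background") %in% names(estimates)))
  kept <- dplyr::filter(estimates, !is_background)
  tot <- sum(kept$proportion)
  if (nrow(kept) == 0 || tot <= 0) {
    abort("All components were classified as background; nothing to renormalise.")
  }
  mutate(kept, proportion = proportion / tot)
}

#' One-call decomposition of a sample into class frequencies
#'
#' Convenience wrapper chaining [fit_finite_mixture()],
#' [assign_components_to_classes()] and [renormalize_classes()] for a sample
#' of a clone with a known karyotype. The expected class positions come from
#' the clone's male genome sizes scaled to the female internal-standard peak
#' recorded in the sample.
#'
#' @param sample A [fluorescence_sample()] with a finite `female_peak`.
#' @param karyotype The clone's [ise_karyotype()].
#' @param window,min_weight Passed to [assign_components_to_classes()].
#' @param ... Passed to [fit_finite_mixture()].
#' @return A list with `classes` (renormalised class tibble, all classes
#'   0..n_ise present), `assignment` (pre-normalisation table including
#'   background) and `fit` (the `ise_mixture`).
#' @export
decompose_sample <- function(sample, karyotype, window = 0.05,
                             min_weight = 0.02, ...) {
  stopifnot(inherits(sample, "fluorescence_sample"))
  if (!is.finite(sample$female_peak)) {
    abort("Sample must record the female internal-standard peak position.")
  }
  fit <- fit_finite_mixture(sample, ...)
  pos <- expected_peak_positions(karyotype, sample$female_peak)
  assignment <- assign_components_to_classes(fit, pos, window = window,
                                             min_weight = min_weight)
  list(classes = renormalize_classes(assignment),
       assignment = assignment, fit = fit)
}
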