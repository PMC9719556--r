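#' Describe a clone's ISE complement and genome sizes
#'
#' An ISE karyotype records how many independently segregating elements (ISEs)
#' a clone carries, their sizes, and the clone's genome sizes. ISEs are
#' unpaired in the diploid female, so the female 2C value is
#' `2 * core_1c_mb + sum(ise_sizes_mb)`: haploid males inherit one copy of the
#' core genome plus any subset of the mother's ISEs.
#'
#' At least two of `core_1c_mb`, `female_2c_mb` and `ise_sizes_mb` must be
#' given (with `n_ise`); the missing piece is filled in from the identity
#' above. When individual ISE sizes are unknown they are assumed equal,
#' `(female_2c_mb - 2 * core_1c_mb) / n_ise`.
#'
#' @param n_ise Number of ISEs carried by the (diploid) mother clone.
#' @param core_1c_mb Haploid core genome size in Mb (no ISEs).
#' @param female_2c_mb Diploid female genome size in Mb (internal standard in
#'   flow cytometry).
#' @param ise_sizes_mb Optional numeric vector of per-ISE sizes in Mb, length
#'   `n_ise`.
#' @param clone_id Optional clone label.
#'
#' @return An object of class `ise_karyotype`: a list with fields `n_ise`,
#'   `ise_sizes_mb`, `core_1c_mb`, `female_2c_mb`, `clone_id`.
#' @examples
#' # a clone like ohj67: four ISEs, female 2C of 506 Mb
#' ise_karyotype(n_ise = 4, core_1c_mb = 200, female_2c_mb = 506)
#' @export
ise_karyotype <- function(n_ise, core_1c_mb = NULL, female_2c_mb = NULL,
                          ise_sizes_mb = NULL, clone_id = NULL) {
  stopifnot(length(n_ise) == 1, n_ise >= 0, n_ise == as.integer(n_ise))
  n_ise <- as.integer(n_ise)

  if (!is.null(ise_sizes_mb)) {
    if (length(ise_sizes_mb) != n_ise) {
      abort("`ise_sizes_mb` must have length `n_ise`.")
    }
    if (n_ise > 0 && any(ise_sizes_mb <= 0)) {
      abort("All ISE sizes must be positive.")
    }
  }

  have <- c(core = !is.null(core_1c_mb), female = !is.null(female_2c_mb),
            sizes = !is.null(ise_sizes_mb))
  if (sum(have) < 2) {
    abort(paste("Give at least two of `core_1c_mb`, `female_2c_mb`,",
                "`ise_sizes_mb` so the third can be derived."))
  }

  if (is.null(ise_sizes_mb)) {
    extra <- female_2c_mb - 2 * core_1c_mb
    if (n_ise > 0) {
      if (extra <= 0) abort("`female_2c_mb` must exceed 2 * `core_1c_mb` when n_ise > 0.")
      ise_sizes_mb <- rep(extra / n_ise, n_ise)
    } else {
      if (abs(extra) > 1e-6 * female_2c_mb) {
        abort("With n_ise = 0, `female_2c_mb` must equal 2 * `core_1c_mb`.")
      }
      ise_sizes_mb <- numeric(0)
    }
  } else if (is.null(core_1c_mb)) {
    core_1c_mb <- (female_2c_mb - sum(ise_sizes_mb)) / 2
    if (core_1c_mb <= 0) abort("Derived `core_1c_mb` is not positive; check sizes.")
  } else if (is.null(female_2c_mb)) {
    female_2c_mb <- 2 * core_1c_mb + sum(ise_sizes_mb)
  } else {
    # all three supplied: enforce the accounting identity
    implied <- 2 * core_1c_mb + sum(ise_sizes_mb)
    if (abs(implied - female_2c_mb) > 1e-6 * female_2c_mb) {
      abort(sprintf(
        "female_2c_mb (%.6g) != 2*core_1c_mb + sum(ise_sizes_mb) (%.6g).",
        female_2c_mb, implied))
    }
  }
  if (core_1c_mb <= 0) abort("`core_1c_mb` must be positive.")

  structure(
    list(n_ise = n_ise, ise_sizes_mb = as.numeric(ise_sizes_mb),
         core_1c_mb = as.numeric(core_1c_mb),
         female_2c_mb = as.numeric(female_2c_mb),
         clone_id = clone_id),
    class = "ise_karyotype"
  )
}

#' @export
print.ise_karyotype <- function(x, ...) {
  cat(sprintf("<ise_karyotype>%s\n",
              if (is.null(x$clone_id)) "" else paste0(" clone ", x$clone_id)))
  cat(sprintf("  n_ise: %d | core 1C: %.1f Mb | female 2C: %.1f Mb\n",
              x$n_ise, x$core_1c_mb, x$female_2c_mb))
  if (x$n_ise > 0) {
    cat("  ISE sizes (Mb):", paste(signif(x$ise_sizes_mb, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genome size of a male genome-size class
#'
#' A haploid male carrying `k` of its mother's ISEs has absolute genome size
#' `core_1c_mb + sum(sizes of carried ISEs)`; its size relative to the diploid
#' female (the flow-cytometry internal standard) is `absolute / female_2c_mb`.
#' A male of an ISE-free clone therefore sits at exactly half the female
#' signal.
#'
#' @param karyotype An [ise_karyotype()].
#' @param k Class index (number of ISEs carried), `0..n_ise`. Vectorised.
#' @param carried Optional integer vector of ISE indices carried (length `k`,
#'   only for scalar `k`); defaults to the `k` largest-index ISEs being
#'   irrelevant — with equal sizes any subset gives the same answer, with
#'   unequal sizes the default takes the first `k` in the stored order.
#'
#' @return A tibble with columns `class_k`, `absolute_mb`, `relative_gs`
#'   (fraction of female 2C).
#' @examples
#' ky <- ise_karyotype(n_ise = 2, core_1c_mb = 200, ise_sizes_mb = c(20, 30))
#' male_genome_size(ky, k = 0:2)
#' @export
male_genome_size <- function(karyotype, k = 0:karyotype$n_ise, carried = NULL) {
  stopifnot(inherits(karyotype, "ise_karyotype"))
  if (any(k < 0 | k > karyotype$n_ise)) {
    abort("`k` must lie in 0..n_ise.")
  }
  sizes <- karyotype$ise_sizes_mb
  if (!is.null(carried)) {
    if (length(k) != 1) abort("`carried` requires a single `k`.")
    if (length(carried) != k) abort("`carried` must have length `k`.")
    if (any(carried < 1 | carried > karyotype$n_ise)) abort("Invalid ISE index in `carried`.")
    absolute <- karyotype$core_1c_mb + sum(sizes[carried])
  } else {
    cum <- c(0, cumsum(sizes))
    absolute <- karyotype$core_1c_mb + cum[k + 1]
  }
  tibble(
    class_k = as.integer(k),
    absolute_mb = absolute,
    relative_gs = absolute / karyotype$female_2c_mb
  )
}

#' Expected fluorescence peak positions for each male GS class
#'
#' Places each male genome-size class on the fluorescence axis using the
#' diploid female peak in the same sample as internal standard: a class with
#' relative genome size r sits at `r * female_peak`.
#'
#' @inheritParams male_genome_size
#' @param female_peak Fluorescence position (channel) of the female 2C peak.
#' @return Numeric vector of expected positions for classes `0..n_ise`,
#'   strictly increasing.
#' @export
expected_peak_positions <- function(karyotype, female_peak) {
  stopifnot(is.numeric(female_peak), length(female_peak) == 1, female_peak > 0)
  male_genome_size(karyotype)$relative_gs * female_peak
}
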