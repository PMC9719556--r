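#' Segregation parameters
#'
#' Validates the two parameters of the segregation model. The transmission
#' bias `tb` shifts a single ISE's probability of migrating towards the egg
#' pole to `(1 + tb) / 2` (so `tb = 0.1` means a transmission rate of 0.55,
#' mild meiotic drive; negative values mean drag). The cosegregation bias
#' `cb` acts on pairs of ISEs: positive values favour migration of a pair to
#' the same pole, negative values to opposite poles; `cb = -1` would force
#' strict opposite-pole migration, the behaviour of a regular chromosome
#' pair.
#'
#' Both parameters conceptually range over (-1, 1); the boundary values are
#' rejected because they put zero weight on whole sets of outcomes (and make
#' every outcome zero-weight for three or more ISEs). The fitting grid stays
#' at +/- 0.95 for the same reason.
#'
#' @param tb Transmission bias, in (-1, 1).
#' @param cb Cosegregation bias, in (-1, 1).
#' @return A named list `(tb, cb)` of class `seg_params`.
#' @examples
#' seg_params(tb = 0.1, cb = -0.3)
#' @export
seg_params <- function(tb = 0, cb = 0) {
  stopifnot(is.numeric(tb), length(tb) == 1, is.finite(tb),
            is.numeric(cb), length(cb) == 1, is.finite(cb))
  if (abs(tb) >= 1 || abs(cb) >= 1) {
    abort(paste("Degenerate segregation parameters: |tb| and |cb| must be < 1",
                "(at the boundary, whole outcome sets get zero weight)."))
  }
  structure(list(tb = tb, cb = cb), class = "seg_params")
}

as_seg_params <- function(params, tb = NULL, cb = NULL) {
  if (inherits(params, "seg_params")) return(params)
  if (is.list(params)) return(seg_params(params$tb %||% 0, params$cb %||% 0))
  seg_params(tb %||% 0, cb %||% 0)
}

#' Weight of one meiotic segregation outcome
#'
#' The elementary object of the segregation model: an outcome assigns each of
#' the mother's ISEs to the egg pole or the polar-body pole, and its
#' unnormalised weight is the product of one marginal factor per ISE —
#' `1 + tb` for the egg pole, `1 - tb` for the polar body — and one
#' interaction factor per unordered pair of ISEs — `1 + cb` if the pair went
#' to the same pole, `1 - cb` if it split. Normalising these weights over all
#' `2^n` outcomes yields the model's outcome probabilities.
#'
#' @param poles Character (or factor) vector over `c("egg", "polar")`, one
#'   entry per ISE; may have length zero.
#' @param params A [seg_params()] (or list with `tb`, `cb`).
#' @return A single non-negative weight.
#' @examples
#' outcome_weight(c("egg"), seg_params(tb = 0.1))            # 1.1
#' outcome_weight(c("egg", "egg"), seg_params(cb = -0.3))    # 0.7
#' outcome_weight(c("egg", "polar"), seg_params())           # 1
#' @export
outcome_weight <- function(poles, params) {
  params <- as_seg_params(params)
  poles <- as.character(poles)
  if (!all(poles %in% c("egg", "polar"))) {
    abort('`poles` entries must be "egg" or "polar".')
  }
  n <- length(poles)
  egg <- poles == "egg"
  marg <- prod(ifelse(egg, 1 + params$tb, 1 - params$tb))
  if (n < 2) return(marg)
  inter <- 1
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      inter <- inter * if (egg[i] == egg[j]) 1 + params$cb else 1 - params$cb
    }
  }
  marg * inter
}

# Unnormalised weight of the set of outcomes with exactly k ISEs at the egg
# pole. Every pole vector with k eggs has the same weight (ISEs are
# exchangeable in the model), with C(k,2) + C(n-k,2) same-pole pairs and
# k(n-k) split pairs, so the 2^n-term enumeration collapses to n + 1 terms.
class_weights <- function(n_ise, params) {
  k <- 0:n_ise
  choose(n_ise, k) *
    (1 + params$tb)^k * (1 - params$tb)^(n_ise - k) *
    (1 + params$cb)^(choose(k, 2) + choose(n_ise - k, 2)) *
    (1 - params$cb)^(k * (n_ise - k))
}

new_class_distribution <- function(freqs, n_ise, tb = NA_real_, cb = NA_real_) {
  out <- tibble(class_k = 0:n_ise, frequency = as.numeric(freqs))
  attr(out, "n_ise") <- as.integer(n_ise)
  attr(out, "tb") <- tb
  attr(out, "cb") <- cb
  class(out) <- c("ise_class_distribution", class(out))
  out
}

# Accept a class-distribution tibble (class_k, frequency) or a bare numeric
# vector of frequencies for classes 0..n; returns the frequency vector.
class_freq_vector <- function(x, check_normalised = TRUE) {
  if (is.data.frame(x)) {
    if (!all(c("class_k", "frequency") %in% names(x))) {
      abort("Expected columns `class_k` and `frequency`.")
    }
    x <- x[order(x$class_k), ]
    if (!identical(as.integer(x$class_k), seq_len(nrow(x)) - 1L)) {
      abort("`class_k` must be the complete sequence 0..n.")
    }
    f <- x$frequency
  } else {
    f <- as.numeric(x)
  }
  if (any(f < 0)) abort("Frequencies must be non-negative.")
  if (check_normalised && abs(sum(f) - 1) > 1e-8) {
    abort("Frequencies must sum to 1.")
  }
  f
}

#' Exact male genome-size class distribution under biased segregation
#'
#' Enumerates all segregation outcomes of `n_ise` ISEs under the
#' two-parameter model (see [outcome_weight()]) and returns the probability
#' that a haploid male carries `k = 0..n_ise` of them — the predicted
#' relative frequencies of the male genome-size classes. With `cb = 0` the
#' distribution is exactly Binomial(`n_ise`, `(1 + tb) / 2`); with `tb = 0`
#' it is symmetric in `k` and `n_ise - k`.
#'
#' @param n_ise Number of ISEs in the mother clone, at most 12 (the model is
#'   an exact enumeration over `2^n` outcomes).
#' @param params A [seg_params()]; alternatively give `tb` and `cb` directly.
#' @param tb,cb Convenience scalar parameters, used when `params` is missing.
#' @return A tibble of class `ise_class_distribution` with columns `class_k`
#'   (0..n_ise) and `frequency` (sums to 1), carrying `n_ise`, `tb`, `cb` as
#'   attributes.
#' @examples
#' class_distribution(1, tb = 0.1)           # 0.45 / 0.55: transmission rate 0.55
#' class_distribution(2, tb = 0, cb = -0.3)  # 0.175 / 0.65 / 0.175
#' @export
class_distribution <- function(n_ise, params = NULL, tb = 0, cb = 0) {
  stopifnot(length(n_ise) == 1, n_ise >= 0, n_ise == as.integer(n_ise))
  params <- as_seg_params(params, tb = tb, cb = cb)
  if (n_ise > 12) {
    abort(paste("Exact enumeration is capped at n_ise <= 12;",
                "use simulate_segregation() for a Monte-Carlo approximation."))
  }
  w <- class_weights(as.integer(n_ise), params)
  new_class_distribution(w / sum(w), n_ise, tb = params$tb, cb = params$cb)
}

#' Class distribution under unbiased random segregation
#'
#' The null expectation: each ISE independently reaches the egg pole with
#' probability 1/2, so class frequencies are Binomial(`n_ise`, 0.5). This is
#' the denominator of the observed/expected ratios.
#'
#' @inheritParams class_distribution
#' @return An `ise_class_distribution` tibble.
#' @examples
#' unbiased_distribution(2)  # 0.25 / 0.5 / 0.25
#' @export
unbiased_distribution <- function(n_ise) {
  stopifnot(length(n_ise) == 1, n_ise >= 0, n_ise == as.integer(n_ise))
  new_class_distribution(dbinom(0:n_ise, n_ise, 0.5), n_ise, tb = 0, cb = 0)
}

#' Observed/expected ratios per genome-size class
#'
#' Divides each observed class frequency by its expected frequency (usually
#' the unbiased Binomial(n, 0.5) expectation). Ratios above 1 mark
#' overrepresented classes; a monotone trend in class index indicates drive
#' or drag, while under/over-representation of the extreme classes indicates
#' cosegregation bias. Classes with zero expected frequency are flagged
#' undefined instead of divided.
#'
#' @param observed,expected Class distributions over the same classes:
#'   `ise_class_distribution` tibbles, data frames with `class_k` and
#'   `frequency`, or bare frequency vectors.
#' @return A tibble with columns `class_k`, `observed`, `expected`,
#'   `oe_ratio`, `undefined`.
#' @examples
#' oe_ratios(class_distribution(2, cb = -0.3), unbiased_distribution(2))
#' @export
oe_ratios <- function(observed, expected) {
  obs <- class_freq_vector(observed)
  exp_ <- class_freq_vector(expected)
  if (length(obs) != length(exp_)) {
    abort("`observed` and `expected` must cover the same classes.")
  }
  undef <- exp_ <= 0
  ratio <- ifelse(undef, NA_real_, obs / exp_)
  tibble(
    class_k = seq_along(obs) - 1L,
    observed = obs,
    expected = exp_,
    oe_ratio = ratio,
    undefined = undef
  )
}

#' Monte-Carlo simulation of male production under biased segregation
#'
#' Independent sampling oracle for [class_distribution()]: for each of
#' `n_males` meioses it draws a full pole assignment of the `n_ise` ISEs with
#' probability proportional to [outcome_weight()], and tallies how many males
#' fall in each genome-size class. Deterministic for a fixed `seed`.
#'
#' @inheritParams class_distribution
#' @param n_males Number of males (meioses) to simulate.
#' @param seed Integer seed; required so runs are reproducible.
#' @return A tibble with columns `class_k` and `count` (summing to
#'   `n_males`).
#' @examples
#' simulate_segregation(2, seg_params(tb = 0, cb = 0), n_males = 1000, seed = 1)
#' @export
simulate_segregation <- function(n_ise, params = NULL, n_males, seed, tb = 0, cb = 0) {
  stopifnot(length(n_ise) == 1, n_ise >= 0, n_ise == as.integer(n_ise),
            n_males >= 1, n_males == as.integer(n_males))
  params <- as_seg_params(params, tb = tb, cb = cb)
  if (n_ise > 12) abort("simulate_segregation() enumerates outcome weights; n_ise <= 12.")
  n_ise <- as.integer(n_ise)
  if (n_ise == 0) {
    return(tibble(class_k = 0L, count = as.integer(n_males)))
  }
  # all 2^n pole vectors and their weights, via the definitional primitive
  poles <- as.matrix(expand.grid(rep(list(c("egg", "polar")), n_ise),
                                 stringsAsFactors = FALSE))
  w <- apply(poles, 1, outcome_weight, params = params)
  k_of_outcome <- rowSums(poles == "egg")
  counts_by_outcome <- withr_seed(seed, rmultinom(1, n_males, w / sum(w))[, 1])
  count <- vapply(0:n_ise, function(k) sum(counts_by_outcome[k_of_outcome == k]),
                  numeric(1))
  tibble(class_k = 0:n_ise, count = as.integer(count))
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @export
print.ise_class_distribution <- function(x, ...) {
  cat(sprintf("<ise_class_distribution> n_ise = %d, tb = %s, cb = %s\n",
              attr(x, "n_ise"),
              format(attr(x, "tb")), format(attr(x, "cb"))))
  print(as_tibble(unclass_tbl(x)), ...)
  invisible(x)
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), "ise_class_distribution")
  x
}
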