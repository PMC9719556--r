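#' Reconstruct integer class counts from proportions
#'
#' Flow cytometry yields class proportions, but G-tests need counts, so the
#' number of males that went into a sample is redistributed over classes.
#' Largest-remainder (Hamilton) rounding is used: floors first, then the
#' leftover males go to the classes with the largest fractional remainders,
#' ties resolved towards the lower class index. The counts always sum to
#' `n_total`.
#'
#' @param n_total Number of males in the sample.
#' @param proportions Normalised class proportions (vector or data frame
#'   with `class_k`/`proportion` or `class_k`/`frequency`).
#' @param stage,replicate_id Optional labels carried through to the result.
#' @return A tibble with `class_k`, `count` and any labels.
#' @examples
#' reconstruct_counts(200, c(0.54, 0.46))  # 108, 92
#' @export
reconstruct_counts <- function(n_total, proportions, stage = NULL,
                               replicate_id = NULL) {
  stopifnot(length(n_total) == 1, n_total >= 1, n_total == as.integer(n_total))
  if (is.data.frame(proportions)) {
    col <- intersect(c("proportion", "frequency"), names(proportions))[1]
    if (is.na(col)) abort("Need a `proportion` or `frequency` column.")
    proportions <- proportions[order(proportions$class_k), ][[col]]
  }
  p <- as.numeric(proportions)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    abort("`proportions` must be non-negative and sum to 1.")
  }
  raw <- n_total * p
  base <- floor(raw)
  left <- round(n_total - sum(base))
  if (left > 0) {
    extra <- order(-(raw - base), seq_along(p))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  out <- tibble(class_k = seq_along(p) - 1L, count = as.integer(base))
  if (!is.null(stage)) out$stage <- stage
  if (!is.null(replicate_id)) out$replicate_id <- replicate_id
  out
}

count_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("class_k", "count") %in% names(x))) {
      abort("Expected columns `class_k` and `count`.")
    }
    x <- x[order(x$class_k), ]
    cnt <- x$count
  } else {
    cnt <- as.numeric(x)
  }
  if (any(cnt < 0) || sum(cnt) < 1) abort("Counts must be >= 0 and sum to >= 1.")
  cnt
}

g_statistic <- function(obs, expected_probs) {
  e <- sum(obs) * expected_probs
  terms <- ifelse(obs > 0, obs * log(obs / e), 0)
  2 * sum(terms)
}

#' G-test of goodness-of-fit
#'
#' Likelihood-ratio (G) test of observed class counts against expected
#' probabilities: `G = 2 * sum(O * ln(O / E))` with `E = n * p` and
#' `0 * ln(0)` taken as 0; `df = classes - 1`; p-value from the chi-square
#' upper tail. A Williams continuity correction
#' (`G / (1 + (k^2 - 1) / (6 n (k - 1)))`) is available but off by default.
#'
#' @param observed Integer class counts (vector, or tibble with
#'   `class_k`/`count` as from [reconstruct_counts()]).
#' @param expected_probs Expected class probabilities, all positive,
#'   summing to 1 (e.g. `unbiased_distribution(n)$frequency`).
#' @param williams Apply the Williams correction?
#' @param kind Label stored in the result.
#' @return A one-row tibble: `kind`, `G`, `df`, `p`.
#' @examples
#' g_test(c(60, 40), c(0.5, 0.5))
#' @export
g_test <- function(observed, expected_probs, williams = FALSE,
                   kind = "individual") {
  obs <- count_vector(observed)
  p <- class_freq_vector(expected_probs, check_normalised = FALSE)
  if (length(p) != length(obs)) abort("Class counts and probabilities differ in length.")
  if (any(p <= 0)) abort("All expected probabilities must be > 0.")
  p <- p / sum(p)
  G <- g_statistic(obs, p)
  k <- length(obs)
  if (williams) {
    G <- G / (1 + (k^2 - 1) / (6 * sum(obs) * (k - 1)))
  }
  df <- k - 1L
  tibble(kind = kind, G = G, df = as.integer(df),
         p = pchisq(G, df, lower.tail = FALSE))
}

#' Replicated G-tests of goodness-of-fit
#'
#' The replicated goodness-of-fit decomposition used to test transmission
#' across several flow-cytometry samples at once: the total G (sum of the
#' per-replicate G statistics) splits exactly into a pooled G (computed on
#' the summed counts — does the overall class distribution deviate from the
#' expectation?) and a heterogeneity G (total minus pooled — do the
#' replicates deviate from each other?), with degrees of freedom additive
#' in the same way. With `r` replicates and `k` classes the heterogeneity
#' test has `(r - 1) * (k - 1)` degrees of freedom.
#'
#' @param replicates A list of per-replicate counts (vectors or
#'   `class_k`/`count` tibbles), or a single data frame with columns
#'   `replicate_id`, `class_k`, `count`.
#' @inheritParams g_test
#' @return A tibble with rows `total`, `pooled`, `heterogeneity` (plus one
#'   `individual` row per replicate when `keep_individual = TRUE`), columns
#'   `kind`, `replicate_id`, `G`, `df`, `p`.
#' @param keep_individual Also return the per-replicate tests?
#' @examples
#' reps <- list(c(60, 40), c(55, 45), c(63, 37))
#' repeated_g_test(reps, c(0.5, 0.5))
#' @export
repeated_g_test <- function(replicates, expected_probs, williams = FALSE,
                            keep_individual = FALSE) {
  if (is.data.frame(replicates)) {
    stopifnot(all(c("replicate_id", "class_k", "count") %in% names(replicates)))
    ids <- unique(replicates$replicate_id)
    replicates <- lapply(ids, function(id) {
      d <- replicates[replicates$replicate_id == id, ]
      d$count[order(d$class_k)]
    })
    names(replicates) <- as.character(ids)
  }
  if (length(replicates) < 2) abort("Need at least two replicates.")
  counts <- lapply(replicates, count_vector)
  k <- unique(lengths(counts))
  if (length(k) != 1) abort("All replicates must share the same classes.")

  ind <- purrr::imap_dfr(counts, function(cnt, id) {
    mutate(g_test(cnt, expected_probs, williams = williams), replicate_id = as.character(id))
  })
  total <- tibble(kind = "total", replicate_id = NA_character_,
                  G = sum(ind$G), df = sum(ind$df))
  pooled <- g_test(Reduce(`+`, counts), expected_probs, williams = williams,
                   kind = "pooled") %>% mutate(replicate_id = NA_character_)
  het <- tibble(kind = "heterogeneity", replicate_id = NA_character_,
                G = total$G - pooled$G, df = total$df - pooled$df)
  out <- bind_rows(
    mutate(total, p = pchisq(G, df, lower.tail = FALSE)),
    select(pooled, kind, replicate_id, G, df, p),
    mutate(het, p = pchisq(pmax(G, 0), df, lower.tail = FALSE))
  )
  if (keep_individual) {
    out <- bind_rows(select(ind, kind, replicate_id, G, df, p), out)
  }
  select(out, kind, replicate_id, G, df, p)
}
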