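#' Configuration for a synthetic flow-cytometry experiment
#'
#' Collects everything needed to generate a realistic single-sample
#' fluorescence export for a clone: its karyotype, the true segregation
#' parameters, how many males were pooled, how many gated events the
#' instrument records, the peak broadening, and the debris level.
#'
#' Defaults emulate the conditions of the motivating experiments: up to 200
#' males pooled per sample; female-peak coefficients of variation between
#' roughly 1.7 and 3.95% (default 2.5%); a modest uniform debris background.
#' The event total is a generator convention (each male contributes many
#' stained nuclei, so events are allocated to classes in proportion to the
#' simulated male counts rather than per male).
#'
#' @param karyotype An [ise_karyotype()].
#' @param params A [seg_params()]; alternatively `tb`/`cb`.
#' @param tb,cb Convenience scalars used when `params` is missing.
#' @param n_males Males pooled into one sample (default 200).
#' @param n_events Total male-derived fluorescence events (default 8000).
#' @param cv_percent Gaussian peak coefficient of variation in percent,
#'   within `[0.5, 6]` (default 2.5).
#' @param background_fraction Fraction of all events that are uniform debris,
#'   in `[0, 0.5]` (default 0.05).
#' @param female_events Events contributed by the co-stained females
#'   (default 2500).
#' @param female_peak_channel Fluorescence channel of the diploid female
#'   peak (default 1e5, an arbitrary instrument scale).
#' @param stage_effects Optional named list of per-class relative viability
#'   weights, one entry per affected stage (e.g.
#'   `list(hatched = c(1, 1, 0.6))`); weights are applied to the true class
#'   frequencies and renormalised.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(karyotype, params = NULL, tb = 0, cb = 0,
                       n_males = 200, n_events = 8000, cv_percent = 2.5,
                       background_fraction = 0.05, female_events = 2500,
                       female_peak_channel = 1e5, stage_effects = NULL,
                       seed) {
  stopifnot(inherits(karyotype, "ise_karyotype"))
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  params <- as_seg_params(params, tb = tb, cb = cb)
  if (cv_percent < 0.5 || cv_percent > 6) {
    abort("`cv_percent` must lie in [0.5, 6].")
  }
  if (background_fraction < 0 || background_fraction > 0.5) {
    abort("`background_fraction` must lie in [0, 0.5].")
  }
  stopifnot(n_males >= 1, n_events >= 1, female_events >= 0,
            female_peak_channel > 0)
  structure(
    list(karyotype = karyotype, params = params, n_males = as.integer(n_males),
         n_events = as.integer(n_events), cv_percent = cv_percent,
         background_fraction = background_fraction,
         female_events = as.integer(female_events),
         female_peak_channel = female_peak_channel,
         stage_effects = stage_effects, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# apply per-class viability weights to a frequency vector
apply_viability <- function(freqs, weights) {
  if (length(weights) != length(freqs)) {
    abort("Viability weights must have one entry per class.")
  }
  if (any(weights < 0) || sum(freqs * weights) <= 0) {
    abort("Viability weights must be non-negative with non-zero total mass.")
  }
  freqs * weights / sum(freqs * weights)
}

#' Simulate one flow-cytometry sample for a clone
#'
#' Generates the full chain the wet lab would produce: male genome-size
#' class counts drawn multinomially from the segregation model; fluorescence
#' events per class at the positions implied by [male_genome_size()] scaled
#' so the diploid female internal standard sits at the configured reference
#' channel; Gaussian peak broadening at the configured CV; female
#' internal-standard events; and a uniform debris background over
#' `[0.2, 1.2]` times the female channel. Byte-identical for identical
#' configurations (including the seed).
#'
#' @param config A [sim_config()].
#' @param stage Stage label recorded in the sample; if it names an entry of
#'   `config$stage_effects`, those viability weights distort the true class
#'   frequencies before males are drawn.
#' @param seed_offset Internal offset so multi-sample wrappers can derive
#'   independent substreams from one root seed.
#' @return A list with `sample` (a [fluorescence_sample()]), `truth` (the
#'   stage-adjusted true `ise_class_distribution`) and `counts` (tibble
#'   `class_k`/`count` of simulated males).
#' @export
simulate_clone_sample <- function(config, stage = "hatched", seed_offset = 0) {
  stopifnot(inherits(config, "sim_config"))
  ky <- config$karyotype
  truth <- class_distribution(ky$n_ise, config$params)
  freqs <- truth$frequency
  if (!is.null(config$stage_effects) && stage %in% names(config$stage_effects)) {
    freqs <- apply_viability(freqs, config$stage_effects[[stage]])
  }

  pos <- expected_peak_positions(ky, config$female_peak_channel)
  sd_of <- function(mu) mu * config$cv_percent / 100
  if (length(pos) > 1 && any(diff(pos) < 2 * sd_of(pos[-length(pos)]))) {
    warn(paste("Class spacing is below twice the peak SD;",
               "classes will not be resolvable in this sample."))
  }

  events <- withr_seed(config$seed + seed_offset, {
    counts <- as.integer(rmultinom(1, config$n_males, freqs)[, 1])
    ev_class <- as.integer(rmultinom(1, config$n_events,
                                     counts / sum(counts))[, 1])
    male_ev <- unlist(purrr::map2(pos, ev_class, function(mu, m) {
      if (m == 0) numeric(0) else rnorm(m, mu, sd_of(mu))
    }))
    female_ev <- if (config$female_events > 0) {
      rnorm(config$female_events, config$female_peak_channel,
            sd_of(config$female_peak_channel))
    } else numeric(0)
    n_signal <- length(male_ev) + length(female_ev)
    n_bg <- round(config$background_fraction /
                    max(1 - config$background_fraction, 1e-9) * n_signal)
    bg_ev <- runif(n_bg, 0.2 * config$female_peak_channel,
                   1.2 * config$female_peak_channel)
    list(counts = counts,
         all = pmax(c(male_ev, female_ev, bg_ev), 1e-6))
  })

  truth_stage <- new_class_distribution(freqs, ky$n_ise,
                                        tb = config$params$tb,
                                        cb = config$params$cb)
  list(
    sample = fluorescence_sample(
      events = events$all, clone_id = ky$clone_id %||% "sim",
      stage = stage, female_peak = config$female_peak_channel,
      n_individuals = config$n_males),
    truth = truth_stage,
    counts = tibble(class_k = 0:ky$n_ise, count = events$counts)
  )
}

#' Simulate a developmental stage series for one clone
#'
#' Produces one sample per stage — synchronized male eggs (`sync`),
#' accumulated eggs (`accum`), hatched males (`hatched`) — sharing the same
#' underlying segregation parameters. Without stage effects the three
#' samples differ only by sampling noise; configured per-class viability
#' weights (e.g. reduced hatching of high-ISE males) distort the affected
#' stages.
#'
#' @param config A [sim_config()].
#' @param stages Character vector of stage labels.
#' @return A named list of [simulate_clone_sample()] results, one per stage.
#' @export
simulate_stage_series <- function(config,
                                  stages = c("sync", "accum", "hatched")) {
  stopifnot(inherits(config, "sim_config"))
  out <- purrr::imap(setNames(as.list(stages), stages), function(st, nm) {
    simulate_clone_sample(config, stage = st,
                          seed_offset = 1000 * match(st, stages))
  })
  out
}

#' Simulate an egg-level hatching table
#'
#' Generates Bernoulli hatch outcomes for male and female eggs where the
#' log-odds of hatching decline linearly with genome size for males but are
#' flat for females — the pattern of genome-size-dependent male embryonic
#' survival. Intended as input for an off-the-shelf binomial GLM.
#'
#' @param clones A data frame with columns `clone_id`, `female_2c_mb`, and
#'   optionally `male_gs_mb` (defaults to half the female value).
#' @param intercept Log-odds of hatching at the mean genome size.
#' @param male_slope Change in male log-odds per standard deviation of
#'   genome size (0 = no effect).
#' @param n_eggs Eggs per clone and sex.
#' @param seed Integer seed.
#' @return A tibble with one row per egg: `clone_id`, `sex`, `gs_mb`,
#'   `hatched`.
#' @export
simulate_hatching_table <- function(clones, intercept = 1,
                                    male_slope = -1, n_eggs = 100, seed) {
  stopifnot(is.data.frame(clones),
            all(c("clone_id", "female_2c_mb") %in% names(clones)))
  if (missing(seed)) abort("`seed` is mandatory.")
  if (n_eggs == 0) {
    return(tibble(clone_id = character(0), sex = character(0),
                  gs_mb = numeric(0), hatched = integer(0)))
  }
  male_gs <- if ("male_gs_mb" %in% names(clones)) {
    clones$male_gs_mb
  } else clones$female_2c_mb / 2
  grid <- tidyr::expand_grid(i = seq_len(nrow(clones)),
                             sex = c("male", "female"),
                             egg = seq_len(n_eggs))
  gs <- ifelse(grid$sex == "male", male_gs[grid$i],
               clones$female_2c_mb[grid$i])
  s <- sd(male_gs)
  gs_z <- if (is.finite(s) && s > 0) (gs - mean(male_gs)) / s else rep(0, nrow(grid))
  eta <- intercept + ifelse(grid$sex == "male", male_slope * gs_z, 0)
  p <- 1 / (1 + exp(-eta))
  hatched <- withr_seed(seed, rbinom(nrow(grid), 1, p))
  tibble(clone_id = clones$clone_id[grid$i], sex = grid$sex,
         gs_mb = gs, hatched = as.integer(hatched))
}
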