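# Shared fixture builders: everything is generated in code, seeded.

# brute-force class distribution by explicit summation of outcome_weight
# over all 2^n pole vectors -- the independent oracle for class_distribution
enumerate_class_freqs <- function(n_ise, params) {
  if (n_ise == 0) return(1)
  poles <- as.matrix(expand.grid(rep(list(c("egg", "polar")), n_ise),
                                 stringsAsFactors = FALSE))
  w <- apply(poles, 1, outcome_weight, params = params)
  k <- rowSums(poles == "egg")
  freqs <- vapply(0:n_ise, function(kk) sum(w[k == kk]), numeric(1))
  freqs / sum(freqs)
}

# standard small test clone: equal-sized ISEs, core 200 Mb
test_karyotype <- function(n_ise, ise_mb = 25, clone_id = "test") {
  ise_karyotype(n_ise = n_ise, core_1c_mb = 200,
                ise_sizes_mb = rep(ise_mb, n_ise), clone_id = clone_id)
}

# draw events from a mixture of normals (for mixture-fitting unit tests)
rmix_events <- function(n, means, sds, weights, seed) {
  stopifnot(length(means) == length(sds), length(means) == length(weights))
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  rnorm(n, means[comp], sds[comp])
}
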