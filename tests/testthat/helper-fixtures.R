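# fixtures built in code, shared across test files

# tiny deterministic trial: 3 genotypes x 2 blocks, one trait, values chosen
# so sums of squares are easy to brute-force
toy_trial <- function() {
  dat <- data.frame(
    genotype = rep(c("g1", "g2", "g3"), each = 2),
    block = rep(c("b1", "b2"), 3),
    y = c(1, 2, 3, 4, 5, 6)
  )
  trial_table(dat, trait_spec_list_public("y"))
}

# trait_spec_list is internal; rebuild the same thing from the exported API
trait_spec_list_public <- function(names, sense = "increase") {
  specs <- lapply(names, trait_spec, units = "", sense = sense)
  names(specs) <- names
  specs
}

# small simulation config with diagonal covariances
diag_config <- function(n_genotypes = 200, n_blocks = 3, s2g = 4, s2e = 1,
                        k = 1, seed = 1, block_sd = 0.5, mu = 50) {
  trial_config(
    n_genotypes = n_genotypes, n_blocks = n_blocks,
    traits = trait_spec_list_public(paste0("T", seq_len(k))),
    trait_means = rep(mu, k),
    genetic_cov = diag(rep(s2g, k), k),
    block_sd = block_sd,
    residual_cov = diag(rep(s2e, k), k),
    seed = seed
  )
}

# genotype means with a planted partition: `sizes` groups around centroids
# separated by `sep`, within-group noise sd 1
planted_means <- function(sizes, k_traits = 5, sep = 30, seed = 99) {
  set.seed(seed)
  n <- sum(sizes)
  M <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    matrix(rnorm(sizes[i] * k_traits, mean = sep * i), sizes[i], k_traits)
  }))
  rownames(M) <- sprintf("G%02d", seq_len(n))
  colnames(M) <- paste0("T", seq_len(k_traits))
  M
}

# brute-force Gower distance (loop form, independent of the implementation)
gower_brute <- function(M) {
  rng <- apply(M, 2, function(v) diff(range(v)))
  keep <- rng > 0
  M <- M[, keep, drop = FALSE]
  rng <- rng[keep]
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- mean(abs(M[i, ] - M[j, ]) / rng)
    }
  }
  D
}

published_extdata <- function(file) {
  read.csv(system.file("extdata", file, package = "mgidi"), check.names = FALSE)
}
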