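# Shared fixtures.  Heavy objects (trained networks, experiment runs) are
# memoized for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache, inherits = FALSE))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache, inherits = FALSE)
}

random_raw <- function(dims, seed = 1, spacing = voxel_spacing(1, 1, 1)) {
  withr::with_seed(seed, {
    raw_volume(array(sample(0:255, prod(dims), TRUE), dims),
               spacing = spacing)
  })
}

random_labels <- function(dims, seed = 1) {
  withr::with_seed(seed, {
    label_volume(array(sample(0:5, prod(dims), TRUE), dims))
  })
}

# a micro network with jittered biases (exact-zero pre-activations sit on the
# ReLU kink and would confound finite-difference gradient checks)
micro_network <- function(n_classes = 4, side = 8, base = 2, depth = 2,
                          attention = TRUE, batch_norm = TRUE,
                          upsample = "transposed", seed = 3) {
  net <- build_network(network_config(n_classes, side, base, depth,
                                      attention, batch_norm, upsample),
                       seed = seed)
  withr::with_seed(seed + 100, {
    for (pp in sbfseg:::param_paths(net)) {
      p <- net$params[[pp$path]]
      net$params[[pp$path]] <- p + rnorm(length(p), sd = 0.01)
    }
  })
  net
}

# small fixture phantom: reduced fractions so the 32-cube packs reliably
small_fractions <- c(plastid = 0.05, mitochondrion = 0.012, peroxisome = 0,
                     nucleus = 0.025)

# the desk-scale segmentation experiments reused by the acceptance tests
get_experiment <- function(seed) {
  memo(paste0("exp", seed), segmentation_experiment(seed = seed))
}
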