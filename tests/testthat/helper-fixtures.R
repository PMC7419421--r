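# Shared fixtures: all synthetic, built in code at test time.

# Tiny two-class cohort spec with disjoint single segments.
two_class_spec <- function(n_genes = 60, n_per_class = 8, penetrance = 1,
                           noise = 0, seed = 7L) {
  classes <- list(
    class_signature("alpha", data.frame(start = 5, length = 10,
                                        alteration = 2, penetrance = penetrance)),
    class_signature("beta", data.frame(start = 35, length = 10,
                                       alteration = -2, penetrance = penetrance)))
  cohort_spec(n_genes, classes, n_per_class, background_noise_rate = noise,
              seed = seed)
}

# Small six-class cohort used by pipeline tests.
small_six_class <- function(n_genes = 300, n_per_class = 12, seed = 3L, ...) {
  generate_cohort(six_class_default(n_genes = n_genes,
                                    n_samples_per_class = n_per_class,
                                    seed = seed, ...))
}

# Desk-scale model settings shared by pipeline tests.
tiny_ae <- function(...) list(encoder_widths = c(64, 24), code_dim = 8,
                              epochs = 8, ...)
tiny_clf <- function(...) list(filters_per_branch = 4, n_inception_blocks = 1,
                               dense_widths = c(16, 8), epochs = 8, ...)

# Class-separated Gaussian feature matrix for classifier-only tests.
make_features <- function(n_per_class = 20, dim = 16, m = 3, sep = 2,
                          seed = 5L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(m * dim, sd = sep), m, dim)
  x <- do.call(rbind, lapply(seq_len(m), function(c0)
    matrix(stats::rnorm(n_per_class * dim), n_per_class, dim) +
      matrix(centers[c0, ], n_per_class, dim, byrow = TRUE)))
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  labels <- rep(letters[seq_len(m)], each = n_per_class)
  names(labels) <- rownames(x)
  list(features = x, labels = labels)
}

# Brute-force expected accuracy of the likelihood-ratio classifier for
# two classes with disjoint single-segment signatures and zero noise:
# enumerate segment on/off outcomes. Ties split uniformly.
enumerate_two_class_accuracy <- function(p1, p2) {
  # class 1 sample: segment on (prob p1) -> profile impossible under class 2
  # (its background must be zero under zero noise) -> always correct;
  # segment off (prob 1-p1) -> all-zero profile, likelihoods (1-p1) vs (1-p2).
  score_zero <- function(pa, pb) {
    if ((1 - pa) > (1 - pb)) 1 else if ((1 - pa) < (1 - pb)) 0 else 0.5
  }
  acc1 <- p1 + (1 - p1) * score_zero(p1, p2)
  acc2 <- p2 + (1 - p2) * score_zero(p2, p1)
  (acc1 + acc2) / 2
}
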