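# Shared fixtures, built in code at test time.

# A tiny deterministic profile table: 2 compounds x 2 cell lines.
tiny_profiles <- function() {
  grid <- default_concentration_grid()
  resp <- rbind(
    c(0, 0, 0, 0, 0, 0, 10, 20, 35, 50, 65, 80, 90, 95),   # clean sigmoid
    c(3, -8, 12, 40, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99),
    c(rep(0, 14)),                                          # inactive
    c(0, 0, 0, 0, 0, 0, 50, 10, 90, 95, 96, 97, 98, 99))    # one spike
  qhts_profiles(c("cpdA", "cpdA", "cpdB", "cpdB"),
                c("BJ", "Jurkat", "BJ", "Jurkat"),
                resp, concentrations = grid)
}

# Small labelled toy descriptor space for dataset/kNN oracles.
toy_points <- function() {
  m <- matrix(c(0.0, 0.1, 0.2, 0.8, 0.9, 1.0,
                0.0, 0.0, 0.1, 0.9, 1.0, 0.9), ncol = 2,
              dimnames = list(sprintf("c%02d", 1:6), c("d1", "d2")))
  labels <- stats::setNames(c(0, 0, 0, 1, 1, 1), rownames(m))
  list(matrix = descriptor_matrix(m, scaled = TRUE), labels = labels)
}

# Random response curve on the percent scale, reproducible.
random_curve <- function(seed, n = 14) {
  with_seed(seed, runif(n, -30, 110))
}

# Well-separated two-class dataset for model sanity checks: class 1 sits
# near (1,...,1) in the informative columns, class 0 near the origin.
separable_data <- function(n_per_class = 20, p_informative = 3,
                           p_noise = 5, seed = 1, noise = 0.08) {
  with_seed(seed, {
    n <- 2 * n_per_class
    y <- rep(c(0, 1), each = n_per_class)
    inf <- matrix(rep(y, p_informative), n, p_informative) +
      matrix(rnorm(n * p_informative, sd = noise), n, p_informative)
    noise_m <- matrix(runif(n * p_noise), n, p_noise)
    m <- cbind(inf, noise_m)
    m <- pmin(pmax(m, 0), 1)
    dimnames(m) <- list(sprintf("s%03d", seq_len(n)),
                        c(sprintf("inf_%d", seq_len(p_informative)),
                          sprintf("noise_%d", seq_len(p_noise))))
    list(matrix = descriptor_matrix(m, scaled = TRUE),
         labels = stats::setNames(y, rownames(m)))
  })
}
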