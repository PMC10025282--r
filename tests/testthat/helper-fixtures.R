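# Shared fixtures: everything is generated in code at test time.

# Short protocol for fast unit tests: 60 s injection + 20 s recovery at 1 Hz.
shortProtocol <- function() exposureProtocol(60, 20, 1)

# Small noiseless low-humidity config on the short protocol.
smallConfig <- function(seed = 1L, noise = noiselessConfig(), ...) {
  experimentConfig(name = "small", gases = c("NO2", "NH3"),
                   humidity = "low", class_schema = "ratios",
                   mixture_reps = 3L, protocol = shortProtocol(),
                   noise = noise, seed = seed, ...)
}

# Planted-feature binary classification problem: p_inf informative columns
# (class mean shift `shift` s.d.) plus p_noise pure-noise columns.
plantedProblem <- function(n = 200L, p_inf = 10L, p_noise = 90L,
                           shift = 2, seed = 1L) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n %/% 2L)
  X <- matrix(stats::rnorm(n * (p_inf + p_noise)), n)
  X[y == "b", seq_len(p_inf)] <- X[y == "b", seq_len(p_inf)] + shift
  colnames(X) <- c(paste0("inf", seq_len(p_inf)),
                   paste0("noise", seq_len(p_noise)))
  list(X = X, y = y, informative = seq_len(p_inf),
       noise = p_inf + seq_len(p_noise))
}

# Tiny CNN configuration for unit tests (full-size runs live in the
# acceptance tests).
tinyCnn <- function(n_classes = 2L, input_len = 80L, epochs = 3L, ...) {
  cnnConfig(n_classes = n_classes, input_len = input_len,
            conv_widths = c(4L, 8L, 8L), linear_widths = c(16L, 8L),
            epochs = epochs, batch_train = 8L, batch_test = 8L, ...)
}

# Tiny labelled series set: class "a" rising kinetics, class "b" decaying,
# across channels; channels x length x n array plus labels.
tinySeriesSet <- function(n_per_class = 6L, len = 80L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(0, dim = c(7L, len, n))
  y <- rep(c("a", "b"), each = n_per_class)
  t <- seq_len(len) - 1L
  for (i in seq_len(n)) {
    for (ch in 1:7) {
      base <- if (y[i] == "a") (1 - exp(-t / 15)) * ch / 7
        else exp(-t / 15) * ch / 7
      x[ch, , i] <- base + stats::rnorm(len, 0, 0.02)
    }
  }
  x <- x / max(abs(x))
  list(x = x, y = y)
}
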