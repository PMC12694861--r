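# Shared fixtures: all built in code at test time.

random_state <- function(seed) {
  set.seed(seed)
  v <- complex(real = rnorm(16), imaginary = rnorm(16))
  v / sqrt(sum(Mod(v)^2))
}

random_phi <- function(seed) {
  set.seed(seed)
  runif(4)
}

# A basis state |b0 b1 b2 b3> from a bit vector.
basis_state <- function(bits) {
  s <- complex(16)
  s[sum(bits * c(8L, 4L, 2L, 1L)) + 1L] <- 1 + 0i
  s
}

# Tiny two-class blob dataset with a strong mean-intensity signal, for
# fast learnability smoke tests.
tiny_two_class <- function(n_per_class = 15L, size = 8L, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_class
  images <- array(0, dim = c(n, size, size))
  labels <- integer(n)
  for (i in seq_len(n)) {
    cls <- (i - 1L) %/% n_per_class
    base <- if (cls == 0L) 0.25 else 0.75
    images[i, , ] <- pmin(pmax(base + matrix(rnorm(size^2, 0, 0.08), size, size), 0), 1)
    labels[i] <- cls
  }
  list(images = images, labels = labels)
}

fast_config <- function(epochs = 6L, ...) {
  classifier_config(n_classes = 2L, epochs = epochs, batch_size = 10L, ...)
}
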