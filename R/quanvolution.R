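# The quanvolutional feature extractor: 2x2 patch encoding, 1..5 variational
# entangling layers with a fixed pair schedule, per-qubit <Z> measurement.

MAX_LAYERS <- 5L

#' Variational circuit parameters
#'
#' Bundles the trainable rotation angles with the entangler choice. The
#' angle tensor has shape `L x 4 x 3`: layer, qubit, rotation axis in the
#' order (X, Y, Z). One parameter set is shared by every patch of an image
#' (convolution-style weight sharing).
#'
#' @param theta Numeric array of dim `c(L, 4, 3)` with `1 <= L <= 5`, all
#'   entries finite, in radians.
#' @param entangler `"CNOT"` or `"CZ"`.
#' @return An object of class `variational_params`.
#' @export
variational_params <- function(theta, entangler = c("CZ", "CNOT")) {
  entangler <- match.arg(entangler)
  if (!is.numeric(theta) || length(dim(theta)) != 3L ||
      dim(theta)[2L] != 4L || dim(theta)[3L] != 3L) {
    stop("theta must be an L x 4 x 3 numeric array")
  }
  L <- dim(theta)[1L]
  if (L < 1L || L > MAX_LAYERS) stop("number of layers must be 1..", MAX_LAYERS)
  if (!all(is.finite(theta))) stop("all angles must be finite")
  structure(list(theta = theta, entangler = entangler, n_layers = L),
            class = "variational_params")
}

#' Randomly initialised variational parameters
#'
#' Angles drawn uniformly from `[-pi, pi)` using the supplied seed.
#'
#' @param n_layers Number of entangling layers, 1..5.
#' @param entangler `"CNOT"` or `"CZ"`.
#' @param seed Integer seed.
#' @return A `variational_params` object.
#' @export
random_params <- function(n_layers = 1L, entangler = c("CZ", "CNOT"), seed = 1L) {
  entangler <- match.arg(entangler)
  th <- local_seed(seed, stats::runif(n_layers * 4L * 3L, -pi, pi))
  variational_params(array(th, dim = c(n_layers, 4L, 3L)), entangler)
}

#' Zero-angle variational parameters
#'
#' All rotation angles zero; with the CZ entangler the whole circuit is
#' transparent to Z-expectations, which makes this the canonical debugging
#' configuration.
#'
#' @inheritParams random_params
#' @return A `variational_params` object.
#' @export
zero_params <- function(n_layers = 1L, entangler = c("CZ", "CNOT")) {
  variational_params(array(0, dim = c(n_layers, 4L, 3L)), match.arg(entangler))
}

#' @export
print.variational_params <- function(x, ...) {
  cat("<variational_params> ", x$n_layers, " layer(s), entangler = ",
      x$entangler, ", ", length(x$theta), " angles\n", sep = "")
  invisible(x)
}

validate_image <- function(image, tol = 1e-9) {
  if (!is.matrix(image) || !is.numeric(image)) stop("image must be a numeric matrix")
  h <- nrow(image); w <- ncol(image)
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop("image dimensions must be even, got ", h, "x", w)
  }
  if (anyNA(image) || min(image) < -tol || max(image) > 1 + tol) {
    stop("pixel values must lie in [0, 1]; normalise explicitly before quanvolving")
  }
  image
}

#' Split an image into non-overlapping 2x2 patches
#'
#' Each patch is flattened to `(phi0, phi1, phi2, phi3) =
#' (I[j,k], I[j,k+1], I[j+1,k], I[j+1,k+1])` with `(j, k)` the 0-based
#' position of the patch's top-left pixel. Patches are listed in row-major
#' order over the patch grid, so they losslessly reassemble the image.
#'
#' @param image Numeric matrix with even dimensions, values in `[0, 1]`.
#'   Out-of-range values are rejected, never clamped.
#' @return A data frame with one row per patch: columns `phi0`..`phi3` and
#'   the patch origin `row`, `col` (0-based, even).
#' @export
extract_patches <- function(image) {
  validate_image(image)
  ph <- patch_phi_matrix(image)
  org <- patch_origins(nrow(image), ncol(image))
  data.frame(phi0 = ph[1L, ], phi1 = ph[2L, ], phi2 = ph[3L, ], phi3 = ph[4L, ],
             row = org[, 1L], col = org[, 2L])
}

# 4 x n_patches matrix of phi vectors, patches in row-major grid order.
patch_phi_matrix <- function(image) {
  h <- nrow(image); w <- ncol(image)
  jj <- seq(1L, h, by = 2L); kk <- seq(1L, w, by = 2L)
  # row-major: row block varies slowest -> build with col index fastest
  grid <- expand.grid(k = kk, j = jj)
  rbind(image[cbind(grid$j, grid$k)],
        image[cbind(grid$j, grid$k + 1L)],
        image[cbind(grid$j + 1L, grid$k)],
        image[cbind(grid$j + 1L, grid$k + 1L)])
}

patch_origins <- function(h, w) {
  grid <- expand.grid(k = seq(0L, w - 1L, by = 2L), j = seq(0L, h - 1L, by = 2L))
  cbind(grid$j, grid$k)
}

#' Encode a 2x2 patch into a 4-qubit state
#'
#' Per qubit i the circuit applies `RY(pi * phi_i)` to `|0>` and then a
#' Hadamard, so the encoded register is the product state
#' `(x)_i H RY(pi phi_i) |0>`. After encoding, `<Z_i> = sin(pi * phi_i)`.
#'
#' @param phi Numeric vector of 4 pixel intensities in `[0, 1]` (a row of
#'   [extract_patches()] output also works).
#' @return A complex vector of 16 amplitudes (normalised).
#' @export
encode <- function(phi) {
  phi <- as_phi(phi)
  drop(encode_phi(matrix(phi, 4L, 1L)))
}

as_phi <- function(phi, tol = 1e-9) {
  if (is.data.frame(phi)) phi <- unlist(phi[1L, c("phi0", "phi1", "phi2", "phi3")])
  phi <- as.numeric(phi)
  if (length(phi) != 4L) stop("a patch has exactly 4 pixel values")
  if (anyNA(phi) || min(phi) < -tol || max(phi) > 1 + tol) {
    stop("patch values must lie in [0, 1]")
  }
  phi
}

# Batched product-state encoding: phi is 4 x n, result 16 x n.
encode_phi <- function(phi) {
  half <- pi * phi / 2
  c2 <- cos(half); s2 <- sin(half)
  # per-qubit single-qubit state after H . RY(pi phi): ((c+s), (c-s))/sqrt(2)
  up <- (c2 + s2) / sqrt(2)   # 4 x n, amplitude of |0>
  dn <- (c2 - s2) / sqrt(2)   # amplitude of |1>
  n <- ncol(phi)
  out <- matrix(0, DIM, n)
  for (idx in 0:(DIM - 1L)) {
    b <- bitwAnd(bitwShiftR(idx, c(3L, 2L, 1L, 0L)), 1L)
    amp <- rep(1, n)
    for (q in 1:4) amp <- amp * (if (b[q] == 0L) up[q, ] else dn[q, ])
    out[idx + 1L, ] <- amp
  }
  matrix(as.complex(out), DIM, n)
}

#' Entangler pair schedule for one layer
#'
#' The fixed schedule of ordered qubit pairs entangled in layer `l`:
#' ring pairs `(0,1),(1,2),(2,3),(3,0)` for layers 1 and 4, next-nearest
#' pairs `(0,2),(1,3),(2,0),(3,1)` for layers 2 and 5, and
#' `(0,1),(2,3),(1,2),(3,0)` for layer 3. For CNOT the first index of each
#' pair is the control.
#'
#' @param l Layer index, 1..5.
#' @return A 4 x 2 integer matrix of ordered pairs.
#' @export
entangler_pairs <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l != as.integer(l) ||
      l < 1L || l > MAX_LAYERS) {
    stop("layer index must be an integer in 1..", MAX_LAYERS)
  }
  if (l %in% c(1L, 4L)) {
    matrix(c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 0L), ncol = 2L, byrow = TRUE)
  } else if (l %in% c(2L, 5L)) {
    matrix(c(0L, 2L, 1L, 3L, 2L, 0L, 3L, 1L), ncol = 2L, byrow = TRUE)
  } else {
    matrix(c(0L, 1L, 2L, 3L, 1L, 2L, 3L, 0L), ncol = 2L, byrow = TRUE)
  }
}

#' Apply one variational layer
#'
#' Per qubit i, applies `RX(theta[l,i,1])`, then `RY(theta[l,i,2])`, then
#' `RZ(theta[l,i,3])`, followed by the layer's entangler pairs in schedule
#' order using `params$entangler`.
#'
#' @param state A 16-amplitude complex vector or 16 x n matrix.
#' @param params A [variational_params()] object.
#' @param l Layer index, `1 <= l <= params$n_layers`.
#' @return Transformed state, same shape as the input.
#' @export
apply_layer <- function(state, params, l) {
  stopifnot(inherits(params, "variational_params"))
  if (!is.numeric(l) || length(l) != 1L || l < 1L || l > params$n_layers) {
    stop("layer index beyond the configured number of layers")
  }
  l <- as.integer(l)
  ent <- make_gate(params$entangler)
  for (i in 0:3) {
    state <- apply_1q_fast(state, make_gate("RX", params$theta[l, i + 1L, 1L]), i)
    state <- apply_1q_fast(state, make_gate("RY", params$theta[l, i + 1L, 2L]), i)
    state <- apply_1q_fast(state, make_gate("RZ", params$theta[l, i + 1L, 3L]), i)
  }
  pairs <- entangler_pairs(l)
  for (p in seq_len(nrow(pairs))) {
    state <- apply_2q_fast(state, ent, pairs[p, 1L], pairs[p, 2L])
  }
  state
}

# 16 x 16 unitary of the full variational block, built by sequentially
# applying every layer to the 16 basis columns.
variational_unitary <- function(params) {
  U <- diag(as.complex(rep(1, DIM)))
  for (l in seq_len(params$n_layers)) U <- apply_layer(U, params, l)
  U
}

# The same unitary as a full_unitary() op list (dense-embedding oracle path).
variational_op_list <- function(params) {
  ops <- list()
  ent <- make_gate(params$entangler)
  for (l in seq_len(params$n_layers)) {
    for (i in 0:3) {
      ops <- c(ops, list(
        list(gate = make_gate("RX", params$theta[l, i + 1L, 1L]), qubits = i),
        list(gate = make_gate("RY", params$theta[l, i + 1L, 2L]), qubits = i),
        list(gate = make_gate("RZ", params$theta[l, i + 1L, 3L]), qubits = i)))
    }
    pairs <- entangler_pairs(l)
    for (p in seq_len(nrow(pairs))) {
      ops <- c(ops, list(list(gate = ent, qubits = pairs[p, ])))
    }
  }
  ops
}

#' Quanvolve a single patch
#'
#' Encodes the patch, applies all variational layers, and measures
#' `<Z_0>..<Z_3>` on the final state.
#'
#' @param phi Numeric vector of 4 pixel intensities in `[0, 1]`.
#' @param params A [variational_params()] object.
#' @return Numeric vector of 4 expectation values, each in `[-1, 1]`.
#' @export
quanvolve_patch <- function(phi, params) {
  stopifnot(inherits(params, "variational_params"))
  state <- encode(phi)
  for (l in seq_len(params$n_layers)) state <- apply_layer(state, params, l)
  vapply(0:3, function(q) expect_z(state, q), numeric(1L))
}

# Batched feature computation: phi 4 x n -> 4 x n matrix of <Z_i>.
# `enc` may carry pre-encoded states (16 x n) to skip re-encoding.
quanvolve_phi <- function(phi, params, U = NULL, enc = NULL) {
  if (is.null(U)) U <- variational_unitary(params)
  if (is.null(enc)) enc <- encode_phi(phi)
  final <- U %*% enc
  p <- Re(final * Conj(final))
  t(vapply(0:3, function(q) {
    ix <- qubit_index_pairs(q)
    colSums(p[ix$lower, , drop = FALSE]) - colSums(p[ix$upper, , drop = FALSE])
  }, numeric(ncol(final))))
}

#' Quanvolve a whole image into a feature map
#'
#' Runs the quantum circuit on every non-overlapping 2x2 patch and
#' assembles the per-qubit expectations into an `H/2 x W/2 x 4` array: the
#' four channels are `<Z_0>..<Z_3>` of the patch at the corresponding
#' position. All patches share the same parameters.
#'
#' @param image Numeric matrix, even dimensions, values in `[0, 1]`.
#' @param params A [variational_params()] object.
#' @return A numeric array of dim `c(H/2, W/2, 4)`, class `feature_map`,
#'   with attributes `entangler` and `n_layers`.
#' @export
quanvolve_image <- function(image, params) {
  stopifnot(inherits(params, "variational_params"))
  validate_image(image)
  phi <- patch_phi_matrix(image)
  f <- quanvolve_phi(phi, params)   # 4 x n, patches row-major
  h2 <- nrow(image) %/% 2L; w2 <- ncol(image) %/% 2L
  out <- array(0, dim = c(h2, w2, 4L))
  for (ch in 1:4) out[, , ch] <- matrix(f[ch, ], h2, w2, byrow = TRUE)
  structure(out, class = "feature_map",
            entangler = params$entangler, n_layers = params$n_layers)
}
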