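# The hybrid classifier: quanvolution front end -> small classical
# convolutional head, trained jointly. Quantum angles get exact
# parameter-shift gradients; classical weights get ordinary backprop.

#' Classical-head and training configuration
#'
#' The default head is one convolution block (8 filters, 3x3, ReLU, 2x2
#' max-pool), a flatten, a 32-unit ReLU dense layer and a softmax output -
#' a minimal configurable instance of the conv/pool/flatten/dense/softmax
#' family. Learning rate defaults to 0.001 over 40 epochs.
#'
#' @param n_classes Number of classes, `>= 2`.
#' @param conv_filters Number of convolution filters.
#' @param conv_kernel Square kernel size.
#' @param dense_units Width of the hidden dense layer.
#' @param optimizer One of `"adam"`, `"sgd"`, `"rmsprop"`, `"adamax"`.
#' @param learning_rate Positive step size.
#' @param epochs Training epochs, `>= 1`.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param frozen_quantum If `TRUE` the quantum angles are never updated
#'   (features are effectively precomputed once).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_classes = 3L, conv_filters = 8L, conv_kernel = 3L,
                              dense_units = 32L, optimizer = c("adam", "sgd", "rmsprop", "adamax"),
                              learning_rate = 0.001, epochs = 40L, batch_size = 16L,
                              seed = 1L, frozen_quantum = FALSE) {
  optimizer <- match.arg(optimizer)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 dense_units = as.integer(dense_units),
                 optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), frozen_quantum = isTRUE(frozen_quantum)),
            class = "classifier_config")
}

#' Initialise a hybrid quantum-classical model
#'
#' Quantum angles start uniform in `[-pi, pi)`; classical weights use a
#' seeded uniform fan-in initialisation.
#'
#' @param image_size Side length of the (square, even) input images; must
#'   give a feature map at least as large as the convolution kernel.
#' @param entangler `"CNOT"` or `"CZ"`.
#' @param n_layers Number of variational layers, 1..5.
#' @param config A [classifier_config()].
#' @return A `hybrid_model` object.
#' @export
hybrid_model <- function(image_size, entangler = c("CZ", "CNOT"), n_layers = 1L,
                         config = classifier_config()) {
  entangler <- match.arg(entangler)
  if (image_size %% 2L != 0L) stop("image_size must be even")
  h2 <- image_size %/% 2L
  k <- config$conv_kernel
  co <- h2 - k + 1L
  if (co < 1L) stop("image too small for the configured convolution kernel")
  po <- co %/% 2L
  if (po < 1L) stop("image too small for the 2x2 max-pool")
  flat <- po * po * config$conv_filters
  quantum <- random_params(n_layers, entangler, seed = derive_seed(config$seed, 11L))
  classical <- local_seed(derive_seed(config$seed, 13L), {
    fan_in_c <- k * k * 4L
    list(
      Wc = matrix(stats::runif(fan_in_c * config$conv_filters, -1, 1) / sqrt(fan_in_c),
                  fan_in_c, config$conv_filters),
      bc = numeric(config$conv_filters),
      W1 = matrix(stats::runif(flat * config$dense_units, -1, 1) / sqrt(flat),
                  flat, config$dense_units),
      b1 = numeric(config$dense_units),
      W2 = matrix(stats::runif(config$dense_units * config$n_classes, -1, 1) /
                    sqrt(config$dense_units),
                  config$dense_units, config$n_classes),
      b2 = numeric(config$n_classes)
    )
  })
  structure(list(quantum = quantum, classical = classical, config = config,
                 image_size = as.integer(image_size),
                 shapes = list(h2 = h2, conv_out = co, pool_out = po, flat = flat)),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  nq <- length(x$quantum$theta)
  nc <- sum(vapply(x$classical, length, integer(1L)))
  cat("<hybrid_model> ", x$image_size, "x", x$image_size, " input, ",
      x$quantum$n_layers, " ", x$quantum$entangler, " layer(s); ",
      nq, " quantum + ", nc, " classical parameters\n", sep = "")
  invisible(x)
}

as_image_array <- function(images) {
  if (is.list(images)) {
    images <- simplify2array(images)           # H x W x n
    images <- aperm(images, c(3L, 1L, 2L))
  }
  if (is.matrix(images)) images <- array(images, dim = c(1L, dim(images)))
  stopifnot(length(dim(images)) == 3L)
  images
}

# phi matrix (4 x n_images*patches) for a stack of images, patches row-major
# within each image.
stack_phi <- function(images) {
  n <- dim(images)[1L]
  do.call(cbind, lapply(seq_len(n), function(i) patch_phi_matrix(images[i, , ])))
}

# ---- classical head primitives ------------------------------------------

im2col <- function(fmap, k) {
  h <- dim(fmap)[1L]; w <- dim(fmap)[2L]; C <- dim(fmap)[3L]
  ho <- h - k + 1L; wo <- w - k + 1L
  out <- matrix(0, ho * wo, k * k * C)
  pos <- expand.grid(y = seq_len(ho), x = seq_len(wo))   # y fastest
  col <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    col <- col + 1L
    out[, col] <- fmap[cbind(pos$y + dy - 1L, pos$x + dx - 1L, c)]
  }
  out
}

col2im <- function(dcols, h, w, C, k) {
  ho <- h - k + 1L; wo <- w - k + 1L
  pos <- expand.grid(y = seq_len(ho), x = seq_len(wo))
  acc <- array(0, dim = c(h, w, C))
  col <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    col <- col + 1L
    idx <- cbind(pos$y + dy - 1L, pos$x + dx - 1L, c)
    # positions can overlap, so accumulate sequentially
    v <- dcols[, col]
    for (r in seq_len(nrow(idx))) acc[idx[r, 1L], idx[r, 2L], c] <- acc[idx[r, 1L], idx[r, 2L], c] + v[r]
  }
  acc
}

maxpool2 <- function(z) {
  ho <- dim(z)[1L]; wo <- dim(z)[2L]; F <- dim(z)[3L]
  po_h <- ho %/% 2L; po_w <- wo %/% 2L
  out <- array(0, dim = c(po_h, po_w, F))
  argmax <- array(0L, dim = c(po_h, po_w, F))
  for (f in seq_len(F)) for (x in seq_len(po_w)) for (y in seq_len(po_h)) {
    win <- z[(2L * y - 1L):(2L * y), (2L * x - 1L):(2L * x), f]
    m <- which.max(win)
    out[y, x, f] <- win[m]
    argmax[y, x, f] <- m
  }
  list(out = out, argmax = argmax)
}

maxpool2_back <- function(dout, argmax, ho, wo) {
  po_h <- dim(dout)[1L]; po_w <- dim(dout)[2L]; F <- dim(dout)[3L]
  dz <- array(0, dim = c(ho, wo, F))
  off <- cbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))  # which.max order in a 2x2
  for (f in seq_len(F)) for (x in seq_len(po_w)) for (y in seq_len(po_h)) {
    m <- argmax[y, x, f]
    dz[2L * y - 1L + off[m, 1L], 2L * x - 1L + off[m, 2L], f] <- dout[y, x, f]
  }
  dz
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass of the classical head over a list of feature maps.
head_forward <- function(model, fmaps) {
  cl <- model$classical
  k <- model$config$conv_kernel
  n <- length(fmaps)
  caches <- vector("list", n)
  hidden <- matrix(0, n, model$config$dense_units)
  flat <- matrix(0, n, model$shapes$flat)
  for (i in seq_len(n)) {
    cols <- im2col(fmaps[[i]], k)
    zc <- sweep(cols %*% cl$Wc, 2L, cl$bc, `+`)
    a <- pmax(zc, 0)
    aa <- array(a, dim = c(model$shapes$conv_out, model$shapes$conv_out,
                           model$config$conv_filters))
    mp <- maxpool2(aa)
    flat[i, ] <- as.vector(mp$out)
    caches[[i]] <- list(cols = cols, zc = zc, argmax = mp$argmax)
  }
  z1 <- sweep(flat %*% cl$W1, 2L, cl$b1, `+`)
  a1 <- pmax(z1, 0)
  logits <- sweep(a1 %*% cl$W2, 2L, cl$b2, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, caches = caches, flat = flat, z1 = z1, a1 = a1)
}

# Backprop through the classical head. dlogits: n x n_classes (already
# averaged). Returns classical gradients and the gradient w.r.t. every
# feature map (list of h2 x w2 x 4 arrays).
head_backward <- function(model, fwd, dlogits, need_input_grad = TRUE) {
  cl <- model$classical
  k <- model$config$conv_kernel
  n <- nrow(dlogits)
  gW2 <- t(fwd$a1) %*% dlogits
  gb2 <- colSums(dlogits)
  da1 <- dlogits %*% t(cl$W2)
  dz1 <- da1 * (fwd$z1 > 0)
  gW1 <- t(fwd$flat) %*% dz1
  gb1 <- colSums(dz1)
  dflat <- dz1 %*% t(cl$W1)
  gWc <- matrix(0, nrow(cl$Wc), ncol(cl$Wc))
  gbc <- numeric(length(cl$bc))
  dfmaps <- if (need_input_grad) vector("list", n) else NULL
  co <- model$shapes$conv_out
  for (i in seq_len(n)) {
    ca <- fwd$caches[[i]]
    dpool <- array(dflat[i, ], dim = c(model$shapes$pool_out, model$shapes$pool_out,
                                       model$config$conv_filters))
    dz <- maxpool2_back(dpool, ca$argmax, co, co)
    dzc <- matrix(dz, co * co, model$config$conv_filters) * (ca$zc > 0)
    gWc <- gWc + t(ca$cols) %*% dzc
    gbc <- gbc + colSums(dzc)
    if (need_input_grad) {
      dcols <- dzc %*% t(cl$Wc)
      dfmaps[[i]] <- col2im(dcols, model$shapes$h2, model$shapes$h2, 4L, k)
    }
  }
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       dfmaps = dfmaps)
}

fmaps_from_phi <- function(phi, U, params, h2, n_images, enc = NULL) {
  f <- quanvolve_phi(phi, params, U = U, enc = enc)   # 4 x (n*np)
  np <- h2 * h2
  lapply(seq_len(n_images), function(i) {
    block <- f[, ((i - 1L) * np + 1L):(i * np), drop = FALSE]
    arr <- array(0, dim = c(h2, h2, 4L))
    for (ch in 1:4) arr[, , ch] <- matrix(block[ch, ], h2, h2, byrow = TRUE)
    arr
  })
}

#' Forward pass of the hybrid model
#'
#' Quanvolves every image with the model's quantum parameters and runs the
#' classical head; rows of the result are softmax class probabilities.
#'
#' @param model A [hybrid_model()].
#' @param images A `n x H x W` array, a list of matrices, or one matrix.
#' @return An `n x n_classes` matrix of probabilities (rows sum to 1).
#' @export
forward <- function(model, images) {
  stopifnot(inherits(model, "hybrid_model"))
  images <- as_image_array(images)
  if (dim(images)[2L] != model$image_size || dim(images)[3L] != model$image_size) {
    stop("image shape does not match the model's configured input size")
  }
  phi <- stack_phi(images)
  U <- variational_unitary(model$quantum)
  fmaps <- fmaps_from_phi(phi, U, model$quantum, model$shapes$h2, dim(images)[1L])
  head_forward(model, fmaps)$probs
}

#' Predicted class labels
#'
#' Argmax of [forward()] probabilities; ties break to the lowest class
#' index. Labels are 0-based.
#'
#' @inheritParams forward
#' @return Integer vector of labels in `0..n_classes-1`.
#' @export
predict_labels <- function(model, images) {
  probs <- forward(model, images)
  max.col(probs, ties.method = "first") - 1L
}

#' Parameter-shift gradient of the patch features
#'
#' Exact gradient of the four `<Z>` features of one patch with respect to
#' the rotation angle `theta[l, i, k]`, computed with the parameter-shift
#' rule `(f(theta + pi/2) - f(theta - pi/2)) / 2`, which is exact for Pauli
#' rotations.
#'
#' @param phi Numeric vector of 4 pixel values in `[0, 1]`.
#' @param params A [variational_params()].
#' @param l Layer (1-based), `i` qubit (0-based, 0..3), `k` axis (0 = X,
#'   1 = Y, 2 = Z).
#' @param i,k See `l`.
#' @return Numeric vector of 4 feature derivatives.
#' @export
quantum_gradient <- function(phi, params, l, i, k) {
  stopifnot(inherits(params, "variational_params"))
  if (l < 1L || l > params$n_layers) stop("layer index out of range")
  if (i < 0L || i > 3L) stop("qubit index out of range")
  if (k < 0L || k > 2L) stop("axis index out of range")
  shift <- function(delta) {
    th <- params$theta
    th[l, i + 1L, k + 1L] <- th[l, i + 1L, k + 1L] + delta
    variational_params(th, params$entangler)
  }
  (quanvolve_patch(phi, shift(pi / 2)) - quanvolve_patch(phi, shift(-pi / 2))) / 2
}

# Batched parameter-shift over pre-encoded states: gradient of the scalar
# loss, given dL/dfeatures (4 x n matrix aligned with the state columns).
quantum_gradients_batch <- function(enc, params, dfeat) {
  L <- params$n_layers
  g <- array(0, dim = dim(params$theta))
  for (l in seq_len(L)) for (i in 1:4) for (k in 1:3) {
    th <- params$theta
    th[l, i, k] <- th[l, i, k] + pi / 2
    fp <- quanvolve_phi(NULL, variational_params(th, params$entangler), enc = enc)
    th[l, i, k] <- th[l, i, k] - pi
    fm <- quanvolve_phi(NULL, variational_params(th, params$entangler), enc = enc)
    g[l, i, k] <- sum(dfeat * (fp - fm) / 2)
  }
  g
}

# ---- optimizers ----------------------------------------------------------

make_optimizer <- function(name, lr) {
  t <- 0L; m <- NULL; v <- NULL
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rho <- 0.9
  switch(name,
    sgd = function(par, grad) par - lr * grad,
    adam = function(par, grad) {
      t <<- t + 1L
      if (is.null(m)) { m <<- numeric(length(par)); v <<- numeric(length(par)) }
      m <<- b1 * m + (1 - b1) * grad
      v <<- b2 * v + (1 - b2) * grad^2
      mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
      par - lr * mhat / (sqrt(vhat) + eps)
    },
    rmsprop = function(par, grad) {
      if (is.null(v)) v <<- numeric(length(par))
      v <<- rho * v + (1 - rho) * grad^2
      par - lr * grad / (sqrt(v) + eps)
    },
    adamax = function(par, grad) {
      t <<- t + 1L
      if (is.null(m)) { m <<- numeric(length(par)); v <<- numeric(length(par)) }
      m <<- b1 * m + (1 - b1) * grad
      v <<- pmax(b2 * v, abs(grad))
      par - (lr / (1 - b1^t)) * m / (v + eps)
    },
    stop("unknown optimizer: ", name)
  )
}

flatten_list <- function(lst) unlist(lst, use.names = FALSE)

unflatten_list <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    piece <- vec[(pos + 1L):(pos + n)]
    if (!is.null(dim(template[[nm]]))) dim(piece) <- dim(template[[nm]])
    out[[nm]] <- piece
    pos <- pos + n
  }
  out
}

#' Train the hybrid model
#'
#' Joint minibatch gradient descent on the categorical cross-entropy:
#' classical weights by backprop, quantum angles by the parameter-shift
#' rule (skipped when `config$frozen_quantum`). Fully deterministic for a
#' given model (the model carries the seed).
#'
#' @param model A freshly initialised [hybrid_model()].
#' @param images Training images, `n x H x W` array or list of matrices.
#' @param labels Integer labels in `0..n_classes-1`.
#' @param val_images,val_labels Optional held-out set evaluated each epoch.
#' @param verbose Print one line per epoch.
#' @return A list with `model` (trained) and `history` (data frame with
#'   epoch, loss, accuracy and validation columns when a validation set is
#'   supplied).
#' @export
train_hybrid <- function(model, images, labels, val_images = NULL,
                         val_labels = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hybrid_model"))
  images <- as_image_array(images)
  n <- dim(images)[1L]
  if (n == 0L) stop("empty training set")
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match image count")
  if (any(labels < 0L | labels >= model$config$n_classes)) {
    stop("labels must lie in 0..n_classes-1")
  }
  local_seed(derive_seed(model$config$seed, 17L),
             train_hybrid_impl(model, images, labels, val_images, val_labels, verbose))
}

train_hybrid_impl <- function(model, images, labels, val_images, val_labels, verbose) {
  cfg <- model$config
  n <- dim(images)[1L]
  h2 <- model$shapes$h2
  np <- h2 * h2
  phi_all <- stack_phi(images)
  enc_all <- encode_phi(phi_all)   # encoding is parameter-free: compute once
  has_val <- !is.null(val_images)
  if (has_val) {
    val_images <- as_image_array(val_images)
    enc_val <- encode_phi(stack_phi(val_images))
    nval <- dim(val_images)[1L]
  }
  onehot <- matrix(0, n, cfg$n_classes)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate)
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; ep_correct <- 0L
    for (bt in batches) {
      nb <- length(bt)
      cols <- as.vector(vapply(bt, function(i) ((i - 1L) * np + 1L):(i * np),
                               integer(np)))
      enc_b <- enc_all[, cols, drop = FALSE]
      U <- variational_unitary(model$quantum)
      fmaps <- fmaps_from_phi(NULL, U, model$quantum, h2, nb, enc = enc_b)
      fwd <- head_forward(model, fmaps)
      p_true <- fwd$probs[cbind(seq_len(nb), labels[bt] + 1L)]
      loss <- -mean(log(pmax(p_true, 1e-12)))
      if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch, "; aborting")
      ep_loss <- ep_loss + loss * nb
      ep_correct <- ep_correct + sum(max.col(fwd$probs, ties.method = "first") - 1L == labels[bt])
      dlogits <- (fwd$probs - onehot[bt, , drop = FALSE]) / nb
      grads <- head_backward(model, fwd, dlogits,
                             need_input_grad = !cfg$frozen_quantum)
      if (!cfg$frozen_quantum) {
        # dL/dfeature aligned with phi columns: channel c = qubit c-1,
        # patches row-major; invert the feature-map reshape
        dfeat <- matrix(0, 4L, nb * np)
        for (i in seq_len(nb)) {
          dm <- grads$dfmaps[[i]]
          for (ch in 1:4) {
            dfeat[ch, ((i - 1L) * np + 1L):(i * np)] <- as.vector(t(dm[, , ch]))
          }
        }
        gq <- quantum_gradients_batch(enc_b, model$quantum, dfeat)
      } else {
        gq <- array(0, dim = dim(model$quantum$theta))
      }
      par <- c(flatten_list(model$classical), as.vector(gqpar <- model$quantum$theta))
      grad <- c(flatten_list(grads[c("Wc", "bc", "W1", "b1", "W2", "b2")]),
                as.vector(gq))
      par_new <- opt(par, grad)
      ncl <- length(par) - length(gqpar)
      model$classical <- unflatten_list(par_new[seq_len(ncl)], model$classical)
      theta_new <- array(par_new[(ncl + 1L):length(par_new)],
                         dim = dim(model$quantum$theta))
      model$quantum <- variational_params(theta_new, model$quantum$entangler)
    }
    row <- data.frame(epoch = epoch, loss = ep_loss / n, accuracy = ep_correct / n)
    if (has_val) {
      U <- variational_unitary(model$quantum)
      fmaps_v <- fmaps_from_phi(NULL, U, model$quantum, h2, nval, enc = enc_val)
      pv <- head_forward(model, fmaps_v)$probs
      lv <- -mean(log(pmax(pv[cbind(seq_len(nval), as.integer(val_labels) + 1L)], 1e-12)))
      row$val_loss <- lv
      row$val_accuracy <- mean(max.col(pv, ties.method = "first") - 1L == as.integer(val_labels))
    }
    hist[[epoch]] <- row
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.4f%s\n", epoch, row$loss, row$accuracy,
                  if (has_val) sprintf("  val_acc %.4f", row$val_accuracy) else ""))
    }
  }
  history <- do.call(rbind, hist)
  class(history) <- c("training_history", "data.frame")
  list(model = model, history = history)
}
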