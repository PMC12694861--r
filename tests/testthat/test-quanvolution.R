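# Patch extraction, encoding, the layer schedule, and the feature extractor.

test_that("extract_patches tiles the image losslessly in row-major order", {
  img <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2, byrow = TRUE)
  p <- extract_patches(img)
  expect_equal(nrow(p), 1L)
  expect_equal(unlist(p[1L, 1:4], use.names = FALSE), c(0.1, 0.3, 0.2, 0.4))
  img4 <- matrix(runif(16), 4, 4)
  p4 <- extract_patches(img4)
  expect_equal(nrow(p4), 4L)
  expect_equal(cbind(p4$row, p4$col),
               matrix(c(0L, 0L, 0L, 2L, 2L, 0L, 2L, 2L), ncol = 2, byrow = TRUE))
  # reassembly
  rec <- matrix(0, 4, 4)
  for (i in seq_len(4)) {
    j <- p4$row[i] + 1L; k <- p4$col[i] + 1L
    rec[j, k] <- p4$phi0[i]; rec[j, k + 1L] <- p4$phi1[i]
    rec[j + 1L, k] <- p4$phi2[i]; rec[j + 1L, k + 1L] <- p4$phi3[i]
  }
  expect_equal(rec, img4)
  expect_equal(nrow(extract_patches(matrix(0.5, 10, 10))), 25L)
  expect_error(extract_patches(matrix(0.5, 3, 4)), "even")
  expect_error(extract_patches(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})

test_that("encoding gives the closed-form <Z> = sin(pi * phi)", {
  s0 <- encode(c(0, 0, 0, 0))
  for (q in 0:3) expect_equal(expect_z(s0, q), 0, tolerance = 1e-12)
  s_half <- encode(rep(0.5, 4))
  for (q in 0:3) expect_equal(expect_z(s_half, q), 1, tolerance = 1e-12)
  s_one <- encode(rep(1, 4))
  for (q in 0:3) expect_equal(expect_z(s_one, q), 0, tolerance = 1e-12)
  for (seed in 1:10) {
    phi <- random_phi(seed)
    s <- encode(phi)
    expect_equal(sum(Mod(s)^2), 1, tolerance = 1e-12)
    for (q in 0:3) expect_equal(expect_z(s, q), sin(pi * phi[q + 1L]),
                                tolerance = 1e-12)
  }
  expect_error(encode(c(0.5, 0.5, 1.5, 0.5)), "\\[0, 1\\]")
})

test_that("entangler schedule matches the printed layer pattern", {
  ring <- matrix(c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 0L), ncol = 2, byrow = TRUE)
  expect_equal(entangler_pairs(1), ring)
  expect_equal(entangler_pairs(4), ring)
  expect_equal(entangler_pairs(2),
               matrix(c(0L, 2L, 1L, 3L, 2L, 0L, 3L, 1L), ncol = 2, byrow = TRUE))
  expect_equal(entangler_pairs(5), entangler_pairs(2))
  expect_equal(entangler_pairs(3),
               matrix(c(0L, 1L, 2L, 3L, 1L, 2L, 3L, 0L), ncol = 2, byrow = TRUE))
  expect_error(entangler_pairs(0), "1..5")
  expect_error(entangler_pairs(6), "1..5")
})

test_that("a zero-angle CZ layer leaves every Z-expectation unchanged", {
  for (l in 1:5) {
    pr <- zero_params(5, "CZ")
    for (seed in 1:5) {
      v <- random_state(seed + 50)
      w <- apply_layer(v, pr, l)
      expect_equal(sum(Mod(w)^2), 1, tolerance = 1e-12)
      for (q in 0:3) expect_equal(expect_z(w, q), expect_z(v, q), tolerance = 1e-12)
    }
  }
})

test_that("a zero-angle CNOT ring propagates |1000> around the ring", {
  pr <- zero_params(1, "CNOT")
  s <- basis_state(c(1, 0, 0, 0))
  out <- apply_layer(s, pr, 1)
  # (0,1): |1100>, (1,2): |1110>, (2,3): |1111>, (3,0): |0111>
  expect_lt(max(Mod(out - basis_state(c(0, 1, 1, 1)))), 1e-12)
})

test_that("layer application rejects out-of-range layers", {
  pr <- zero_params(2, "CZ")
  expect_error(apply_layer(ground_state(), pr, 3), "beyond")
  expect_error(variational_params(array(0, dim = c(6, 4, 3))), "1..5")
  expect_error(variational_params(array(NaN, dim = c(1, 4, 3))), "finite")
})

test_that("quanvolve_patch has the zero-angle CZ closed form", {
  phi <- c(0.25, 0.5, 0.75, 1.0)
  for (L in 1:5) {
    f <- quanvolve_patch(phi, zero_params(L, "CZ"))
    expect_equal(f, c(sqrt(2) / 2, 1, sqrt(2) / 2, 0), tolerance = 1e-9)
  }
  # CNOT on |+> states: all expectations vanish at zero angles
  f0 <- quanvolve_patch(c(0, 0, 0, 0), zero_params(1, "CNOT"))
  expect_equal(f0, c(0, 0, 0, 0), tolerance = 1e-12)
})

test_that("quanvolve_patch matches the dense full_unitary oracle on random draws", {
  set.seed(303)
  max_diff <- 0
  for (r in 1:200) {
    L <- sample(1:5, 1)
    ent <- sample(c("CZ", "CNOT"), 1)
    pr <- variational_params(array(runif(L * 12, -pi, pi), dim = c(L, 4, 3)), ent)
    phi <- runif(4)
    f <- quanvolve_patch(phi, pr)
    expect_true(all(f >= -1 - 1e-12 & f <= 1 + 1e-12))
    # build the dense circuit independently, gate by gate
    ops <- list()
    for (l in seq_len(L)) {
      for (i in 0:3) {
        ops <- c(ops, list(
          list(gate = make_gate("RX", pr$theta[l, i + 1, 1]), qubits = i),
          list(gate = make_gate("RY", pr$theta[l, i + 1, 2]), qubits = i),
          list(gate = make_gate("RZ", pr$theta[l, i + 1, 3]), qubits = i)))
      }
      prs <- entangler_pairs(l)
      for (p in seq_len(nrow(prs))) {
        ops <- c(ops, list(list(gate = make_gate(ent), qubits = prs[p, ])))
      }
    }
    U <- full_unitary(ops)
    s <- U %*% encode(phi)
    f_oracle <- vapply(0:3, function(q) expect_z(drop(s), q), numeric(1))
    max_diff <- max(max_diff, max(abs(f - f_oracle)))
  }
  expect_lt(max_diff, 1e-9)
})

test_that("feature maps have the contracted shape and respect locality", {
  pr <- random_params(2, "CNOT", seed = 9)
  img <- matrix(runif(100), 10, 10)
  fm <- quanvolve_image(img, pr)
  expect_equal(dim(fm), c(5L, 5L, 4L))
  expect_true(all(is.finite(fm)) && all(fm >= -1 - 1e-12) && all(fm <= 1 + 1e-12))
  fm28 <- quanvolve_image(matrix(0.5, 28, 28), random_params(1, "CZ", seed = 1))
  expect_equal(dim(fm28), c(14L, 14L, 4L))
  # constant 0.5 image under zero-angle CZ: all entries 1
  fm_const <- quanvolve_image(matrix(0.5, 6, 6), zero_params(3, "CZ"))
  expect_equal(as.vector(unclass(fm_const)), rep(1, 6 / 2 * 6 / 2 * 4),
               tolerance = 1e-9)
  # locality: perturbing one patch changes only its feature-map pixel
  img2 <- img
  img2[3:4, 5:6] <- runif(4)   # patch at grid position (2, 3)
  fm2 <- quanvolve_image(img2, pr)
  changed <- which(apply(abs(unclass(fm2) - unclass(fm)) > 1e-12, c(1, 2), any))
  diff_mask <- apply(abs(unclass(fm2) - unclass(fm)) > 1e-12, c(1, 2), any)
  expect_equal(which(diff_mask, arr.ind = TRUE)[1, ], c(row = 2L, col = 3L))
  expect_equal(sum(diff_mask), 1L)
  expect_error(quanvolve_image(matrix(0.5, 5, 6), pr), "even")
})

test_that("quanvolution is deterministic and patch-order independent", {
  pr <- random_params(3, "CZ", seed = 4)
  img <- matrix(runif(64), 8, 8)
  expect_identical(quanvolve_image(img, pr), quanvolve_image(img, pr))
  # every feature-map pixel equals the independent single-patch computation
  fm <- quanvolve_image(img, pr)
  pt <- extract_patches(img)
  for (i in sample(nrow(pt), 5)) {
    f <- quanvolve_patch(unlist(pt[i, 1:4], use.names = FALSE), pr)
    expect_equal(as.numeric(fm[pt$row[i] / 2 + 1, pt$col[i] / 2 + 1, ]), f,
                 tolerance = 1e-12)
  }
})

test_that("zero-angle CZ transparency holds for every pixel and layer count", {
  img <- matrix(runif(64, 0, 1), 8, 8)
  for (L in 1:5) {
    fm <- quanvolve_image(img, zero_params(L, "CZ"))
    pt <- extract_patches(img)
    for (ch in 1:4) {
      expected <- sin(pi * pt[[ch]])
      got <- as.vector(t(unclass(fm)[, , ch]))
      expect_lt(max(abs(got - expected)), 1e-9)
    }
  }
})
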