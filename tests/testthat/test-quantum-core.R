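# The 4-qubit statevector engine and the printed gate matrices.

test_that("gate matrices match their printed definitions and are unitary", {
  cz <- make_gate("CZ")
  expect_equal(unclass(cz), diag(as.complex(c(1, 1, 1, -1))),
               ignore_attr = TRUE, tolerance = 1e-12)
  cnot <- make_gate("CNOT")
  expect_equal(Mod(cnot[4L, 3L]), 1)  # control 1 flips target
  expect_equal(Mod(cnot[3L, 4L]), 1)
  h <- make_gate("H")
  expect_equal(unclass(h) * sqrt(2), matrix(as.complex(c(1, 1, 1, -1)), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(make_gate("RY", 0)), diag(as.complex(c(1, 1))),
               ignore_attr = TRUE, tolerance = 1e-12)
  ry_pi <- make_gate("RY", pi)
  expect_equal(as.vector(Mod(ry_pi %*% c(1, 0) - c(0, 1))), c(0, 0),
               tolerance = 1e-12)
  for (nm in c("H", "CNOT", "CZ", "Z", "SX", "ECR")) {
    g <- make_gate(nm)
    expect_lt(max(Mod(Conj(t(g)) %*% g - diag(nrow(g)))), 1e-10)
  }
})

test_that("make_gate rejects bad input", {
  expect_error(make_gate("TOFFOLI"), "unknown gate")
  expect_error(make_gate("CZ", pi), "no angle")
  expect_error(make_gate("RY"), "requires an angle")
  expect_error(make_gate("RX", Inf), "finite")
})

test_that("hermitian gates are involutions and SX squares to X", {
  for (nm in c("H", "Z", "CNOT", "CZ")) {
    g <- make_gate(nm)
    expect_lt(max(Mod(g %*% g - diag(nrow(g)))), 1e-12)
  }
  sx <- make_gate("SX")
  x <- matrix(as.complex(c(0, 1, 1, 0)), 2, 2)
  expect_equal(unitary_fidelity(sx %*% sx, x), 1, tolerance = 1e-12)
})

test_that("rotations compose additively", {
  for (nm in c("RX", "RY", "RZ")) {
    a <- 0.7; b <- -1.3
    expect_lt(max(Mod(make_gate(nm, a) %*% make_gate(nm, b) -
                        make_gate(nm, a + b))), 1e-12)
  }
})

test_that("ground state is |0000> with unit norm and <Z> = +1 everywhere", {
  s <- ground_state()
  expect_equal(Mod(s[1L]), 1)
  expect_equal(sum(Mod(s)^2), 1, tolerance = 1e-12)
  for (q in 0:3) expect_equal(expect_z(s, q), 1)
})

test_that("single-qubit application matches tensor-product structure", {
  h <- make_gate("H")
  s <- apply_1q(ground_state(), h, 0)
  expect_equal(Mod(s[1L])^2, 0.5, tolerance = 1e-12)   # |0000>
  expect_equal(Mod(s[9L])^2, 0.5, tolerance = 1e-12)   # |1000>
  expect_equal(expect_z(s, 0), 0, tolerance = 1e-12)
  # H twice restores the state
  expect_lt(max(Mod(apply_1q(s, h, 0) - ground_state())), 1e-12)
  # <Z> = cos(theta) after RY(theta)|0>
  s2 <- apply_1q(ground_state(), make_gate("RY", pi / 2), 0)
  expect_equal(expect_z(s2, 0), 0, tolerance = 1e-12)
  expect_error(apply_1q(ground_state(), h, 4), "0..3")
  expect_error(apply_1q(ground_state(), matrix(as.complex(c(1, 1, 0, 1)), 2, 2), 0),
               "unitary")
})

test_that("two-qubit application honours control/target order and symmetry", {
  cnot <- make_gate("CNOT"); cz <- make_gate("CZ")
  s <- basis_state(c(1, 0, 0, 0))
  expect_lt(max(Mod(apply_2q(s, cnot, 0, 1) - basis_state(c(1, 1, 0, 0)))), 1e-12)
  # target in |1>, control in |0>: nothing happens
  s01 <- basis_state(c(0, 1, 0, 0))
  expect_lt(max(Mod(apply_2q(s01, cnot, 0, 1) - s01)), 1e-12)
  # reversed pair flips the other way
  expect_lt(max(Mod(apply_2q(s01, cnot, 1, 0) - basis_state(c(1, 1, 0, 0)))), 1e-12)
  for (seed in 1:5) {
    v <- random_state(seed)
    expect_lt(max(Mod(apply_2q(v, cz, 0, 3) - apply_2q(v, cz, 3, 0))), 1e-12)
    expect_lt(max(Mod(apply_2q(apply_2q(v, cz, 1, 2), cz, 1, 2) - v)), 1e-12)
  }
  expect_error(apply_2q(s, cnot, 2, 2), "must differ")
  expect_error(apply_2q(s, cnot, 0, 5), "0..3")
})

test_that("expect_z reads the right bit and stays in [-1, 1]", {
  expect_equal(expect_z(basis_state(c(0, 0, 0, 0)), 2), 1)
  expect_equal(expect_z(basis_state(c(1, 1, 1, 1)), 2), -1)
  for (seed in 1:10) {
    v <- random_state(seed)
    for (q in 0:3) {
      z <- expect_z(v, q)
      expect_true(z >= -1 - 1e-12 && z <= 1 + 1e-12)
    }
  }
})

test_that("norm is preserved through long random circuits", {
  set.seed(11)
  for (r in 1:10) {
    s <- random_state(r)
    for (step in 1:30) {
      if (runif(1) < 0.6) {
        s <- apply_1q(s, make_gate(sample(c("RX", "RY", "RZ"), 1), runif(1, -pi, pi)),
                      sample(0:3, 1))
      } else {
        q <- sample(0:3, 2)
        s <- apply_2q(s, make_gate(sample(c("CNOT", "CZ"), 1)), q[1L], q[2L])
      }
    }
    expect_lt(abs(sqrt(sum(Mod(s)^2)) - 1), 1e-9)
  }
})

test_that("full_unitary agrees with sequential application on random circuits", {
  set.seed(202)
  for (r in 1:100) {
    n_ops <- sample(3:10, 1)
    ops <- vector("list", n_ops)
    s_seq <- v0 <- random_state(r + 1000)
    for (j in seq_len(n_ops)) {
      if (runif(1) < 0.5) {
        g <- make_gate(sample(c("RX", "RY", "RZ"), 1), runif(1, -pi, pi))
        q <- sample(0:3, 1)
        ops[[j]] <- list(gate = g, qubits = q)
        s_seq <- apply_1q(s_seq, g, q)
      } else {
        g <- make_gate(sample(c("CNOT", "CZ"), 1))
        q <- sample(0:3, 2)
        ops[[j]] <- list(gate = g, qubits = q)
        s_seq <- apply_2q(s_seq, g, q[1L], q[2L])
      }
    }
    U <- full_unitary(ops)
    expect_lt(max(Mod(U %*% v0 - s_seq)), 1e-9)
  }
})

test_that("full_unitary of [(CZ, (0,1))] is diagonal with -1 exactly where b0=b1=1", {
  U <- full_unitary(list(list(gate = make_gate("CZ"), qubits = c(0, 1))))
  expect_lt(max(Mod(U - diag(diag(U)))), 1e-12)
  idx <- 0:15
  both <- bitwAnd(bitwShiftR(idx, 3L), 1L) & bitwAnd(bitwShiftR(idx, 2L), 1L)
  expect_equal(Re(diag(U)), ifelse(both, -1, 1))
  expect_error(full_unitary(list()), "nonempty")
  expect_error(full_unitary(list(list(gate = make_gate("CZ"), qubits = 0))),
               "dimension mismatch")
})
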