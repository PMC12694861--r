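# Dense statevector simulation of a 4-qubit register.
#
# Convention (fixed package-wide): qubit 0 is the leftmost tensor factor,
# i.e. the most significant bit of the basis index. Basis state |b0 b1 b2 b3>
# lives at 0-based index b0*8 + b1*4 + b2*2 + b3 (1-based index + 1 in R).

N_QUBITS <- 4L
DIM <- 16L

#' Construct a gate matrix
#'
#' Returns the unitary matrix of a named gate. Rotation gates (`RY`, `RX`,
#' `RZ`) take an angle in radians; all other gates are fixed. `RZ` uses the
#' symmetric-phase convention `diag(exp(-i*lambda/2), exp(+i*lambda/2))`.
#' `SX` is the square root of X (`SX %*% SX` equals X up to global phase) and
#' `ECR` is the echoed cross-resonance gate in the superconducting-hardware
#' convention `(X kron I - Y kron X)/sqrt(2)` on (control, target).
#'
#' @param name One of `"RY"`, `"RX"`, `"RZ"`, `"H"`, `"CNOT"`, `"CZ"`, `"Z"`,
#'   `"SX"`, `"ECR"`.
#' @param angle Rotation angle in radians; required for `RY`/`RX`/`RZ` and
#'   forbidden for the fixed gates.
#' @return A complex matrix (2x2 for single-qubit gates, 4x4 for two-qubit
#'   gates) with attributes `label` and `gate_dim`.
#' @examples
#' make_gate("CZ")
#' make_gate("RY", pi / 2)
#' @export
make_gate <- function(name, angle = NULL) {
  rot <- c("RY", "RX", "RZ")
  fixed <- c("H", "CNOT", "CZ", "Z", "SX", "ECR")
  if (!is.character(name) || length(name) != 1L || !(name %in% c(rot, fixed))) {
    stop("unknown gate name: ", paste(name, collapse = ","))
  }
  if (name %in% rot) {
    if (is.null(angle)) stop("gate ", name, " requires an angle")
    if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle)) {
      stop("angle must be a single finite number")
    }
  } else if (!is.null(angle)) {
    stop("gate ", name, " takes no angle")
  }
  m <- switch(name,
    RY = {
      c <- cos(angle / 2); s <- sin(angle / 2)
      matrix(as.complex(c(c, s, -s, c)), 2L, 2L)
    },
    RX = {
      c <- as.complex(cos(angle / 2)); s <- -1i * sin(angle / 2)
      matrix(c(c, s, s, c), 2L, 2L)
    },
    RZ = diag(c(exp(-1i * angle / 2), exp(1i * angle / 2))),
    H = matrix(as.complex(c(1, 1, 1, -1)), 2L, 2L) / sqrt(2),
    Z = diag(as.complex(c(1, -1))),
    SX = matrix(c(1 + 1i, 1 - 1i, 1 - 1i, 1 + 1i), 2L, 2L) / 2,
    CNOT = {
      m <- diag(as.complex(rep(1, 4)))
      m[3:4, 3:4] <- matrix(as.complex(c(0, 1, 1, 0)), 2L, 2L)
      m
    },
    CZ = diag(as.complex(c(1, 1, 1, -1))),
    ECR = {
      X <- matrix(as.complex(c(0, 1, 1, 0)), 2L, 2L)
      Y <- matrix(c(0, 1i, -1i, 0), 2L, 2L)
      I2 <- diag(as.complex(c(1, 1)))
      (kronecker(X, I2) - kronecker(Y, X)) / sqrt(2)
    }
  )
  structure(m, label = name, gate_dim = nrow(m))
}

#' The 4-qubit ground state
#'
#' @return Complex vector of 16 amplitudes with amplitude 1 at `|0000>`.
#' @export
ground_state <- function() {
  s <- complex(DIM)
  s[1L] <- 1 + 0i
  s
}

check_qubit <- function(qubit) {
  if (!is.numeric(qubit) || length(qubit) != 1L || is.na(qubit) ||
      qubit != as.integer(qubit) || qubit < 0L || qubit >= N_QUBITS) {
    stop("qubit index must be an integer in 0..3, got ", qubit)
  }
  as.integer(qubit)
}

check_unitary <- function(gate, tol = 1e-10) {
  d <- nrow(gate)
  if (max(abs(Conj(t(gate)) %*% gate - diag(d))) > tol) {
    stop("gate is not unitary within ", tol)
  }
  invisible(gate)
}

# 1-based index pairs (i0, i1) for each qubit: rows of `lower` have bit q = 0,
# rows of `upper` the matching index with bit q = 1.
qubit_index_pairs <- function(qubit) {
  bit <- bitwAnd(bitwShiftR(0:(DIM - 1L), 3L - qubit), 1L)
  list(lower = which(bit == 0L), upper = which(bit == 1L))
}

#' Apply a single-qubit gate to a 4-qubit state
#'
#' Applies `I (x) ... (x) U (x) ... (x) I` with `U` at tensor position
#' `qubit`. `state` may be a length-16 complex vector or a 16-column-state
#' matrix (16 x n), in which case the gate is applied to every column.
#'
#' @param state Complex vector of 16 amplitudes, or a 16 x n complex matrix.
#' @param gate A 2x2 unitary (from [make_gate()] or any complex matrix).
#' @param qubit Qubit index in 0..3 (0 = leftmost tensor factor).
#' @return Transformed state, same shape as the input.
#' @export
apply_1q <- function(state, gate, qubit) {
  qubit <- check_qubit(qubit)
  if (!is.matrix(gate) || nrow(gate) != 2L || ncol(gate) != 2L) {
    stop("apply_1q needs a 2x2 gate")
  }
  check_unitary(gate)
  apply_1q_fast(state, gate, qubit)
}

apply_1q_fast <- function(state, gate, qubit) {
  ix <- qubit_index_pairs(qubit)
  vec <- !is.matrix(state)
  if (vec) state <- matrix(state, DIM, 1L)
  a <- state[ix$lower, , drop = FALSE]
  b <- state[ix$upper, , drop = FALSE]
  state[ix$lower, ] <- gate[1L, 1L] * a + gate[1L, 2L] * b
  state[ix$upper, ] <- gate[2L, 1L] * a + gate[2L, 2L] * b
  if (vec) dim(state) <- NULL
  state
}

# 4 x 4 matrix of 1-based state indices: rows are the (bit_a, bit_b) sector
# (00, 01, 10, 11), columns the four configurations of the remaining qubits.
pair_index_table <- function(qubit_a, qubit_b) {
  idx <- 0:(DIM - 1L)
  ba <- bitwAnd(bitwShiftR(idx, 3L - qubit_a), 1L)
  bb <- bitwAnd(bitwShiftR(idx, 3L - qubit_b), 1L)
  sector <- ba * 2L + bb
  tab <- matrix(0L, 4L, 4L)
  for (s in 0:3) tab[s + 1L, ] <- which(sector == s)
  # align columns so that entries in one column share the spectator bits
  rest <- idx - ba * bitwShiftL(1L, 3L - qubit_a) - bb * bitwShiftL(1L, 3L - qubit_b)
  for (s in 0:3) tab[s + 1L, ] <- tab[s + 1L, order(rest[tab[s + 1L, ]])]
  tab
}

#' Apply a two-qubit gate to a 4-qubit state
#'
#' Applies the 4x4 `gate` to the ordered pair (`qubit_a`, `qubit_b`); for
#' CNOT, `qubit_a` is the control and `qubit_b` the target. Accepts a state
#' vector or a 16 x n column-state matrix.
#'
#' @inheritParams apply_1q
#' @param gate A 4x4 unitary matrix.
#' @param qubit_a,qubit_b Distinct qubit indices in 0..3.
#' @return Transformed state, same shape as the input.
#' @export
apply_2q <- function(state, gate, qubit_a, qubit_b) {
  qubit_a <- check_qubit(qubit_a)
  qubit_b <- check_qubit(qubit_b)
  if (qubit_a == qubit_b) stop("qubit_a and qubit_b must differ")
  if (!is.matrix(gate) || nrow(gate) != 4L || ncol(gate) != 4L) {
    stop("apply_2q needs a 4x4 gate")
  }
  check_unitary(gate)
  apply_2q_fast(state, gate, qubit_a, qubit_b)
}

apply_2q_fast <- function(state, gate, qubit_a, qubit_b) {
  tab <- pair_index_table(qubit_a, qubit_b)
  vec <- !is.matrix(state)
  if (vec) state <- matrix(state, DIM, 1L)
  old <- lapply(1:4, function(s) state[tab[s, ], , drop = FALSE])
  for (s_out in 1:4) {
    acc <- gate[s_out, 1L] * old[[1L]]
    for (s_in in 2:4) acc <- acc + gate[s_out, s_in] * old[[s_in]]
    state[tab[s_out, ], ] <- acc
  }
  if (vec) dim(state) <- NULL
  state
}

#' Pauli-Z expectation of one qubit
#'
#' `<psi|Z_qubit|psi>`, the probability-weighted average of +1 (bit 0) and
#' -1 (bit 1) for the given qubit. Always in `[-1, 1]`.
#'
#' @inheritParams apply_1q
#' @return A real scalar, or a vector of length n for a 16 x n state matrix.
#' @export
expect_z <- function(state, qubit) {
  qubit <- check_qubit(qubit)
  ix <- qubit_index_pairs(qubit)
  vec <- !is.matrix(state)
  if (vec) state <- matrix(state, DIM, 1L)
  p <- Re(state * Conj(state))
  out <- colSums(p[ix$lower, , drop = FALSE]) - colSums(p[ix$upper, , drop = FALSE])
  if (vec) out[[1L]] else out
}

# Embed a 1q gate at `qubit` into the full 16 x 16 register unitary.
embed_1q <- function(gate, qubit) {
  I2 <- diag(as.complex(c(1, 1)))
  factors <- rep(list(I2), N_QUBITS)
  factors[[qubit + 1L]] <- gate
  Reduce(kronecker, factors)
}

# Embed a 4x4 gate on the ordered pair (a, b) into 16 x 16, elementwise:
# U16[i, j] = G[sector(i), sector(j)] when the spectator bits agree.
embed_2q <- function(gate, qubit_a, qubit_b) {
  idx <- 0:(DIM - 1L)
  ba <- bitwAnd(bitwShiftR(idx, 3L - qubit_a), 1L)
  bb <- bitwAnd(bitwShiftR(idx, 3L - qubit_b), 1L)
  sector <- ba * 2L + bb
  rest <- idx - ba * bitwShiftL(1L, 3L - qubit_a) - bb * bitwShiftL(1L, 3L - qubit_b)
  U <- matrix(as.complex(0), DIM, DIM)
  for (i in seq_len(DIM)) {
    for (j in seq_len(DIM)) {
      if (rest[i] == rest[j]) U[i, j] <- gate[sector[i] + 1L, sector[j] + 1L]
    }
  }
  U
}

#' Dense 16x16 unitary of a gate sequence
#'
#' Brute-force composition of a circuit into a single register unitary. The
#' first listed operation acts first (the returned matrix is
#' `U_n %*% ... %*% U_1`). Intended as an oracle against which the sparse
#' sequential application in [apply_1q()]/[apply_2q()] can be checked.
#'
#' @param ops A list of operations, each a list with elements `gate` (a 2x2 or
#'   4x4 complex matrix) and `qubits` (one index, or an ordered pair).
#' @return A 16x16 complex matrix.
#' @examples
#' u <- full_unitary(list(list(gate = make_gate("H"), qubits = 0)))
#' @export
full_unitary <- function(ops) {
  if (!is.list(ops) || length(ops) == 0L) stop("ops must be a nonempty list")
  U <- diag(as.complex(rep(1, DIM)))
  for (op in ops) {
    g <- op$gate
    q <- op$qubits
    emb <- if (length(q) == 1L) {
      if (nrow(g) != 2L) stop("dimension mismatch: 1 qubit but gate is ", nrow(g), "x", ncol(g))
      embed_1q(g, check_qubit(q))
    } else if (length(q) == 2L) {
      if (nrow(g) != 4L) stop("dimension mismatch: 2 qubits but gate is ", nrow(g), "x", ncol(g))
      embed_2q(g, check_qubit(q[[1L]]), check_qubit(q[[2L]]))
    } else {
      stop("each op must address 1 or 2 qubits")
    }
    U <- emb %*% U
  }
  U
}

#' Fidelity between unitaries up to global phase
#'
#' `|trace(Conj(t(u)) %*% v)| / dim`, which is 1 exactly when `u` and `v`
#' are equal up to a global phase.
#'
#' @param u,v Square complex matrices of equal dimension.
#' @return A real number in `[0, 1]` (up to rounding).
#' @export
unitary_fidelity <- function(u, v) {
  if (!all(dim(u) == dim(v))) stop("dimension mismatch")
  Mod(sum(diag(Conj(t(u)) %*% v))) / nrow(u)
}
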