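# Hardware-level comparison of the two entanglers: decomposition of CNOT and
# CZ into the native ECR/SX/RZ basis of cross-resonance superconducting
# processors, gate counting, Pauli dephasing-error conjugation, and the
# coherence-time error-probability model.

#' Native decomposition of CNOT
#'
#' The CNOT gate expressed in the ECR/SX/RZ native basis,
#' `CNOT = (I (x) (SX . RZ(-pi/2))) . ECR . ((RZ(pi/2) . SX) (x) I)`,
#' listed first-applied-first: SX and RZ(pi/2) on the control, ECR on
#' (control, target), then RZ(-pi/2) and SX on the target. Five native gates
#' in total (1 ECR, 2 SX, 2 RZ).
#'
#' @return A `native_sequence` object (data frame of steps with columns
#'   `gate`, `q1`, `q2`, `angle`) with attribute `logical_gate`.
#' @export
cnot_native_sequence <- function() {
  steps <- data.frame(
    gate  = c("SX", "RZ", "ECR", "RZ", "SX"),
    q1    = c(0L, 0L, 0L, 1L, 1L),
    q2    = c(NA, NA, 1L, NA, NA),
    angle = c(NA, pi / 2, NA, -pi / 2, NA)
  )
  new_native_sequence("CNOT", steps)
}

#' Native decomposition of CZ
#'
#' The CZ gate in the same native basis,
#' `CZ = (I (x) RZ(pi)) . ECR . (RZ(-pi/2) (x) I)`: RZ(-pi/2) on the first
#' qubit, ECR, then RZ(pi) on the second. Three native gates (1 ECR, 2 RZ) -
#' no SX pulses at all.
#'
#' @return A `native_sequence` object.
#' @export
cz_native_sequence <- function() {
  steps <- data.frame(
    gate  = c("RZ", "ECR", "RZ"),
    q1    = c(0L, 0L, 1L),
    q2    = c(NA, 1L, NA),
    angle = c(-pi / 2, NA, pi)
  )
  new_native_sequence("CZ", steps)
}

new_native_sequence <- function(logical_gate, steps) {
  stopifnot(all(steps$gate %in% c("ECR", "SX", "RZ")))
  stopifnot(all(is.na(steps$q2) | steps$gate == "ECR"))
  structure(steps, class = c("native_sequence", "data.frame"),
            logical_gate = logical_gate)
}

#' @export
print.native_sequence <- function(x, ...) {
  cat("<native_sequence> for", attr(x, "logical_gate"), "-",
      nrow(x), "native gates\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Count native gates in a sequence
#'
#' @param seq A `native_sequence`.
#' @return A list with `counts` (named integer vector per gate name) and
#'   `total`.
#' @export
native_gate_count <- function(seq) {
  stopifnot(is.data.frame(seq))
  counts <- table(factor(seq$gate, levels = c("ECR", "SX", "RZ")))
  list(counts = c(counts), total = nrow(seq))
}

#' Percentage reduction in native gate count
#'
#' `100 * (total(a) - total(b)) / total(a)`: how many fewer native gates
#' sequence `b` needs relative to reference `a`.
#'
#' @param a Reference `native_sequence` (must be nonempty).
#' @param b Comparison `native_sequence`.
#' @return A percentage (positive when `b` is cheaper).
#' @export
reduction_pct <- function(a, b) {
  ta <- native_gate_count(a)$total
  tb <- native_gate_count(b)$total
  if (ta == 0L) stop("reference sequence is empty")
  100 * (ta - tb) / ta
}

# Compose a native sequence into its dense 4x4 unitary (qubit 0 = leftmost
# tensor factor), first step applied first.
compose_sequence <- function(seq) {
  I2 <- diag(as.complex(c(1, 1)))
  U <- diag(as.complex(rep(1, 4)))
  for (s in seq_len(nrow(seq))) {
    g <- if (is.na(seq$angle[s])) make_gate(seq$gate[s]) else make_gate(seq$gate[s], seq$angle[s])
    emb <- if (seq$gate[s] == "ECR") {
      if (seq$q1[s] == 0L && seq$q2[s] == 1L) g else stop("only the (0,1) pair is supported here")
    } else if (seq$q1[s] == 0L) {
      kronecker(g, I2)
    } else {
      kronecker(I2, g)
    }
    U <- emb %*% U
  }
  U
}

#' Check a native sequence against its logical gate
#'
#' Composes the sequence into a dense 4x4 unitary and reports its fidelity
#' (up to global phase) with the logical gate it claims to implement, plus
#' a boolean at threshold `1 - 1e-9`. Reporting a fidelity rather than
#' asserting exactness keeps a phase-convention mismatch in the ECR
#' definition detectable instead of silently wrong.
#'
#' @param seq A `native_sequence`.
#' @return List with `fidelity` and `equivalent`.
#' @export
verify_native_sequence <- function(seq) {
  target <- make_gate(attr(seq, "logical_gate"))
  fid <- unitary_fidelity(target, compose_sequence(seq))
  list(fidelity = fid, equivalent = fid >= 1 - 1e-9)
}

pauli_1q <- function(ch) {
  switch(ch,
    I = diag(as.complex(c(1, 1))),
    X = matrix(as.complex(c(0, 1, 1, 0)), 2L, 2L),
    Y = matrix(c(0, 1i, -1i, 0), 2L, 2L),
    Z = diag(as.complex(c(1, -1))),
    stop("Pauli characters must be one of I, X, Y, Z")
  )
}

pauli_2q <- function(label) {
  chars <- strsplit(label, "")[[1L]]
  if (length(chars) != 2L) stop("a two-qubit Pauli label has exactly 2 characters")
  kronecker(pauli_1q(chars[1L]), pauli_1q(chars[2L]))
}

pauli_labels_2q <- function() {
  as.vector(t(outer(c("I", "X", "Y", "Z"), c("I", "X", "Y", "Z"), paste0)))
}

phase_label <- function(z, tol = 1e-10) {
  cand <- c(`+1` = 1 + 0i, `-1` = -1 + 0i, `+i` = 0 + 1i, `-i` = 0 - 1i)
  d <- abs(cand - z)
  if (min(d) > tol) stop("phase ", format(z), " is not a 4th root of unity")
  names(cand)[which.min(d)]
}

#' Conjugate a Pauli error through an entangling gate
#'
#' For a Clifford gate G and Pauli error P, returns the Pauli E with
#' `G P = E G`, i.e. `E = G P G^dagger`, found by dense matrix algebra and
#' matched (within 1e-10) against the 16-element two-qubit Pauli basis.
#' This is the mechanism behind dephasing-error locality: a Z error on the
#' target commutes with CZ but is spread into a correlated ZZ error by CNOT.
#'
#' @param gate `"CNOT"` or `"CZ"` (first label character = control qubit).
#' @param error Two-character Pauli label over `I, X, Y, Z`, e.g. `"IZ"`.
#' @return List with `label` (the conjugated Pauli) and `phase` (one of
#'   `"+1"`, `"-1"`, `"+i"`, `"-i"`).
#' @examples
#' pauli_conjugation("CNOT", "IZ")  # -> ZZ: the error spreads
#' pauli_conjugation("CZ", "IZ")    # -> IZ: the error stays local
#' @export
pauli_conjugation <- function(gate = c("CNOT", "CZ"), error) {
  gate <- match.arg(gate)
  G <- make_gate(gate)
  P <- pauli_2q(error)
  E <- G %*% P %*% Conj(t(G))
  for (lab in pauli_labels_2q()) {
    Q <- pauli_2q(lab)
    # overlap tr(Q^dagger E)/4: a unit-modulus scalar iff E is that Pauli
    ov <- sum(diag(Conj(t(Q)) %*% E)) / 4
    if (abs(Mod(ov) - 1) < 1e-10) {
      if (max(Mod(E - ov * Q)) > 1e-10) next
      return(list(label = lab, phase = phase_label(ov)))
    }
  }
  stop("conjugation result is not proportional to a single Pauli (internal error)")
}

#' Pauli weight of a label
#'
#' Number of non-identity characters; the "size" of the error.
#'
#' @param label Pauli label string, e.g. `"IZ"`.
#' @return Integer weight.
#' @export
pauli_weight <- function(label) {
  sum(strsplit(label, "")[[1L]] != "I")
}

#' Coherence-limited gate error probability
#'
#' `P_err = 1 - exp(-t / T)` with `T = T1` for amplitude damping or
#' `T = T2` for dephasing: the probability that a gate of duration `t`
#' suffers the corresponding incoherent error.
#'
#' @param t Gate duration (seconds), `t >= 0`.
#' @param T1 Relaxation time (seconds), `> 0`.
#' @param T2 Dephasing time (seconds), `> 0`.
#' @param channel `"dephasing"` or `"amplitude_damping"`.
#' @return Probability in `[0, 1)`.
#' @export
error_probability <- function(t, T1, T2, channel = c("dephasing", "amplitude_damping")) {
  channel <- match.arg(channel)
  if (!is.numeric(t) || any(t < 0)) stop("gate duration t must be >= 0")
  if (T1 <= 0 || T2 <= 0) stop("coherence times must be positive")
  Tc <- if (channel == "dephasing") T2 else T1
  1 - exp(-t / Tc)
}

#' Machine-readable gate-level comparison report
#'
#' Assembles the full hardware argument for CZ over CNOT: both native
#' sequences with per-gate counts, the percentage reduction, composition
#' fidelities against the logical gates, and the conjugation table of all
#' 16 two-qubit Pauli errors through each gate.
#'
#' @return A list of class `gate_report`, serialisable to JSON via
#'   [gate_report_json()].
#' @export
gate_report <- function() {
  cnot_seq <- cnot_native_sequence()
  cz_seq <- cz_native_sequence()
  conj_tab <- do.call(rbind, lapply(c("CNOT", "CZ"), function(g) {
    do.call(rbind, lapply(pauli_labels_2q(), function(lab) {
      r <- pauli_conjugation(g, lab)
      data.frame(gate = g, input = lab, output = r$label, phase = r$phase,
                 input_weight = pauli_weight(lab),
                 output_weight = pauli_weight(r$label))
    }))
  }))
  structure(list(
    sequences = list(CNOT = as.data.frame(cnot_seq), CZ = as.data.frame(cz_seq)),
    counts = list(CNOT = native_gate_count(cnot_seq), CZ = native_gate_count(cz_seq)),
    reduction_pct = reduction_pct(cnot_seq, cz_seq),
    fidelity = list(CNOT = verify_native_sequence(cnot_seq)$fidelity,
                    CZ = verify_native_sequence(cz_seq)$fidelity),
    depth = list(CNOT = sequence_depth(cnot_seq), CZ = sequence_depth(cz_seq)),
    conjugation = conj_tab
  ), class = "gate_report")
}

# Longest qubit path through the sequence (depth of these sequences as
# written; transpiler outputs for the same gates may differ).
sequence_depth <- function(seq) {
  busy <- c(0L, 0L)
  for (s in seq_len(nrow(seq))) {
    qs <- if (is.na(seq$q2[s])) seq$q1[s] + 1L else c(seq$q1[s], seq$q2[s]) + 1L
    level <- max(busy[qs]) + 1L
    busy[qs] <- level
  }
  max(busy)
}

#' Serialise a gate report to JSON
#'
#' @param report A [gate_report()] object.
#' @param path Optional file path; when given the JSON is also written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
gate_report_json <- function(report = gate_report(), path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.gate_report <- function(x, ...) {
  cat("Native-gate comparison (ECR/SX/RZ basis)\n")
  cat(sprintf("  CNOT: %d gates (fidelity %.6f, depth %d)\n",
              x$counts$CNOT$total, x$fidelity$CNOT, x$depth$CNOT))
  cat(sprintf("  CZ:   %d gates (fidelity %.6f, depth %d)\n",
              x$counts$CZ$total, x$fidelity$CZ, x$depth$CZ))
  cat(sprintf("  reduction: %.1f%%\n", x$reduction_pct))
  spread <- x$conjugation[x$conjugation$output_weight > x$conjugation$input_weight, ]
  cat("  error-spreading conjugations:",
      paste(sprintf("%s: %s->%s", spread$gate, spread$input, spread$output),
            collapse = ", "), "\n")
  invisible(x)
}
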