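---
title: "Quanvolutional feature extraction and hybrid training: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quanvolutional feature extraction and hybrid training: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quanvolve)
```

# The model

`quanvolve` implements a quanvolutional feature extractor followed by a small
classical convolutional classifier, trained jointly. A grayscale image
$I \in [0,1]^{H \times W}$ (H, W even) is tiled into non-overlapping
$2\times 2$ patches; each patch is flattened to
$\phi = (\phi_0, \phi_1, \phi_2, \phi_3)$ with $\phi_0 = I_{j,k}$,
$\phi_1 = I_{j,k+1}$, $\phi_2 = I_{j+1,k}$, $\phi_3 = I_{j+1,k+1}$, and fed to
a 4-qubit circuit:

1. **Encoding.** Starting from $|0\rangle^{\otimes 4}$, each qubit $i$
   receives $R_Y(\pi \phi_i)$ followed by a Hadamard, so
   $U_{\text{enc}}(\phi) = \bigotimes_i H\, R_Y(\pi\phi_i)$. The encoded
   register is a product state, which the implementation exploits: encoding
   is a 4-fold Kronecker product, computed once per patch and reused across
   all variational evaluations.
2. **Variational layers.** Each of $L \in \{1,\dots,5\}$ layers applies per
   qubit the rotation string $R_Z(\theta_{l,i,2}) R_Y(\theta_{l,i,1})
   R_X(\theta_{l,i,0})$ (rightmost factor first), then an entangling block of
   four ordered two-qubit gates — CNOT for the v1 architecture, CZ for v2 —
   on a fixed schedule: ring pairs $(0,1),(1,2),(2,3),(3,0)$ in layers 1 and
   4, next-nearest pairs $(0,2),(1,3),(2,0),(3,1)$ in layers 2 and 5, and
   $(0,1),(2,3),(1,2),(3,0)$ in layer 3. The first index of a pair is the
   CNOT control.
3. **Measurement.** The Pauli-Z expectation of each qubit is read out
   exactly from the statevector. The four values become the four channels of
   the output pixel, producing an $H/2 \times W/2 \times 4$ feature map; one
   parameter tensor $\theta \in \mathbb{R}^{L\times 4\times 3}$ is shared by
   every patch, exactly as a convolution shares its kernel.

A useful closed form anchors the whole stack: after encoding,
$\langle Z_i \rangle = \sin(\pi \phi_i)$, and because CZ is diagonal it
cannot change any $|{\cdot}|^2$, so with all angles zero the CZ extractor is
*transparent*: every feature equals $\sin(\pi\cdot\text{pixel})$ for any
number of layers. This is the identity the test suite leans on hardest.

## Conventions

* **Bit order.** Qubit 0 is the leftmost tensor factor (most significant
  bit): basis index $= b_0\cdot 8 + b_1\cdot 4 + b_2\cdot 2 + b_3$. All
  embedding, measurement and oracle code shares this single convention.
* **Operator order.** Products apply right-to-left; the first gate listed in
  a sequence acts first.
* **$R_Z$ phase.** Symmetric convention
  $\mathrm{diag}(e^{-i\lambda/2}, e^{+i\lambda/2})$.
* **Rotation string.** The per-qubit string is $R_Z R_Y R_X$. A ZYZ
  ("strongly entangling layers") string is an equally defensible reading of
  the architecture family; the $R_ZR_YR_X$ form is the formal specification
  of this circuit and is what we implement. Since both are universal
  single-qubit parameterisations the difference is a reparameterisation of
  the same model class.
* **Superposition layer.** The Hadamard is folded into the encoder and
  applied exactly once, at encoding; it is not repeated per layer.
* **Layer 2/5 CZ degeneracy.** The printed schedule for layers 2 and 5
  contains each unordered pair twice ($(0,2),(2,0)$ and $(1,3),(3,1)$).
  CZ is symmetric and self-inverse, so for the CZ entangler these layers
  collapse to pure rotations. We implement the schedule literally rather
  than "fix" it: the degeneracy is a property of the architecture as
  specified, and the CNOT variant does not share it.

# Numerical design

The simulator is an exact dense statevector engine. Single- and two-qubit
gates act on a $16\times n$ complex matrix of column states via index
arithmetic (no $16\times 16$ products in the hot path), so a whole batch of
patches moves through the circuit at once. Because the variational block is
patch-independent, training evaluates it as one $16\times 16$ unitary
applied to all pre-encoded patch states with a single complex matrix
product. An independent oracle path (`full_unitary()`) composes the same
circuit by explicit Kronecker-embedded $16\times16$ matrix products; the
test suite checks the two routes agree to $10^{-9}$ on hundreds of random
circuits.

Tolerances: $10^{-10}$ for algebraic identities on fixed gate matrices,
$10^{-9}$ for composed circuits — comfortably above double-precision
accumulation over tens of gates. Unitary comparisons are made up to global
phase via $|\mathrm{tr}(U^\dagger V)|/\dim$. Pixel values outside $[0,1]$
(beyond $10^{-9}$) are rejected, never clamped, so silent data corruption is
impossible; normalisation is an explicit user step.

# Gradients and training

Quantum angles are trained with the parameter-shift rule,
$\partial_\theta f = [f(\theta + \pi/2) - f(\theta - \pi/2)]/2$, which is
exact for Pauli rotations — not an approximation — and makes the gradient
contract implementation-independent: the suite verifies it against central
finite differences ($h = 10^{-5}$, agreement within $10^{-5}$) on random
configurations. The classical head (default: one conv block of 8 filters,
$3\times3$, ReLU, $2\times2$ max-pool; dense 32, ReLU; softmax output) is
differentiated by ordinary backprop, and its input gradient is chained into
the parameter-shift factors so both parameter sets descend the same
cross-entropy jointly. A `frozen_quantum` mode covers the common shortcut of
treating the extractor as a fixed random feature map.

Optimizers: adam, sgd, rmsprop and adamax with the standard published update
rules; only the learning rate (default 0.001) and epoch count (default 40)
are treated as study conditions, the remaining hyperparameters sit at their
conventional defaults ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$; $\rho = 0.9$; zero momentum). Batch size defaults
to 16. Initialisation: quantum angles uniform in $[-\pi, \pi)$, classical
weights uniform scaled by $1/\sqrt{\text{fan-in}}$, all under seeds derived
deterministically from the single configured seed, so identical
configurations give bit-identical training histories. Ties in the argmax
prediction break to the lowest class index.

# Hardware-level analysis

The two entanglers are compared at the native-gate level of cross-resonance
superconducting processors, where neither CNOT nor CZ is native:

* CNOT decomposes as
  $(I \otimes (SX \cdot R_Z(-\pi/2))) \cdot \mathrm{ECR} \cdot ((R_Z(\pi/2) \cdot SX) \otimes I)$
  — five native gates (1 ECR, 2 SX, 2 RZ);
* CZ as $(I \otimes R_Z(\pi)) \cdot \mathrm{ECR} \cdot (R_Z(-\pi/2) \otimes I)$
  — three native gates (1 ECR, 2 RZ), a 40% reduction per entangling
  operation.

The package adopts the common convention
$\mathrm{ECR} = (X\otimes I - Y\otimes X)/\sqrt{2}$ and *verifies rather than
assumes* the decompositions: `verify_native_sequence()` composes each
sequence densely and reports its fidelity with the logical gate up to global
phase. Under this (or any other entangling) ECR convention the printed
sequences are **not** exactly equivalent to CNOT/CZ — solving for the ECR
the CZ formula would need yields a diagonal matrix, which no entangling gate
satisfies — so the sequences should be read as gate-count accounting of a
transpiler's output, with phases elided, rather than as exact circuit
identities. The report carries the fidelities so this remains visible; the
gate counts, the 40% reduction, and the depth of the sequences as written
are unaffected.

The dephasing argument is exact, however: `pauli_conjugation()` computes
$E = G P G^\dagger$ by dense algebra and matches it to the two-qubit Pauli
basis. A Z error on the target commutes with CZ
($\mathrm{CZ}\,(I\otimes Z) = (I\otimes Z)\,\mathrm{CZ}$) and stays
weight-1, while CNOT maps it to a correlated ZZ error
($\mathrm{CNOT}\,(I\otimes Z) = (Z\otimes Z)\,\mathrm{CNOT}$). The full
16-entry conjugation table for both gates is exported in `gate_report()`.
Gate error scales with duration through $P_{\text{err}} = 1 - e^{-t/T}$,
with $T = T_1$ (amplitude damping) or $T_2$ (dephasing).

# The synthetic task

No public fruit-quality accession backs a desk-scale rerun, so the package
generates its own three-class task (fresh / mild / rotten): a bright disc
("fruit", intensity 0.85) on a dark background (0.15), blemished by dark
spots (0.25) whose expected coverage fraction is the class signal —
per-class densities 0, 0.15 and 0.4 — plus Gaussian pixel noise
($\sigma = 0.05$) and sub-pixel placement jitter, all clipped to $[0,1]$.
The default dataset is 150 images, 50 per class, at $16\times16$ — the
balanced 150-image, three-class design of the study's custom apple set,
scaled from $100\times100$ to a resolution at which full 5-fold
cross-validated joint training runs in minutes on one CPU ($100\times100$
generation is supported via `image_size`). Spot count is Poisson with mean
$\text{density}\cdot(r_{\text{disc}}/r_{\text{spot}})^2$; the default spot
radius of 0.8 px keeps that count high enough that Poisson fluctuations do
not swamp the between-class intensity gaps, which a pilot of the
mean-intensity baseline (`separability_check()`, nearest class mean on
per-image mean intensity) places at roughly 0.85 holdout accuracy —
learnable but not trivial.

What the generator does *not* emulate: real textures, lighting and pose
variation, class-dependent shape deformation, label noise, and RGB colour.
Passing tests on this task therefore demonstrate that the pipeline trains,
that both entanglers learn a monotone intensity/texture signal well above
chance, and that the paired harness isolates the entangler — not that any
accuracy printed here transfers to photographs of fruit.

# Evaluation protocol

`kfold_split()` produces deterministic, by default label-stratified folds
(sizes within one of each other). `run_cv_experiment()` trains one model per
fold and reports fold accuracies, pooled out-of-fold metrics, and a
`mean ± margin` summary whose interval is literally
$(\text{mean}-\text{margin}, \text{mean}+\text{margin})$ — the convention of
the report tables this mirrors. The margin estimator is configurable
(sample standard deviation by default, standard error or t-based 95%
half-width as alternatives) because the source tables are not consistent
with any single estimator across rows; every report stamps the estimator it
used. Precision/recall/F1 aggregate support-weighted (macro also emitted);
a zero denominator scores 0 with a warning. `compare_entanglers()` forces
identical fold splits and identical per-fold initialisation seeds across
the CNOT and CZ arms, so differences are attributable to the entangler;
`entangler_stability()` exposes the dispersion comparison across seeds as a
measurable without asserting a winner.

Problem sizes used by the shipped checks: the oracle-equivalence suite runs
200 random circuit draws, the gradient check 50, and the end-to-end
acceptance run is the full default task (150 images, 5 folds, 40 epochs,
both entanglers) — about seven minutes of compute in total.

# Known limitations

* Exact expectations only: no sampling shot noise, no density-matrix noise
  channels; the dephasing analysis is algebraic, not a noisy simulation.
* The register is fixed at 4 qubits / $2\times2$ patches, stride 2,
  grayscale; the entangler schedule is defined for at most 5 layers and
  deliberately not extrapolated.
* The classical head is intentionally small; it is a harness for comparing
  entanglers, not a competitive image classifier.
* Reported accuracies concern the synthetic task only.
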