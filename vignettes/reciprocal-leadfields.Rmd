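---
title: "Reciprocal EEG lead fields: models, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal EEG lead fields: models, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science and the
numerical choices behind it: the forward model and its charge-based
boundary-element discretization, the reciprocal construction of the EEG
lead field, the PCA correction of the reference-electrode bias, the
depth-weighted minimum-norm inverse with dSPM normalization, and the
synthetic photic-stimulation study that ties everything together. It also
records the design decisions that were genuinely open, and what the
passing tests do and do not demonstrate about real data.

## The forward model

EEG source analysis treats focal cortical activation as a current dipole
with moment $q\,d$ (A·m) inside a piecewise-homogeneous volume conductor.
Under the quasi-static approximation, the potential $\phi$ satisfies
$\nabla\cdot(\sigma\nabla\phi) = \nabla\cdot J_{imp}$, with the current
density normal component continuous across conductivity interfaces and
vanishing on the skin--air boundary. A single EEG channel measures the
referenced potential difference
$$V_{i,0}(p;q) \;=\; \phi(r_i) - \phi(r_0),$$
where $r_i$, $r_0$ are the channel and reference electrode positions. The
lead-field (gain) matrix $L$ collects $L_{ij} = V_{i,0}(p_j; q_j)$ over a
source space of dipoles $(p_j, q_j)$; this package restricts sources to
unit dipoles oriented along the outward normal of a designated cortical
surface.

### Charge-based boundary elements

The solver's unknown is the induced surface charge density on every
conductivity interface (stored as $g = \rho/\varepsilon_0$, so potentials
come out in volts without carrying $\varepsilon_0$ around). On an
interface with inside/outside conductivities $\sigma_{in}, \sigma_{out}$
and contrast $k = (\sigma_{in}-\sigma_{out})/(\sigma_{in}+\sigma_{out})$,
current continuity yields a Fredholm equation of the second kind,
$$\frac{g}{2} - k\, n \cdot E_{ind}(g) \;=\; k\, n\cdot E_{primary},$$
where $E_{ind}$ is evaluated in the principal-value sense and
$E_{primary}$ is the impressed source's free-space field. Faces carry one
constant charge unknown, collocated at centroids. Four ingredients proved
essential for accuracy at desk scale and are worth recording:

* **Closed-form triangle integrals.** Potentials and fields of a
  uniformly charged flat triangle are evaluated with the standard
  line-integral closed forms whenever the target lies within six face
  diameters of the source face (`near_mult`); beyond that, centroid point
  charges suffice. The closed forms are exact for the principal value as
  well, so the self-term of the field operator vanishes for flat faces.
* **Row-sum corrected diagonal.** For a point on a closed surface the
  principal-value integral of the normal field of a *uniform* unit charge
  over that same surface equals exactly $1/2$. The self coefficient is
  set to reproduce this identity with the *computed* same-surface row
  sum, which cancels the discretization error of the strongest (uniform)
  mode of every surface.
* **Per-surface deflation.** The uniform mode of a closed surface has
  operator eigenvalue $(1-k)/2$: zero on the skin--air boundary ($k=1$)
  and about $0.0125$ on a resistive skull interface ($k\approx0.975$),
  so discretization error in those modes is amplified enormously. The
  physical solution carries zero net charge on every closed interface,
  which licenses a rank-one term per surface (proportional to its charge
  total) that leaves the solution unchanged while moving those
  eigenvalues to order $1/2$.
* **Consistent loads for concentrated sources.** The right-hand side is
  face-averaged: in closed form (a solid angle) for the injection
  monopoles, and by adaptive barycentric quadrature for dipoles close to
  a face. Point collocation of a nearly singular load aliases
  catastrophically.

The dense system is factorized in place with LAPACK (`dgetrf`), and the
factorization is cached on the operator object: a reciprocal lead-field
build solves ~60 right-hand sides on one geometry, where a single
factorization amortizes. A restarted matrix-free GMRES (`solver =
"gmres"`) is provided behind the same operator contract and is
cross-checked against the factorization in the tests; at desk scale the
factorization is both faster and more robust, which is why it is the
default. Residual diagnostics for the factorized path are computed by
re-applying $P L U$.

### Electrode model

Electrodes are circular contacts imprinted onto the skin triangulation:
faces whose centroid lies within the contact radius (measured
*geodesically* -- chordal distance misses membership entirely when faces
are larger than the disc, as happens at the cap apex on a coarse
icosphere) are bisected by conforming longest-edge (Rivara) refinement
until their longest edge is at most one third of the contact radius.
Injection distributes the total current over the contact faces by area,
as point monopoles displaced inward to half the local skin thickness.
The displacement depth is a deliberate deviation from placing monopoles
half an *edge length* below the surface: after imprinting, edges are a
fraction of a millimeter, and a monopole that shallow induces a shielding
charge structure at the same sub-millimeter scale, which the mesh cannot
represent; the representation error then behaves like current leaking
through the scalp and corrupts the deep field globally. Mid-skin
placement keeps the injected current physically equivalent (the patch
limit is recovered as the contact refines) while the induced structure
stays resolvable.

## Reciprocity and the lead-field builds

Helmholtz reciprocity states that the referenced potential a unit dipole
at $p$ (direction $d$) produces between electrodes $e_i$ and $e_0$ equals
$-E(p)\cdot d / I$, where $E$ is the electric field at $p$ when a current
$I$ enters at $e_i$ and leaves at $e_0$. The reciprocal build therefore
fills $L$ *by rows*: one injection solve per channel (anode = channel,
cathode = the common reference, 1 mA), then one field evaluation over all
sources. Sixty-one electrodes give sixty basis functions. The direct
build fills $L$ *by columns* -- one dipole solve per source, reading
contact-averaged skin potentials -- and serves as the independent
cross-check; it is what the simulator uses, so that recovery tests never
invert the same numerical route that generated the data.

For the default three-shell model the source shell is an interior probe
surface, not a conductivity interface, so the charge-density shortcut for
normally oriented dipoles (the field at an interface equals the local
induced charge density) degenerates there; rows are computed with the
field evaluator, which is what the identity reduces to. A charge sampler
(`sample_charge_density`) is available for models whose source surface is
a genuine interface.

### How closely do the two builds agree?

On the default configuration (three-shell sphere at subdivision 3,
61-electrode cap, 1280 sources at 60 mm radius) the two routes correlate
to 0.9993 with a relative Frobenius discrepancy of about 4%; on a sparser
31-electrode cap about 2.5%. A convergence study showed this residual is
a genuine property of zeroth-order collocation at this resolution: it
survives exact (closed-form) integration everywhere, it is insensitive to
refining individual surfaces, and it shrinks only with overall mesh size.
Discrete collocation simply does not satisfy reciprocity exactly --- the
evaluation functionals of the two builds are not adjoint with respect to
the discretized operator --- and the gap closes at the discretization
rate. Galerkin-type discretizations would restore near-exact discrete
reciprocity at the same resolution, at substantially higher assembly
cost; that trade-off is documented here as a known limitation rather than
hidden behind a tuned setting.

## PCA correction of the reference bias

Every reciprocal basis function shares the charge concentration near the
common reference cathode, so the rows of $L$ are predominantly
positively correlated (on the synthetic cap about 90% of pairs, with
distant electrode pairs anti-correlating) and the leading eigenvector of
the uncentered second-moment matrix $LL^\top$ has entries of a single
sign -- a Perron--Frobenius situation, verified in the tests. Subtracting the mean basis function is not
enough, because the shared component enters each row with a different
scale; projecting all rows onto the orthogonal complement of the leading
eigenvector removes it exactly ($u^\top L' = 0$ to machine precision).
The uncentered second moment -- not the mean-centered covariance -- is
used deliberately: mean-centering is precisely the correction that the
phenomenon defeats. The correction refuses to act when the two leading
eigenvalues are degenerate to within $10^{-10}$ relative, rather than
tie-breaking silently. A CAR (common average reference) re-expression of
the corrected matrix, with the implicit all-zero reference row, makes the
lead field compatible with common-average-referenced recordings and is
applied by default after the correction.

## Inverse operator

With $\hat L = \Sigma^{-1/2} L$ the noise-whitened (PCA-corrected, CAR)
lead field, the minimum-norm kernel is
$$M \;=\; R\,\hat L^\top\,(\hat L R \hat L^\top + \lambda s I)^{-1},
\qquad R_{jj} = \|\hat L_{\cdot j}\|^{-2\gamma},$$
with $s = \mathrm{tr}(\hat L R\hat L^\top)/M$ making $\lambda$
dimensionless and $R$ rescaled to median one. Two notational ambiguities
in the source material were resolved on dimensional grounds: the kernel
must carry $R\,\hat L^\top$ on the left (the stated form is not
conformable), and the depth exponent must be negative -- weaker (deeper)
columns need *larger* prior variance for the prior to act as a depth
correction; a positive exponent would anti-correct. The exponent rule
remains configurable for sensitivity checks. Pipeline defaults are
$\gamma = 1.4$ and $\lambda = 0.8$; when the regularized Gram matrix is
ill-conditioned, `auto_regularize()` doubles $\lambda$ until its 2-norm
condition number falls below $10^6$ (a double-precision safety margin;
the threshold is configurable).

dSPM divides each source time course by its noise sensitivity, the row
norm of $M$ (whitened noise has identity covariance), so pure noise maps
to unit per-source variance -- the tests verify this Monte-Carlo. Note
that dSPM is *not* invariant to rescaling the noise covariance alone
(claiming larger noise genuinely lowers the SNR map, by $c^{-1/2}$); the
invariance that holds, and is asserted in the tests, is joint unit
rescaling of data and covariance.

## The synthetic photic-stimulation study

The simulator emulates the paradigm the pipeline is designed for:
20 trials of 80 flashes at half the individual alpha peak frequency
(50% duty cycle), 5-second inter-trial breaks, 1000 Hz sampling, a
61-channel cap with one apex reference. Each flash evokes a biphasic
Gaussian-windowed burst peaking 100 ms later (12.7 ms Gaussian width,
~30 ms FWHM) on every source within the planted patch (12 mm radius,
10 nA·m per source). Patch centers are drawn from the posterior upper
quadrant of the source shell -- the synthetic analogue of the visual
cortex that photic stimulation activates. Sensor data are the *direct*
lead field applied to the patch, plus: spatially correlated pink noise
(20 latent $1/f$ sources mixed into channels, 15 µV RMS per channel) and
an amplitude-modulated alpha rhythm at the paradigm's iAPF (5 µV RMS) on
the posterior channels. With ~1500 averaged epochs this puts the evoked
SNR in the range where real recordings of this paradigm operate. A
separate resting-state generator plants an alpha bump at a chosen
frequency over pink noise to validate the alpha-peak estimator.

What the generator does *not* emulate: ocular/cardiac artifacts, bad
channels, non-stationary noise, skull inhomogeneity, and real cortical
folding. Passing recovery tests therefore demonstrate the correctness of
the numerical chain (meshing, forward solves, reciprocity, correction,
whitening, inversion) under the stated noise model -- not robustness to
the artifacts that visual inspection and ICA handle in experimental
practice, which the package accepts only as caller-provided masks.

## Preprocessing choices

The alpha-peak estimator follows the standard resting pipeline: 2--45 Hz
zero-phase FIR (Hamming-windowed, FFT-applied, group delay compensated;
the default tap count puts the transition at the lower band edge and
keeps DC below $-40$ dB), common average reference, occipital channels,
non-overlapping 30 s epochs with first and last dropped, Welch spectra
(4 s Hann segments, 50% overlap, 0.25 Hz bins), Savitzky--Golay smoothing
(11 bins, order 3), and the band-interior maximum in 8--13 Hz. The Welch
and smoothing parameters are stated choices -- 0.25 Hz resolution is the
granularity at which individual alpha peaks such as 8.75 Hz are
meaningful -- and are exposed in the configuration. The noise covariance
uses pooled baseline epochs with 5% diagonal shrinkage (guaranteeing
invertibility on the subspace that survives CAR); the P100 latency is the
global-field-power maximum in 65--155 ms, a window spanning the latencies
reported for this component, with ties broken toward the earlier sample.

## Scale of the shipped configuration

The default desk-scale model is a three-shell sphere (radii 90/85/80 mm,
conductivities 0.33/0.0042/0.33 S/m) at icosphere subdivision 3, about
22k charge unknowns after electrode imprinting, with a 1280-source shell
at 60 mm (two brain-face diameters below the innermost interface, keeping
the field evaluation at the sources in its smooth regime). One full
reciprocal build -- assembly, factorization, 60 injection solves, field
sampling -- takes a few minutes on one core; the planted-patch study runs
twenty seeded simulations through the complete pipeline. These sizes are
the package's choice of a configuration on which every claim can be
recomputed routinely; the method itself has no such ceiling (the matrix
is dense $O(N^2)$, and the GMRES path accepts any matvec, which is where
a fast-multipole accelerator would plug in).

## Known limitations

* Discrete reciprocity holds only to the collocation error (~2.5--4% at
  the shipped resolution; see above).
* The analytic oracles cover concentric spheres only; realistic
  geometries are validated indirectly (watertightness, convergence,
  reciprocity closure).
* The voltage-electrode (first-kind) contact model is not implemented;
  the current-electrode model stands in, with correctness pinned by the
  convention-free reciprocity and oracle tests.
* Anisotropic conductivity and MEG are out of scope.
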