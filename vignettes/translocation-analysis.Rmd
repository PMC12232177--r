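---
title: "Machine-learned collective variables and OPES for DNA polymerase translocation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-learned collective variables and OPES for DNA polymerase translocation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(opescv)
```

## The scientific problem

After a DNA polymerase adds a nucleotide, the double-stranded DNA must
slide through the enzyme by one base pair to free the active site —
*translocation*. In Y-family polymerases such as pol eta, crystal
structures of the pre-translocation (PRE) and post-translocation (POST)
complexes are nearly identical apart from the shifted DNA, so the dynamic
mechanism is invisible to static structures. The modern computational
route is: (i) describe the protein–DNA interface by a large set of
contact distances between positively charged side chains (lysine N-zeta,
arginine C-zeta) and backbone phosphates; (ii) learn low-dimensional
collective variables (CVs) from those descriptors; (iii) drive the slow
transition with on-the-fly probability enhanced sampling (OPES) biased
along the CVs; and (iv) reweight the biased trajectories into a free
energy surface (FES) whose minimum-energy paths and barriers summarise
the mechanism. The central mechanistic result this methodology exposes is
an *asynchronous, stepwise* translocation: the two DNA strands move one
at a time, defining two mutually exclusive pathways through intermediates
in which only the primer strand (INT1) or only the template strand (INT2)
has moved.

`opescv` implements that entire analysis chain and exercises it against a
synthetic surrogate system with fully known ground truth, so every stage
— descriptor filtering, CV training, biasing, state and pathway
classification, barrier extraction — is tested quantitatively.

## The surrogate system

### Landscape

`build_surrogate()` constructs a smooth two-dimensional potential over
latent coordinates $(x_1, x_2)$ = (primer progress, template progress).
Four basins sit at the corners of the unit square: PRE $(0,0)$, INT1
$(1,0)$, INT2 $(0,1)$, POST $(1,1)$. The functional form is a Coons-patch
blend of four one-dimensional edge profiles plus a central product bump:

* each edge profile is `E0 + (E1 - E0) * s(t) + b * phi(t)` with `s` the
  quintic smootherstep and `phi(t) = 16 t^2 (1-t)^2`;
* the blend reproduces each edge profile exactly on its edge, leaves the
  corners as exact critical points, and grows quartically outside the
  square (confinement);
* the bump amplitudes `b` are calibrated at build time by 1-D line scans
  and root finding so the edge saddles hit their targets to machine
  precision.

Defaults (kcal/mol): saddles above PRE of 7.5 (PRE–INT1), 15.0
(INT1–POST), 17.0 (PRE–INT2), and an INT2–POST saddle placed 10.0 above
the INT2 basin. Basin energies are PRE = 0 (the normalisation),
INT1 = 2.5, INT2 = 3.0, POST = 0. These basin values are a design choice
(nothing in the reference protocol pins them): each basin must lie below its
adjoining saddles, and with INT2 at 3.0 the INT2–POST saddle sits at 13.0
above PRE, which makes POST-origin transitions prefer the template-first
route (13.0 < 15.0) — the mirror of the PRE-origin primer-first
preference (7.5 < 17.0). A central penalty of 25 kcal/mol makes the
direct diagonal PRE–POST crossing at least 10 kT higher than every edge
saddle, so the two stepwise paths are the only viable routes.

Thermal energy is kT = 0.616 kcal/mol (310 K), keeping all energies on
the laboratory scale. Dynamics are overdamped Langevin (Euler–Maruyama)
with timestep 2.5e-4 in reduced units, chosen so the stiffest basin
curvature satisfies the usual accuracy condition and the
harmonic-oscillator equipartition test passes within 5%.

### Descriptors

`descriptor_specs()` defines the designed candidate pool of 350
contact-distance columns mirroring the ~350-contact screen of a real
polymerase–DNA interface:

* **69 informative** columns (35 primer-axis, 34 template-axis), one per
  synthetic residue–base-pair group: a logistic switch of one latent axis
  between a bound (~4 Å) and an unbound (~9 Å) plateau, crossing at
  $x = 0.5$ with width `tau = 0.2`, plus Gaussian noise of 0.4 Å;
* **81 redundant duplicates** sharing a residue–base-pair group with an
  informative column (noisier, slightly different response);
* **100 low-presence** columns whose plateaus (7.5–10.5 Å) stay above the
  contact cutoff in essentially all frames of both states;
* **100 non-discriminative** columns with a state-independent
  distribution.

The switching width deserves a note: it is set to 0.2 — comparable to a
few thermal widths of a basin (sd ~0.04 in latent units) — so that the
descriptors, and therefore any CV trained on them, vary appreciably over
the whole path, not just at the saddle. A much narrower switch makes the
trained CVs flat across most of each edge (the training data never sees
the slope), which leaves chain-rule bias forces without anything to push
on. Since the package's purpose is CV-driven biasing through the analytic
descriptor map, the response width is chosen to support that; it is wide
enough to be realistic (contacts break over a substantial fraction of a
base-pair step) and still leaves the two-SD separation rule with a large
margin.

### What the surrogate does and does not emulate

It reproduces the *statistical structure* the analysis assumes: many
correlated candidate descriptors of which a designed subset is
discriminative, metastable states separated by barriers of 12–28 kT, two
asymmetric pathways, and reactive configurations between states. It does
not emulate atomistic detail: no solvent or force field, no water-mediated
contacts, descriptor noise is independent Gaussian (real contact
distances have correlated, skewed fluctuations), and the latent dynamics
is two-dimensional by construction. Passing tests therefore validate the
*machinery* — filtering, training, biasing, reweighting, barrier
extraction — not any claim about a specific enzyme.

## Contact descriptors and the three-rule filter

For real structures, `compute_contact_distances()` reads PDB files
(single- or multi-model) via bio3d and measures lysine-N-zeta /
arginine-C-zeta to phosphate-P distances, one column per contact
definition.

`filter_descriptors()` screens a candidate pool against two state
ensembles with three rules applied in order; every rejection records the
first failing rule:

1. **presence** — the contact is within `presence_cutoff` of the partner
   in at least 50% of the frames of at least one state. The contact-
   presence cutoff is left open by the filtering rules themselves, so a default of
   6.0 Å is used — the upper end of the salt-bridge range for these atom
   pairs — and exposed as a knob.
2. **separation** — the state means differ by more than two standard
   deviations. The conservative `max(sd_A, sd_B)` reference is the
   default; a pooled-SD variant is available.
3. **de-duplication** — one survivor per residue–base-pair group, keeping
   the largest rule-2 margin (ties broken lexicographically, so output is
   deterministic).

On the packaged pool the filter retains exactly the 69 informative
columns. Filtering is idempotent and symmetric in the two states; both
properties are asserted in the test suite.

## The Deep-LDA collective variable

`train_deep_lda()` optimises a feed-forward network (default widths
[69, 30, 20, 15, 10, 5], ReLU) so that the leading generalized
eigenvalue of the two-class scatter problem in its last hidden layer —
Fisher's ratio of between-state to within-state variance — is maximised.
Training uses Adam at learning rate 5e-4 for 500 epochs (full batch),
L2 penalty 1e-4, and a ridge of 0.05 on the within scatter. The
per-sample gradient of the leading generalized eigenvalue is computed
with the standard fixed-eigenvector envelope formula and backpropagated.

The exported CV applies, in order:

1. the discriminant projection $u = w^\top h(x)$, sign-fixed so PRE is
   positive;
2. an affine normalisation $\hat u = a u + b$ placing the training-state
   means at exactly +1 (PRE) and −1 (POST) — the convention the
   protocol's downstream walls at ±1.5 assume;
3. a bounded saturation $s = L \arctan(\hat u / L)$ with scale $L = 40$,
   whose derivative is a Lorentzian window.

The ordering is deliberate. A trained discriminant projection has
magnitude of order $10^3$ on these cleanly separable data; saturating it
*before* normalisation crushes every state onto ±(saturation limit) and
erases the gradations between them — in particular the intermediates
become indistinguishable from POST, and chain-rule bias forces vanish
along the second translocation step. Normalising first keeps the
saturation inactive over the trained range (|û| ~ 1 ≪ 40), so it acts
purely as an extrapolation guard that keeps the CV bounded on arbitrary
inputs.

On the fixture the CV maps PRE/POST at +1/−1 with within-state spread
~0.05, the intermediates at intermediate values (INT1 ≈ −0.3,
INT2 ≈ −0.45), and PRE/POST histograms overlap by less than 5%.

## The multitask 2-D collective variable

`train_multitask()` fits an autoencoder (encoder [69, 50, 30, 15, 5, 2],
symmetric decoder, shifted-softplus activations, Adam at 1e-3 for 500
epochs) with two losses:

* **reconstruction** (mean squared error in standardized descriptor
  space) on unlabeled "reactive" data drawn along the transition tubes;
* **targeted-discriminant (TDA)** loss on the 2-D latent bottleneck,
  $\sum_{s,k} \alpha (\mu_{sk} - \mu^{tg}_{sk})^2 +
  \beta (\sigma_{sk} - \sigma^{tg}_{sk})^2$, pinning each labeled state
  to its target Gaussian. Targets: PRE (−6,−6), INT2 (−3,3), INT1 (3,−3),
  POST (6,6), all widths 0.2.

The reference protocol leaves open the TDA weights and how batches mix
the two datasets. Defaults here: equal loss weights
($\alpha = \beta = 1$, reconstruction:TDA = 1:1); each optimisation step
draws a stratified labeled sub-batch (250 frames per state) for the TDA
term and an independent unlabeled sub-batch (1000 frames) for the
reconstruction term, with 5 such steps per epoch (2500 Adam updates in
total). On the fixture (5000 labeled frames per state + 10000 reactive)
the four latent centroids land within 0.05 of their targets and
per-state latent SDs within [0.17, 0.21].

## OPES

`opes_config()` / `run_opes()` implement the OPES bias
$V(s) = \beta^{-1} \log (p(s) / p_{tg}(s))$ with the well-tempered target
$P_{tg} \propto P^{1/\gamma}$, from a kernel density estimate over
deposited Gaussians. Key parameters follow the method's standard names: BARRIER
(default 20 kcal/mol; $\gamma = \beta \cdot \mathrm{BARRIER}$ by
default), STRIDE (deposition interval), SIGMA (initial bandwidth; when
unset it is estimated from a short unbiased pre-run).

Internals the publication leaves to the method literature are documented
configuration choices here:

* **Variants.** `"explore"` builds the KDE of the *sampled* distribution
  with unit kernel weights (prefactor $(\gamma - 1)/\beta$);
  `"standard"` builds a weighted estimate of the *unbiased* distribution
  (kernel weights $e^{\beta V}$, prefactor $(1 - 1/\gamma)/\beta$).
* **Normalisation.** $Z$ is the running *maximum* of the density estimate
  over kernel centers, so the bias lies in
  $[\mathrm{pref} \cdot \log \varepsilon,\ \approx 0]$ — a clean
  realisation of the BARRIER cap. (A mean-based normalisation lets the
  explore-variant bias overshoot the cap several-fold early in a run.)
* **Floor.** $\varepsilon = e^{-\beta B / (1 - 1/\gamma)}$ (standard) or
  $e^{-\beta B/(\gamma - 1)}$ (explore).
* **Kernels.** Bandwidth shrinks with effective sample size as
  $n_{eff}^{-1/(d+4)}$ down to a configurable floor
  (`sigma_min_frac`); kernels closer than one bandwidth merge
  (moment-preserving), keeping the kernel list compact.
* **Walls.** One-sided power restraints, zero inside the limits,
  $k (s - \mathrm{limit})^2$ outside (±1.5, k = 40000 for the 1-D CV;
  ±7.5 per component for the 2-D CV).

Bias forces reach the latent coordinates by the chain rule through the
trained network and the analytic descriptor map; the compiled core
evaluates the CV, its input Jacobian, the kernel bias and the walls every
step.

**Choosing the variant per stage.** The exploration stage (1-D Deep-LDA
CV) uses the explore variant: it is the aggressive choice for flooding
basins and discovering states, and those runs are read only
qualitatively (which states, which order, how many transitions). The
quantitative stage (2-D multitask CV, reweighted to a FES) uses the
standard variant: at $\gamma = \beta B \approx 32$ the explore
reweighting raises the KDE to the power $\gamma - 1$, so a modest
density-estimate error becomes several kcal/mol of FES error, and its
$\varepsilon$ floor is of the same order as the nearly-flat well-tempered
density itself; the standard variant's KDE estimates the unbiased
distribution directly and its log-error enters the FES linearly.

**Integrator stability against the bias.** The bias curvature scales as
$\mathrm{pref}/\sigma^2$ times the squared CV Jacobian (up to ~25 in
latent units for the trained 2-D CV). Narrow adaptive kernels make the
biased dynamics stiffer than the physical landscape and the
Euler–Maruyama step then distorts sampling near saddles. The quantitative
2-D runs therefore use a fixed bandwidth of 0.25 CV units
(`sigma_min_frac = 1`), for which dt·curvature stays well below one; a
displacement clamp (10 thermal step widths) guards against residual force
spikes and its activation count is reported in the trajectory
diagnostics (zero in the default runs).

**Reweighting.** `reweight()` uses the umbrella-like final-bias
estimator, $w_t \propto e^{\beta V_{final}(s_t)}$, normalized with a
log-sum-exp guard.

## States, transitions, pathways

`assign_states()` labels frames by fixed-radius spheres (default 0.25
latent units) around the four state centers, with TRANSIT elsewhere —
deliberately independent of any trained CV so it can audit CV-driven
runs. `count_transitions()` emits a record whenever the settled end state
(PRE or POST; a state counts as entered after 10 consecutive frames)
changes, attributing the last intermediate label seen in between;
`pathway_preference()` reports the PRE-origin fraction via INT1 with an
exact binomial interval.

On pooled 1-D OPES runs the surrogate reproduces the designed mechanism:
every PRE–POST excursion passes through exactly one intermediate, and
essentially all PRE-origin transitions go via INT1 (the 7.5 vs 17.0
kcal/mol saddle asymmetry corresponds to a factor $e^{15.4}$ in crossing
probability on the unbiased transverse direction). Two regimes matter
here: a *converged* 2-D bias deliberately flattens both pathways
(BARRIER = 20 exceeds every saddle), so pathway statistics from long 2-D
runs are uninformative by design; the 1-D CV, by contrast, cannot bias
the INT1-vs-INT2 branch (it is transverse to the CV), so the preference
survives arbitrarily long runs. Mechanism statistics are therefore
collected from many short 1-D runs, which also mirrors the
transient-regime observations such counts represent in practice.

## Free energy surfaces and barriers

`estimate_fes()` bins weighted CV samples on a regular grid,
$F = -\beta^{-1} \log(\text{weighted occupancy})$, min-shifted, with
unsampled cells flagged (never zero-filled). `minimum_energy_path()`
returns the 8-connected minimax path (union-find over cells sorted by
free energy, then BFS within the threshold set) — the path that
minimises the maximum free energy crossed — and the barrier relative to
the start basin. `edge_barriers()` extracts the four designed-edge
barriers using half-plane masks along the PRE–POST diagonal (with a
one-cell band) to separate the two pathways; `barrier_errors()`
recomputes each barrier on contiguous trajectory blocks and reports the
standard error.

**Which coordinates to bin.** Reweighted samples can be binned in any
coordinate system. The FES over the learned CV space is the natural
display surface, but it represents each free energy only up to
$kT \log |J|$, the local stretch of the learned mapping; with states
pinned to width 0.2 while physical basin widths vary, this
representational term is about +1.5 kcal/mol at the lowest saddle here
(verified in development by exact quadrature of the designed landscape
pushed through the trained encoder, which agrees with the sampled
CV-space FES to ~0.3 kcal/mol). Barrier recovery is therefore audited on
the FES over the surrogate's own strand-progress coordinates — the
analogue of binning a real system's per-strand displacement metrics —
where the designed barriers are defined and the Jacobian term is absent.
The default quantitative run (6e6 steps, standard variant, fixed
bandwidth 0.25, 60x60 grid) recovers 7.3 / 14.6 / 17.0 / 10.1 against
the designed 7.5 / 15.0 / 17.0 / 10.0 kcal/mol.

## Problem sizes

The package's reference-scale settings are 20000 frames per state for the
candidate pool and desk-scale trainings of 5000 frames per state (Deep-
LDA; multitask adds 10000 reactive frames). Biased runs use 2.5e6 steps
per 1-D exploration run (16 seeds pooled for mechanism statistics) and
6e6 steps for the quantitative 2-D run. The end-to-end `run_pipeline()`
defaults are scaled further down (thousands of frames, ~1e6 steps) so a
full pass completes in about two minutes; every size is a configuration
knob.

## Known limitations

* The surrogate's descriptor noise is independent and Gaussian; real
  contact distances are correlated and skewed, so filter margins and CV
  separations here are cleaner than in practice.
* The final-bias reweighting estimator ignores the bias's early history;
  it is adequate once the bias has stopped evolving appreciably, which
  the default step budgets ensure on the surrogate, but it is not a
  time-dependent-weight estimator.
* Barriers read off a learned-CV FES include a representational
  $kT \log|J|$ term (quantified above); comparisons against physical
  coordinates should bin in those coordinates.
* The explore-variant reweighting at large biasfactors is statistically
  fragile (documented above); it is retained for exploration, not
  quantification.
* No kinetics: biased transition counts are mechanism evidence, not
  rates.
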