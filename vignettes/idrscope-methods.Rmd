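---
title: "Models and methods behind idrscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idrscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

idrscope connects three descriptions of the conformational ensembles of
intrinsically disordered regions (IDRs): single-molecule FRET
measurements analyzed at the photon level, a semi-analytical polymer
model that turns mean transfer efficiencies into distance distributions,
and a coarse-grained simulation model whose interaction parameters can
be trained against those efficiencies. Around these sit the supporting
pieces a study of sequence-ensemble relationships needs: sequence
descriptors, maximum-entropy reweighting, in-silico dye placement,
weighted-ensemble analytics, and seeded synthetic-data generators that
make every stage testable without measured data. This vignette explains
the models, the tunable parameters, and the numerical and design choices
made where the literature leaves them open.

## Sequence descriptors

Hydrophobicity is the mean Kyte–Doolittle index rescaled to [0, 1]:
$H = N^{-1}\sum_i (KD_i + 4.5)/9$. The charge descriptors use the
standard assignment D, E = −1 and K, R = +1, histidine neutral and
termini uncharged, the convention of the charge-patterning literature;
FCR $= f_+ + f_-$ and NCPR $= f_+ - f_-$ follow. The patterning
parameter $\kappa$ is the blob-based Das–Pappu statistic: the mean
squared deviation of the local charge asymmetry
$\sigma = (f_+-f_-)^2/(f_++f_-)$ in fully overlapping windows of 5 and 6
residues from its global value, normalized by the same quantity for the
most segregated arrangement of identical composition and averaged over
the two blob sizes. Two conventions are open in print and fixed here:
windows are *fully overlapping with step one*, so terminal residues
enter fewer blobs than interior ones, and the normalizing arrangement
places all positive charges first, all negative charges last, and the
neutral residues between them. SCD is
$N^{-1}\sum_{i<j} q_i q_j \sqrt{j-i}$, negative for blocky
polyampholytes. Expression-tag overhangs (GSGSC/CTLGPR) are carried as a
boolean mask: masked residues are excluded from every descriptor but the
formulas never change.

## Photon-level smFRET analysis

Bursts are maximal runs of photons whose interphoton times stay below
150 µs, kept above 50 photons, on 16-ps-resolution arrival times under
pulsed interleaved excitation. The dual-channel filter re-applies the
burst criterion separately to the donor-excitation and
acceptor-excitation photons of each burst. Because each period sees only
a thinned subset of the photons, the per-period interphoton threshold
defaults to 300 µs rather than 150 µs; the per-period photon minima (25
donor-excitation, 10 acceptor-excitation) are configuration, as the
measured values are instrument-dependent and unpublished. Treating the
burst boundaries as sentinels — the period photons must also start and
end within the threshold of the burst edges — is what rejects bursts
whose acceptor bleaches mid-transit.

Corrections are applied in the standard multiparameter order:
background rates × burst duration first, then spectral crosstalk and
direct acceptor excitation, then the $\gamma$ factor on the donor
counts. Stoichiometry $S = n_{tot,Dex}/(n_{tot,Dex}+n_{tot,Aex})$ is
computed from corrected totals and bursts outside the *open* interval
$0.2 < S < 0.8$ are flagged; transfer efficiency is
$E = n_A/(n_A + n_D)$ from the corrected counts. Bursts whose corrected
denominators become non-positive are flagged invalid rather than
dropped, so correction pathologies stay visible. Efficiency histograms
use 0.02-wide bins on $E \in [-0.1, 1.1]$ and are fit with Gaussian
mixtures by Levenberg–Marquardt least squares seeded from the histogram
modes.

## The SAW-ν model

The end-to-end distance density of a chain with scaling exponent $\nu$
and rms end-to-end distance $R$ is, in reduced units $x = r/R$,
$P(x) = A\,x^{2+g}\exp(-\alpha x^{\delta})$ with $g = (\gamma-1)/\nu$
($\gamma = 1.1615$), $\delta = 1/(1-\nu)$, and $A$, $\alpha$ fixed
analytically (via Gamma functions) by normalization and
$\langle x^2\rangle = 1$. Mean efficiencies integrate
$P(r)/(1+(r/R_0)^6)$ by adaptive quadrature (relative tolerance
1e-10; verified in the tests against a 10^6-draw sampling oracle).
Inversion solves the one-dimensional self-consistency problem for
$\nu$ with $R = b\,N_{\mathrm{eff}}^{\nu}$: the mean efficiency is
strictly decreasing in $\nu$, so root bracketing on
$\nu \in [1/3, 0.95]$ gives a unique solution, refined to 1e-6 in
efficiency. Above $\nu = 0.95$ the stretching exponent $\delta$
diverges and the model is rejected.

The effective segment count is a convention: the 57-residue constructs
carry their dyes on cysteines spanning 59 residues, and the dye linkers
contribute ≈9 equivalent segments, giving $N_{\mathrm{eff}} = 68$ with
prefactor $b = 0.55$ nm. Both are configuration parameters recorded in
the fit object. The inversion's sensitivity to this convention is mild —
a ±5 % change in $N_{\mathrm{eff}}$ moves $R$ by roughly ±1.5 % at fixed
efficiency — but the convention matters when comparing absolute
distances across studies.

## The coarse-grained HPS model

Each residue is one bead with a diameter from the average-volume set,
the residue charge, and a stickiness $\lambda$. Pairs interact through
the Ashbaugh–Hatch form: with $\lambda_{ij}$, $\sigma_{ij}$ arithmetic
means and $\Phi_{LJ}$ the 12-6 potential at well depth $\epsilon$,
$U = \Phi_{LJ} + (1-\lambda_{ij})\epsilon$ inside the minimum
$2^{1/6}\sigma_{ij}$ and $\lambda_{ij}\Phi_{LJ}$ outside, plus a
Debye–Hückel term screened at the ionic strength's Debye length.
Numerical settings: $\epsilon = 0.8368$ kJ/mol (0.2 kcal/mol, the HPS
lineage value, configurable), short-range cutoff 2.0 nm, electrostatic
cutoff 3.5 nm, $\epsilon_r = 80$, bonded 1–2 pairs excluded from
nonbonded terms. Bonds are harmonic, $U = (k/2)(r-r_0)^2$ with
$r_0 = 0.38$ nm and $k = 481.4$ kJ nm⁻² mol⁻¹ — the spring-constant
convention is fixed by requiring the bond-length variance
$k_B T/k$, which the tests check against exact quadrature of the
Boltzmann distribution.

Dyes are small bead trees: three linker beads and a four-bead
chromophore core with one branch point, attached at the labeling
cysteines. Published information fixes the bead roles (negative,
neutral, positive, linker), the net charges (Alexa 488/594: −2, Cy3B:
0, CF660R: −1), the 100 amu bead mass, and that harmonic angle terms
($k = 48.14$ kJ rad⁻² mol⁻¹, $\pi/2$ at branch points, $\pi$
elsewhere) act only on chromophore beads, never on linkers. The exact
bead counts and geometry are not published; the shipped specifications
are editable YAML and are declared approximations. The FRET distance is
measured between each dye's declared center bead.

Dynamics uses the BAOAB splitting of Langevin dynamics at 300 K, 10 fs
time step, friction 1.0 ps⁻¹, with a deterministic counter-based RNG so
equal seeds give bit-identical trajectories on any platform. Before
dynamics a displacement-capped steepest descent (500 steps, cap 0.01 nm)
relaxes overlaps in the generated starting structure. A configurable
fraction of each run (default 1/6, mirroring 100 ns of 600 ns) is
discarded as equilibration. Equilibrium averages do not depend on the
friction coefficient, so property tests that need decorrelated samples
run at lower friction (0.2–0.5 ps⁻¹) to reach effective sample sizes
faster; protocol-level checks (equipartition) keep 1.0 ps⁻¹.

Test and acceptance runs use reduced problem sizes chosen once: the
excluded-volume scaling check uses a 40-bead λ = 0 chain for 160 ns
(internal-scaling fit window $|i-j| \in [5, 35]$) — long enough that
the apparent exponent's seed-to-seed spread is well inside the ±0.03
band, short enough to run on one CPU in minutes; force-balance recovery
uses three 20-bead constructs at 12 ns per iteration. Finite chain
length biases apparent exponents upward (chain ends are locally more
expanded), which is why the fit window and chain length are stated with
the result.

## Force-balance optimization

The mismatch loss is
$\sum_c (\langle E\rangle_c - E^{exp}_c)^2 +
\alpha\sum_k(\lambda_k - \lambda^0_k)^2$ with L2 regularization anchored
at the starting parameters ($\alpha = 10^{-4}$, learning rate
$\eta = 5.0$ by default; at the reduced test scale $\eta = 3$ matches
the larger gradients of short chains). Gradients come
from linear response on the stored frames:
$\partial\langle E\rangle/\partial\lambda_k =
-\beta(\langle E u_k\rangle - \langle E\rangle\langle u_k\rangle)$ with
$u_k$ the per-frame derivative of the total potential with respect to
$\lambda_k$ ($-\epsilon$ inside the crossover, $\Phi_{LJ}$ outside,
half-shared between the two pair partners). The update equations are
not published; this covariance estimator is the natural one for the
cited optimization family and the tests validate it against exponential
reweighting of the same frames at $\lambda \pm \delta$. Each iteration
re-simulates every construct, so the per-iteration mean efficiencies
are stochastic; the optimizer halves $\eta$ after two consecutive loss
increases (aborting at a floor), stops on a loss plateau or the
iteration cap, and reports both the final $\lambda$ and a three-iteration
tail average that damps the stochastic-gradient noise. Dye and residue
$\lambda$ live in one vector with a freeze mask; initial dye values can
come from a coarse grid search over (chromophore, linker) pairs.

## Maximum-entropy reweighting

Given per-frame efficiencies and a measured mean with error, the
posterior weights $w_i \propto w^0_i e^{-\theta E_i}$ minimize the KL
divergence to the prior subject to the constraint. The measurement
error is treated as an inequality relaxation: if the prior mean is
already within the error, $\theta = 0$; otherwise the constraint is
solved to the *nearer edge* of the tolerance band, which is the
minimum-divergence feasible point. $\theta$ is found by bracketed root
finding on the (strictly monotone) reweighted mean with log-sum-exp
guards; weights below 1e-12 are floored and renormalized. When several
simulation replicas exist they are concatenated and reweighted jointly —
whether the published implementation solved per replica or globally is
not stated, and joint solution is the assumption made here. Ensembles
whose reweighting exceeds $D_{KL} = 0.1$ nats are flagged, mirroring
the practice of restricting downstream interpretation to mildly
perturbed ensembles.

## Dye placement on ensembles

For atomistic (or pseudo-atomistic) frames, rotamers are drawn with
replacement from a library (50 trials per site), placed with ideal
γ-sulfur geometry along the Cβ–Sγ axis, and rejected if any dye atom
comes within 5 Å of a protein atom outside the attachment residue.
Frames where both sites reach 20 accepted placements contribute all
mutually non-clashing cross pairs; the same 5 Å radius is reused for the
pair stage, since only one radius is published. Distances are measured
between declared dye-center atoms. The shipped rotamer set is synthetic
(random bent chains, labeled as such); a measured library in the same
local-frame format can be substituted. Trials use sampling with
replacement — the published description does not say, and with
replacement keeps acceptance statistics independent of library size.

## Ensemble analytics

Internal scaling profiles average RMS distances in the published order:
the inner average is $\langle r_{ij}^2\rangle^{1/2}$ over conformations
(weighted by posterior weights when given), the outer average runs over
all pairs at each separation. The homopolymer fit
$A_0|i-j|^{\nu}$ uses nonlinear least squares over a window defaulting
to $|i-j| \in [5, N-5]$; scaled distance maps divide each weighted RMS
distance by that fit, masking separations below 10. Whether the
published maps fit the weighted or unweighted profile is not stated;
weighted is the default here with unweighted available by passing
uniform weights. Contact maps count weighted frames whose minimum
site-site distance is below 10 Å (bead distance for one-site-per-residue
models, closest-heavy via the site-to-residue mapping otherwise), and
contact networks draw edges at ≥35 % of the per-chain maximum contact
probability, excluding $|i-j| \le 2$, with the residue-class color
scheme carried as vertex metadata. Shape metrics come from gyration
tensor eigenvalues; SAXS curves use the Debye formula with unit form
factors — only $I(q)/I(0)$ is compared, normalized at the simulation's
$q = 0$ value — and the Guinier fit iterates the $qR_g \le 1$ window.
Regression tooling fits every 1–3-feature OLS combination, reports
$\rho^2$, leave-one-out distributions, and Lin's concordance
$\rho_c = 2\,\mathrm{cov}(x,y)/(\sigma_x^2+\sigma_y^2+(\bar x-\bar y)^2)$
with population moments.

## Synthetic data: what it does and does not emulate

The generators are first-class, seeded, and emit truth attributes.
Sequences are composition-constrained draws over a neutral pool
excluding Trp (dye quenching) and Cys (reserved for labeling), with
charge counts set by FCR/NCPR and κ tuned into a requested band by
accept/reject swaps; integer rounding at N = 57 bounds the achievable
target accuracy at about ±0.02. Ensembles are Gaussian chains (bond
variance $b^2/3$ per axis, so $\langle R^2\rangle = (N-1)b^2$ exactly,
with $b = 0.38$ nm matching the CG bond length) or rigid rods. Photon
streams plant Poisson bursts with exponential interphoton times, a
floor on inter-burst gaps (so the planted burst count is recoverable
exactly), binomial acceptor counts at
$p = E + (1-E)\,ct$, direct-excitation leakage, and uniform background;
the emitted truth includes the correction set that exactly undoes the
corruption ($lk = ct/(1-ct)$, $\gamma = 1/(1-ct)$).

What passing tests show, therefore, is that every algorithm is correct
against its generative model and its closed-form or brute-force oracle.
What they cannot show is robustness to what real data adds: dye
photophysics beyond a single crosstalk coefficient, heteropolymeric
ensembles outside the Gaussian/rod/HPS families, conformational
exchange during bursts, and atomistic packing in dye placement.

## Known limitations

The dye geometries are approximations of unpublished structures; the
CG simulator is a single-CPU O(N²) implementation intended for the
50–100-bead regime, not for proteome-scale scans; force-balance
gradients are linear-response estimates whose accuracy degrades for
large parameter steps; and the regression utilities assume complete
feature tables (κ is undefined below two charges and must be imputed by
the caller).
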