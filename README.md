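# idrscope

Tools for studying how amino-acid sequence controls the chain dimensions
of intrinsically disordered protein regions (IDRs), written for
structural biophysicists who combine single-molecule FRET with polymer
theory and coarse-grained simulation.

The package covers the full arc of such a study:

- **Sequence descriptors** (`sequence_features()`): normalized
  Kyte–Doolittle hydrophobicity, fraction of charged residues (FCR), net
  charge per residue (NCPR), the Das–Pappu charge-patterning parameter κ,
  sequence charge decoration SCD = N⁻¹ Σ_{i<j} qᵢqⱼ√(j−i), and per-residue
  / group composition fractions, with overhang masking and FASTA I/O.
- **Photon-level smFRET analysis** (`find_bursts()`,
  `dual_channel_filter()`, `correct_and_score()`, `fit_histogram()`):
  burst search on interphoton times (< 150 µs, ≥ 50 photons),
  dual-channel filtering under pulsed interleaved excitation, background
  / crosstalk / direct-excitation / γ corrections, stoichiometry
  filtering (0.2 < S < 0.8), and Gaussian peak fits of efficiency
  histograms.
- **SAW-ν polymer inversion** (`saw_fit()`): the self-avoiding-walk-based
  end-to-end distance density
  P(x) ∝ x^{2+g} exp(−αx^δ), g = (γ−1)/ν, δ = 1/(1−ν), normalized so
  ⟨x²⟩ = 1, inverted so that ⟨E⟩ = ∫P(r)(1+(r/R₀)⁶)⁻¹dr matches a
  measured mean transfer efficiency with R = b·N_eff^ν.
- **Coarse-grained HPS simulation** (`build_topology()`,
  `run_langevin()`): one bead per residue with stickiness λ
  (Ashbaugh–Hatch potential) plus Debye–Hückel electrostatics, explicit
  multi-bead FRET dyes with branch-point angle terms, BAOAB Langevin
  dynamics (compiled core), bit-reproducible under a seed.
- **Force-balance training** (`force_balance()`): gradient descent on the
  λ vector against measured mean efficiencies, gradients by linear
  response −β(⟨Eu_k⟩−⟨E⟩⟨u_k⟩), L2 starting-point regularization,
  learning-rate adaptation, freeze masks, dye/linker grid search.
- **Maximum-entropy reweighting** (`maxent()`): minimal-KL posterior
  weights w ∝ w⁰e^{−θE} matching a measured mean within its error, with
  Kullback–Leibler diagnostics and a 0.1-nat flagging cutoff.
- **Dye placement** (`attach_dyes()`): rotamer-library attachment with
  5 Å clash rejection and per-frame Förster efficiencies (R₀ = 6 nm).
- **Ensemble analytics** (`internal_scaling()`, `scaled_distance_map()`,
  `contact_map()`, `contact_network()`, `shape_metrics()`,
  `saxs_profile()`, `regression_suite()`): weighted internal scaling with
  homopolymer fits ⟨R_{i,j}⟩ = A₀|i−j|^ν, scaled distance maps, contact
  maps/networks, gyration-tensor shape metrics, Debye-formula SAXS
  profiles, and OLS/leave-one-out/Lin-concordance statistics.
- **Synthetic data** (`gen_sequences()`, `gen_ensemble()`,
  `gen_photons()`, `gen_rotamer_library()`): seeded generators with truth
  sidecars for every input class.

## Worked example

Invert a measured mean transfer efficiency into a distance distribution:

```r
library(idrscope)

fit <- saw_fit(E = 0.4, R0 = 6.0, N_eff = 68, b = 0.55)
fit
#> SAW-nu inversion of mean transfer efficiency
#>   <E> = 0.4000 (R0 = 6.00 nm, N_eff = 68, b = 0.550 nm)
#>   nu  = 0.6189
#>   R   = 7.492 nm (rms end-to-end)
```

So a chain reporting ⟨E⟩ = 0.4 with this dye pair behaves like an
excluded-volume coil (ν ≈ 0.62) with a root-mean-squared end-to-end
distance of ≈ 7.5 nm; `predict(fit, type = "efficiency")` returns 0.4,
closing the round trip, and `saw_distance_table(fit)` tabulates P(r).
The same call with ⟨E⟩ = 0.9 gives ν = 0.4507 and R = 3.683 nm — a chain
near effective theta conditions, almost half the size at identical
length.

Reweight a simulated ensemble to a measurement and inspect the
perturbation:

```r
ens <- gen_ensemble(5000, n_residues = 60, seed = 1)
ree <- sqrt(rowSums((ens$coords[, 60, ] - ens$coords[, 1, ])^2))
E_frame <- 1 / (1 + (ree / 6)^6)
fit <- maxent(E_frame, target = mean(E_frame) + 0.03)
fit$kl        # nats of reweighting needed
flag_high_divergence(list(myidr = fit))  # <= 0.1: mild perturbation
```

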