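# pamscope

Statistical analysis of PAM recognition dynamics in Cas9 molecular
simulations.

CRISPR-Cas9 reads the protospacer adjacent motif (PAM) through an
arginine dyad (R1333/R1335) in its PAM-interacting domain, and engineered
variants with broader PAM compatibility appear to work by tuning the
*flexibility* of those arginines rather than by changing their direct
contacts. Quantifying that claim from molecular-dynamics output takes a
specific analysis stack, and `pamscope` implements it as a reusable R
toolkit for simulators and structural bioinformaticians:

- **Contact statistics** (`contacts`): arginine-DNA contacts classified by
  a dual criterion - COM distance below 0.6 nm (base) / 0.5 nm (phosphate)
  *and* attractive interaction energy of at least 100 / 350 kJ/mol - with
  a 5% pooled-proximity candidate filter. Interaction frequencies are
  treated as Bernoulli variables; the error of the mean uses the number of
  effective samples `n_eff = T_total / tau`, with
  `tau = dt (1 + 2 sum_k rho(k))` the integrated autocorrelation time of
  the interaction-energy series (largest across replicates), so
  `stderr = sqrt(p (1 - p) / n_eff)`.
- **Hydrogen bonds** (`hbonds`): geometric detection (donor-acceptor
  distance <= 3.5 A, hydrogen-donor-acceptor angle <= 30 deg), per-category
  frequencies and their normalisation, and the specificity index
  `(f_PAM + eps) / (f_nonPAM + eps)`.
- **Flexibility and entropy** (`flex_entropy`): mass-weighted
  superposition, RMSF profiles, fluctuation covariances, and
  quasi-harmonic conformational entropy from the eigenvalues
  `lambda_i` of the mass-weighted covariance:
  `omega_i = sqrt(kB T / lambda_i)` and
  `S = R sum_i [a_i/(e^{a_i}-1) - ln(1-e^{-a_i})]`, `a_i = hbar omega_i / kB T`.
- **Well-tempered metadynamics** (`metadynamics`): the history-dependent
  bias `V(s,t) = sum_hills w tG e^{-V/(kB dT)} e^{-sum_i (s_i-c_i)^2/2 sigma_i^2}`,
  free-energy recovery `F(s) = -(T+dT)/dT V(s)` min-shifted to zero,
  one-sided harmonic walls, HILLS text I/O, and a compiled Langevin
  multi-walker toy engine used to validate the reconstruction against
  quadrature oracles.
- **Alchemical free energies** (`alchemy`): a multistate Bennett
  acceptance ratio (MBAR) solver (self-consistent iteration plus Newton
  polish, asymptotic covariance errors), Metropolis exchange-acceptance
  estimation, gradient-descent optimization of the lambda schedule toward
  equalized neighbour acceptance with a >= 10% floor, the thermodynamic
  cycle `ddG = dG_m2 - dG_m1` with quadrature errors, and per-residue
  enthalpic decomposition `dE = <E>_1 - <E>_0` with five-block errors.
- **Structure comparison** (`struct_compare`): domain COM distances
  (REC3 498-718, HNH 775-908 by default), Kabsch superposition RMSD,
  two-tailed Z tests on effective sample sizes, kernel densities.
- **Synthetic data** (`synthetic`): every input class with known ground
  truth - two-state Markov contact dynamics, harmonic positional
  ensembles, donor-hydrogen-acceptor geometries, harmonic-oscillator
  alchemical states with closed-form dG, Langevin trajectories on
  analytic potentials - so the whole pipeline is testable at desk scale.

## Worked example

A synthetic arginine-base contact with 30% true occupancy and a 10 ps
correlation time, pushed through the full contact pipeline:

```r
library(pamscope)

spec <- markov_contact_spec(p_on = 0.3, tau = 10, dt = 1,
                            n_frames = 20000, seed = 42)
sim <- gen_markov_contact(spec)
d <- com_distance_series(sim$trajectory,
                         atom_group(0, "R1335 guanidinium"),
                         atom_group(1, "G3 base"))
occ <- classify_contacts(d, sim$energy$values, contact_criteria(),
                         kind = "base")
frequency_with_error(occ, sim$energy$values, dt = 1)
#> FrequencyEstimate: mean 0.3092 +/- 0.0156 (tau 22.74 ps, n_eff 879, 1 replicate)
```

The estimate brackets the true occupancy of 0.3, and the error bar
reflects that 20,000 correlated frames are worth only ~880 independent
ones. The same style of closed-loop validation works for the free-energy
machinery:

```r
g <- gen_alchemical_harmonics(c(1, 4), n_per_state = 10000, seed = 42)
mbar_free_energies(g$u, temperature = 300)
#> FreeEnergyResult (relative to state 1):
#>   state  1:   0.0000 +/- 0.0000 kT
#>   state  2:   0.7007 +/- 0.0068 kT
```

against the exact `0.5 ln 4 = 0.6931 kT`.

Stages can also be driven from YAML configurations via `run_stage()` or
the `inst/cli/pamscope` script; see `?run_stage`.

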