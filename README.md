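# apichap

Analysis toolkit for studying how isolated chaperonin (CCT/TRiC) apical
domains inhibit aggregation of the tau 4R (K18) fragment. The package
covers both halves of that analysis:

* **Aggregation kinetics** — ThT plate-reader time courses: replicate
  averaging, heparin-free control subtraction, min-max normalisation,
  fitting of a sigmoidal transition between two straight lines, Z-test
  comparison of half-times, double-logarithmic half-time-vs-concentration
  scaling, and forward simulation + global fitting of moment-equation
  aggregation mechanisms (nucleation-elongation, secondary nucleation,
  fragmentation, saturating elongation + fragmentation) with
  model selection by mean residual error (MRE).
* **Coarse-grained simulation** — C-alpha-bead Langevin dynamics of a
  folded apical domain (native-topology 12-10 contacts, harmonic
  bonds/angles, cosine dihedrals) plus a disordered tau chain (bonds
  only), with Debye-Hückel electrostatics and hydrophobicity-scaled
  attraction; trajectories are reduced to residue-residue interaction
  probability heat maps (3-residue bins) and contiguous tau binding
  segments.
* **Synthetic data** — generators for every input: sigmoid plates with
  Gaussian noise and ground-truth sidecars, mechanism concentration
  series, C-alpha-only PDB mini-domains with hand-countable contacts, and
  charged disordered sequences (the canonical tau 244-372 construct ships
  as a built-in).

## Core models

Time courses are fitted with

    F(t) = (m1*t + n1) * (1 - L) + (m2*t + n2) * L,
    L(t) = 1 / (1 + exp(k * (t05 - t)))

(`m1, n1` pre-transition baseline; `m2, n2` post-transition; `t05`
half-time in h; `k` transition steepness in 1/h). Mechanisms are the
two-moment equations `dP/dt = kn*m^nc [+ k2*m^n2*M | + kminus*M]`,
`dM/dt = 2*kplus*m*P [/(1 + m/KS)]` with `m = m0 - M`, integrated by an
adaptive Runge-Kutta 4(5); half-time scaling exponents follow the
standard theory (-nc/2, -(n2+1)/2, -1/2, → 0).

## Worked example

```r
library(apichap)

## fit a noise-free curve generated with the tau-alone parameters
t <- seq(0, 24, by = 5/60)
curve <- averaged_curve(t, eval_sigmoid(t, 0, 0, 0, 1, 1.79, 4.41))
fit_sigmoid(curve)
#> <sigmoid_fit> t05 = 4.41 +/- 6e-10 h, k = 1.79 +/- 1.2e-09 1/h (1/k = 0.5587 h)
#>   baselines: pre -1.82e-09*t + 2.26e-09, post 2.01e-11*t + 1; rmse 4.88e-10; converged

## half-times 4.41 +/- 0.02 h vs 11.22 +/- 0.05 h are very different
z <- compare_halftimes(list(t05 = 4.41, se = c(t05 = 0.02), converged = TRUE),
                       list(t05 = 11.22, se = c(t05 = 0.05), converged = TRUE))
sprintf("Z = %.1f, log10(p) = %.1f", z$Z, z$log10_p)
#> "Z = 126.5, log10(p) = -3474.8"

## fragmentation-mechanism scaling: slope ~ -1/2
m <- kinetic_model("fragmentation", kn = 1e-18, kplus = 80, kminus = 0.01)
tt <- seq(0, 48, by = 0.02)
m0s <- c(2.5, 5, 10, 20, 40)   # uM
t05 <- sapply(m0s, function(m0)
  numeric_halftime(tt, simulate_model(m, m0, tt, atol = 1e-30), target = 0.5))
round(t05, 2)
#> 18.18 12.61  8.75  6.06  4.20
halftime_scaling(m0s, t05)
#> <scaling_fit> slope = -0.529 +/- 0.000, r^2 = 1.0000 (n = 5)
```

The fitted half-time and steepness reproduce the generating values; the
Z statistic shows the half-time shift caused by 7 µM apiCCT3 is far
beyond chance; and forward-simulated fragmentation kinetics display the
−1/2 half-time scaling that identifies the mechanism.

## Command line

```sh
apichap synth plate --out plate/ --noise 0.02 --replicates 12 --seed 1
apichap kinetics fit --plate plate/plate.csv --meta plate/meta.csv --out fits.csv
apichap kinetics scaling --fits fits.csv --out scaling.csv
apichap synth series --model fragmentation --noise 0.01 --out curves.csv
apichap mech compare --curves curves.csv --out mre.csv
apichap synth domain --n 24 --geometry helix_hairpin --out domain.pdb
apichap synth idp --length 20 --charge 2 --out idp.fasta
apichap cg run --structure domain.pdb --idp idp.fasta --steps 100000 \
    --replicas 2 --seed 7 --box 80 --out runs/
apichap contacts --trajs runs/ --cutoff 6 --bin 3 --out heatmap.tsv \
    --segments segs.bed --threshold 0.2
```

(`apichap` = the `exec/apichap` script, or
`Rscript -e 'apichap::apichap_main()' <args>`.)

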