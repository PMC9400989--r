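# ufdexsy

Simulation and analysis of **ultrafast diffusion exchange spectroscopy
(UF DEXSY)** on single-sided, constant-gradient NMR instruments.

## The problem

DEXSY correlates a molecule's diffusion coefficient before and after a
mixing time τ<sub>M</sub>: molecules that change diffusion environment
during τ<sub>M</sub> show up as off-diagonal (cross) peaks of a 2D
exchange map. On a single-sided magnet the built-in strong constant
gradient (here 7.28 T m⁻¹ at 0.3 T) supplies the diffusion contrast, and a
frequency-swept chirp pulse spatially encodes the indirect dimension into
~300 μm of sample depth, so the whole 2D experiment fits into a single
scan — fast enough to use a hyperpolarized (dDNP) sample. The price is
that the raw data are shaped by strongly position-dependent coil
sensitivity, chirp-edge artefacts, and diffusive mixing of the encoded
layers during τ<sub>M</sub>, so the exchange map cannot be read off the
raw matrix; it must be recovered through a forward model.

`ufdexsy` implements that forward model and its inversion for two-site
exchange (e.g. intra- and extracellular water in a cell suspension):

1. **Encoding** — stimulated-echo spatial encoding with a depth-linear
   effective pulse length δ(z) = δ<sub>max</sub> z/L, giving a
   Stejskal–Tanner weighting
   b(z) = (2πγ̄)² G² δ(z)² (Δ − δ(z)/3)
   per depth, modulated by the coil profile C(z) and two Gaussian
   chirp-edge drops.
2. **Mixing** — joint evolution over (start site, current site) of the
   encoded magnetization: first-order two-site exchange with rate matrix
   eigenvalue −k, free-diffusion blurring of the layers (spectral
   propagator, exact for any step), and inflow of unencoded magnetization
   across the region boundary.
3. **Readout** — single-scan CPMG under the constant gradient; echo n is
   attenuated by exp(−n[(2πγ̄)²G²t<sub>E</sub>³D/12 + t<sub>E</sub>/T₂]),
   which pins the post-mixing diffusivity of each magnetization fraction.
4. **Inversion** — nonnegative least squares of the raw matrix onto four
   fixed-diffusivity basis surfaces (start site × end site), normalized to
   a 2×2 exchange map per mixing time.
5. **Kinetics** — fit of the two-site model
   I<sub>jj</sub>(τ) = p<sub>j</sub>(p<sub>j</sub> + (1−p<sub>j</sub>)e^(−kτ)),
   I<sub>jk</sub>(τ) = p<sub>j</sub>p<sub>k</sub>(1−e^(−kτ))
   across mixing times, yielding k, p<sub>intra</sub>, the site rates
   k<sub>intra</sub> = p<sub>intra</sub>k, k<sub>extra</sub> =
   (1−p<sub>intra</sub>)k, and the intracellular lifetime
   τ<sub>intra</sub> = 1/k<sub>intra</sub>.

A seeded synthetic-data generator plays the role of the experiment: it
produces noisy raw matrices (SNR ≈ 280, fresh hyperpolarization amplitude
per mixing time) with known ground truth, so the whole pipeline can be
validated closed-loop.

## Worked example

```r
library(ufdexsy)

scn <- read_config(system.file("extdata", "yeast_suspension.cfg", package = "ufdexsy"))
ds  <- generate_dataset(scn, master_seed = 1L)   # 3 noisy raw matrices
an  <- analyze_dataset(ds)                       # invert + kinetics fit
an$maps[[3]]
an$fit
```

```
Exchange map at tau_M = 100 ms (residual 0.41):
     end
start      1      2
    1 0.1020 0.1383
    2 0.1389 0.6208
Two-site exchange fit:
  k       =     14 +- 0.1 /s
  p_intra =  0.241 +- 0.00048
  k_intra =   3.37 +- 0.024 /s, k_extra =   10.7 +- 0.081 /s
  tau_intra = 0.296 +- 0.0021 s
  3 mixing times, residual sum of squares 1.37e-05
```

The map shows that after 100 ms about 28% of the signal sits in the cross
peaks (equal within noise, as detailed balance requires), and the fit
recovers the generating truth (k = 14 s⁻¹, p_intra = 0.24): an
intracellular residence time of roughly 0.3 s.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/ufdexsy.R simulate --config inst/extdata/yeast_suspension.cfg --seed 1 --out run1
Rscript inst/cli/ufdexsy.R invert   --config inst/extdata/yeast_suspension.cfg --out run1/maps.tsv run1/raw_*.dat
Rscript inst/cli/ufdexsy.R kinetics --out run1/fit.txt run1/maps.tsv
```

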