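---
title: "Apparent pKa of ionizable lipids from umbrella-sampling free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apparent pKa of ionizable lipids from umbrella-sampling free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnpka)
```

## The problem

Lipid nanoparticles (LNPs) deliver mRNA and siRNA into cells by exploiting a
pH switch: their ionizable lipid (IL) is near-neutral in circulation and
becomes protonated in the acidifying endosome, destabilising the endosomal
membrane. The property that controls this switch is not the IL's
bulk-solution pKa (pKa^S, typically 8.5–9.5 for the amines involved) but its
*apparent* pKa in the formulated particle (pKa^A, empirically ~6–7). The gap
arises because the neutral form of the lipid partitions into the bilayer
interior far more favourably than the charged form, which stays anchored at
the headgroup interface.

`lnpka` implements the free-energy route to that shift. Given potentials of
mean force (PMFs) $W_+(z)$ and $W_0(z)$ for the protonated and neutral
lipid along the bilayer normal $z$ (distance of the amine nitrogen from the
bilayer center), the shift is a ratio of Boltzmann averages over the
membrane region,

$$
\Delta \mathrm{p}K_a \;=\; \log_{10}
\frac{\left\langle e^{-W_+(z)/k_BT} \right\rangle_{z\in[0,z_{hi}]}}
     {\left\langle e^{-W_0(z)/k_BT} \right\rangle_{z\in[0,z_{hi}]}},
\qquad
\mathrm{p}K_a^A \;=\; \mathrm{p}K_a^S + \Delta \mathrm{p}K_a ,
$$

with $\langle\cdot\rangle$ an unweighted arithmetic mean over uniformly
spaced bins from the bilayer center ($z=0$) to the point $z_{hi}$ where the
PMF has reached its bulk plateau. Because $z$ is a straight-line coordinate
normal to a planar bilayer, no radial ($4\pi r^2$) volume weighting applies.
When the neutral form binds more strongly ($W_0 < W_+$ over the membrane),
the denominator dominates and $\Delta \mathrm{p}K_a < 0$: the formulated
lipid is a weaker acid—base couple than in water, exactly the behaviour LNP
formulators rely on.

The sign and form of the expression are pinned by three constraints: a
uniform offset $W_+ = W_0 + c$ must reduce to the standard
thermodynamic-cycle result $\Delta \mathrm{p}K_a = -c/(k_BT\ln 10)$;
stronger neutral binding must give a negative shift; and the shift is
invariant when the same constant is added to both PMFs.

## From biased trajectories to PMFs

PMFs come from umbrella sampling: a ladder of windows along $z$, each with a
harmonic restraint $U_i(z) = \tfrac12 k_\parallel (z-z_i)^2$ on the amine
nitrogen. The defaults mirror the standard membrane protocol: windows every
1.0 Å from −2 Å to 50 Å (to 55 Å for systems whose PMFs flatten later),
$k_\parallel = 2.0$ kcal mol⁻¹ Å⁻², T = 310.15 K, 100 ns of sampling per
window of which the first 30 ns are discarded as equilibration. The force
constant is interpreted with the $\tfrac12 k$ convention common to MD
restraint implementations; a `half_factor = FALSE` plan flag switches to the
$k x^2$ convention for engines that use it, and the choice cancels in every
self-consistency test because the sampler and the estimator always share
one convention.

`solve_wham()` recombines the window histograms (0.2 Å bins, left-closed,
anchored at the lower range edge) by plain self-consistent WHAM iteration:

$$
p(b) = \frac{\sum_i n_i(b)}{\sum_i N_i\, e^{(F_i - U_i(z_b))/k_BT}},
\qquad
F_i = -k_BT \ln \sum_b p(b)\, e^{-U_i(z_b)/k_BT},
$$

iterated until $\max_i |\Delta F_i| \le$ `tolerance` (default
$10^{-7}$ kcal/mol, cap $10^5$ iterations), with $F$ pinned to the first
window and $W(z_b) = -k_BT \ln p(b)$ reported up to that additive constant.
Deliberate numerical choices:

* **Bias at bin centers.** $U_i$ is evaluated at the bin center rather than
  integrated across the bin; at 0.2 Å resolution the difference is far below
  the statistical noise, and this matches common WHAM practice.
* **Empty bins stay undefined.** A bin with no counts yields `NA`, never a
  $\pm\infty$ sentinel and never an interpolated value; smoothing skips
  undefined neighbours and the shift integral refuses to run if its range
  contains one. Silent interpolation would fabricate free energies.
* **No statistical-inefficiency weighting.** Windows enter with their raw
  counts. Correlated samples therefore do not bias the PMF (the stationary
  density is unchanged) but error bars must come from replicates, which is
  how the package reports uncertainty.
* **Plain deterministic iteration.** No acceleration, no randomness:
  identical inputs give bit-identical results.

`window_overlap()` computes the shared probability mass
$\sum_b \min(\hat p_i(b), \hat p_{i+1}(b))$ of adjacent windows and flags
pairs below 0.03 — the standard sanity check that the ladder is actually
stitched together.

Post-processing follows the protocol order: an 11-bin centered moving
average first, then a shift placing the bulk tail at 0 kcal/mol. "Bulk" is
quantified as `tail_start`, defaulting to 5 Å short of the profile end; all
supported systems are flat there by construction of their cutoffs. At the
profile edges the smoothing window shrinks symmetrically to the largest odd
width that fits (a `truncate` policy is available); the edge policy is a
free choice the protocol leaves open, and the shrinking variant preserves
linear trends at the boundary. Replicate averaging (`average_replicates()`)
takes the per-bin mean and defines a bin only where every replicate defines
it.

Per-system integration cutoffs $z_{hi}$ follow the reference protocol:
45.5 Å (ALC-0315), 49 Å (Lipid A), 52 Å (MC3), 40 Å (SM-102).
`suggest_bulk_cutoff()` automates the choice (first bin after which
$|W| < 0.1$ kcal/mol for the rest of the profile) but never overrides an
explicit value. Windows below $z = 0$ inform the WHAM solution — they
improve the PMF near the bilayer center — but the shift average starts at
0 by definition of the membrane region.

Two reporting paths exist for the final number: the mean of per-replicate
$\Delta \mathrm{p}K_a$ values, and the $\Delta \mathrm{p}K_a$ of the
replicate-averaged PMF. The reference description is ambiguous about which
it reports, so `run_pipeline()` computes per-replicate shifts (and their
sample standard deviation, $n-1$ denominator) as the primary result, while
`average_replicates()` serves the averaged-PMF path; for well-sampled
systems the two agree within the replicate spread.

## The synthetic sampler: what it emulates and what it does not

Validating the estimator stack needs data with known ground truth, which MD
cannot provide at desk scale. `generate_dataset()` therefore samples the
*same* biased-window structure from analytic membrane-like PMFs using
overdamped (Brownian) Langevin dynamics,

$$
z_{t+\mathrm{d}t} = z_t - \frac{D_c\,\mathrm{d}t}{k_BT}
\frac{\mathrm{d}(W+U_i)}{\mathrm{d}z} + \sqrt{2 D_c\,\mathrm{d}t}\;\xi,
\qquad \xi \sim \mathcal N(0,1),
$$

with the gradient by central difference ($h = 10^{-4}$ Å) and reflecting
walls 2 Å outside the plan range. The test target is the estimator stack —
histogramming, WHAM, post-processing, the shift integral — not membrane
physics, so a 1-D stochastic process whose stationary density is *exactly*
$\propto e^{-(W+U_i)/k_BT}$ is the right stand-in: any systematic deviation
the pipeline shows against the manifest's true shift is the pipeline's own.

The analytic shapes mimic the qualitative structure of IL PMFs: the neutral
form a broad, deep interior well ($W(z) = -D/(1+e^{(|z|-z_m)/w})$, depths
8–10 kcal/mol spanning the bilayer interior), the charged form an
interfacial minimum 4–6 kcal/mol deep at $z_0 \in [18, 28]$ Å whose
interior penalty rises to or above the bulk level at the center
($W(z) = -A e^{-(|z|-z_0)^2/2\sigma^2} + B e^{-z^2/2\sigma_b^2}$). The
`alc0315_like` preset (53 windows, cutoff 45.5 Å) has a true shift of about
−3.3 pKa units, inside the range spanned by real formulations.

Sampler defaults: $D_c = 10$ Å²/ns, $\mathrm{d}t = 10^{-5}$ ns, $10^6$
steps per window recorded every 100 steps, i.e. 10 ns of overdamped
dynamics per window with a within-window relaxation time of
$k_BT/(k_\parallel D_c) \approx 0.03$ ns — hundreds of independent samples
per window after the 30 % burn-in, and stable integration
($\mathrm{d}t \ll$ relaxation time) under the 2.0 kcal mol⁻¹ Å⁻² restraint.
Per-window seeds derive deterministically from one base seed
(`base + index + 104729 × state`), so datasets are byte-reproducible.

What the synthetic data do **not** emulate: slow lipid conformational
relaxation (the real correlation times are nanoseconds, not picoseconds),
coupling between the tagged lipid and membrane undulations, finite
force-field accuracy, and any lateral degrees of freedom. Passing the
recovery tests therefore demonstrates that the estimator introduces no
material bias of its own at realistic noise levels; it says nothing about
whether a given MD engine, force field or sampling time produces accurate
PMFs.

### Statistical behaviour at the default budget

With the default budget the recovered per-replicate shift carries a
standard deviation of roughly 0.4–0.8 pKa units for the `alc0315_like`
system — comparable to the replicate spread reported for real
microsecond-scale campaigns (0.42–0.44), because WHAM stitching noise
accumulates as a random walk across the ~50-window ladder in both
settings, with occasional larger excursions. A single replicate pair is
therefore *not* expected to land within 0.15 units of the truth; the
protocol estimate is the six-replicate mean, and that is the quantity the
end-to-end recovery test checks. The suite uses six independently seeded
campaigns per budget (base seeds 1000·replicate, spaced so per-window seed
blocks never collide); doubling the per-window sampling extends each
window's trajectory and shrinks the replicate spread by ≈ √2 in
expectation. Note that a standard-deviation ratio estimated from six
replicates is itself a noisy statistic (relative sampling error near 45 %),
so any tight band on it will fail for some seed sets even when the scaling
law holds.

## Worked reference numbers

The four studied formulations, with ML-predicted solution pKa values,
MD-derived shifts (shipped as reference inputs; microsecond-scale all-atom
simulations are far outside what this package's sampler can or should
reproduce) and measured apparent pKa values:

```{r}
tab <- table1_reference()
tab
apparent_pka(tab$pka_s, tab$delta_pka)
```

The calculated-versus-experimental agreement across formulations:

```{r}
three <- tab$lipid %in% c("ALC-0315", "MC3", "SM-102")
round(rsquared(tab$pka_a_calc[three], tab$pka_a_expt[three]), 3)
round(rsquared(tab$pka_a_calc, tab$pka_a_expt), 3)
```

## End-to-end example

A scaled-down synthetic run (3 % of the default budget per window, one
replicate) showing the full chain; at this budget the recovered shift is
noisy but the machinery is identical to a production run:

```{r, eval = requireNamespace("lnpka", quietly = TRUE)}
pre <- synthetic_preset("alc0315_like")
ds <- generate_dataset(pre$plan_charged, pre$plan_neutral,
                       pre$pmf_charged, pre$pmf_neutral,
                       cfg = sampler_config(n_steps = 3e4, stride = 100),
                       base_seed = 2024L, z_hi = pre$z_hi)
rec <- suppressWarnings(suppressMessages(
  recover_delta_pka(ds, pre$plan_charged, pre$plan_neutral)))
c(true = rec$true_delta, recovered = rec$delta)
```

## Known limitations

* 1-D WHAM only; no periodic or multidimensional coordinates, and no
  histogram-free estimators (a maximum-likelihood route exists in the test
  suite purely as an independent cross-check).
* No statistical-inefficiency weighting of windows; uncertainty comes from
  replicates, as in the reference protocol.
* pKa^S is an input. Predicting solution pKa is a separate problem with its
  own error budget, and errors in it propagate one-to-one into pKa^A.
* The planar-bilayer geometry is baked into the unweighted z-average; real
  LNP interiors contain non-planar water/lipid structures that can shift
  pKa^A relative to a planar membrane.
* Trajectory ingestion expects the reaction coordinate already extracted
  (two-column or COLVAR-style text); reading binary MD trajectories is out
  of scope.
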