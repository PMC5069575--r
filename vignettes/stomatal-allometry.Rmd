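---
title: "Spatially optimal stomatal allometry: model, estimators and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially optimal stomatal allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomalloc)
```

## The problem

Stomata — pores formed by guard-cell pairs on the leaf epidermis — set both
the leaf's capacity for gas exchange and a cost: the fraction of epidermal
area surrendered to stomatal machinery. `stomalloc` implements a
cost–benefit analysis of this allocation across species. The benefit proxy
is the anatomical maximum stomatal conductance to water vapour,

$$g_{smax} = \frac{d_{H_2O}}{w_v}\,
  \frac{D_s\,a_{max}}{d_p + \frac{\pi}{2}\sqrt{a_{max}/\pi}},$$

where $D_s$ is stomatal density (m$^{-2}$), $a_{max}$ the pore area at full
anatomical aperture (m$^2$), $d_p$ the pore depth (m), $d_{H_2O}$ the
diffusivity of water vapour in air and $w_v$ the molar volume of air. The
cost proxy is the epidermal cover fraction $f_{gc} = D_s\,a_{gc}$, with
$a_{gc}$ the plan-view area of the guard-cell pair.

Across species, two allometries link these traits:

$$a_{gc} = b_s\,D_s^{S}, \qquad a_{max} = b_p\,a_{gc}^{P}.$$

Substituting them (and the pore-depth geometry
$d_p = \sqrt{2\,a_{gc}\,r_{wl}/\pi}$, which equals the guard-cell width when
$w_{gc} = r_{wl}\,l_{gc}$) collapses $g_{smax}$ to a function of density
alone. The quantity of interest is the marginal ratio

$$\Lambda = \frac{\partial g_{smax}/\partial D_s}
                 {\partial f_{gc}/\partial D_s},$$

evaluated under the fitted allometries. Its sign partitions the $(S, P)$
exponent plane: for $S < -1$ the cover falls as density rises, and if
conductance still rises (region II) then $\Lambda < 0$ — the spatially
optimal regime in which leaves gain gas-exchange capacity while giving up
epidermal area. Region III ($S > -1$, conductance rising) and region I
(conductance also falling, which requires $SP < -2$) both give
$\Lambda > 0$. The line $S = -1$ is the area-preserving boundary where
$\partial f_{gc}/\partial D_s = 0$ exactly and $\Lambda$ is signed
infinity; the package encodes it as a `boundary` label rather than an
error, because bootstrap replicates straddle it.

## Estimators

**SMA regression.** Allometric exponents are estimated by standardized
major axis regression on $\log_{10}$ species averages: the slope is
$\mathrm{sign}(r)\,s_y/s_x$, symmetric in $x$ and $y$ (the exponent of the
inverse fit is the reciprocal). The 95% CI uses the classical
$F$-statistic form $b(\sqrt{B+1}\pm\sqrt{B})$ with
$B = F_{0.95;1,n-2}(1-r^2)/(n-2)$. An offset is kept only when a $t$-test
finds the elevation significantly different from zero at $\alpha = 0.05$
($\alpha$ follows the package-wide significance convention), and a fit is flagged invalid when the
Pearson correlation of the log values is not significant at 0.05. Fits on
independent contrasts are forced through the origin
($b = \mathrm{sign}(\sum xy)\sqrt{\sum y^2/\sum x^2}$).

**The marginal ratio.** With
$g(D) = A D^{1+SP} / (k D^{S/2} + m D^{SP/2})$, where
$A = (d_{H_2O}/w_v)\,b_p b_s^P$, $k = \sqrt{2 r_{wl} b_s/\pi}$ and
$m = (\sqrt{\pi}/2)\sqrt{b_p b_s^P}$, the closed-form derivative is

$$\frac{dg}{dD} = \frac{A D^{SP}\left[k\left(1+SP-\tfrac{S}{2}\right)D^{S/2}
  + m\left(1+\tfrac{SP}{2}\right)D^{SP/2}\right]}
  {\left(k D^{S/2} + m D^{SP/2}\right)^2},$$

and $\partial f_{gc}/\partial D_s = b_s(1+S)D^S$. The derivative is
verified against central finite differences in the permanent test suite.
Where the two bracketed coefficients differ in sign the sign of $dg/dD$
depends on the density at which it is evaluated; `marginal_ratio()`
therefore evaluates at a reference density (by default the geometric mean
of the data, the only honest choice since no evaluation point is canonical)
and re-checks the sign at user-supplied densities (the analysis driver uses
the 5th/95th data percentiles), flagging `sign_stable = FALSE` on
disagreement instead of ignoring it.

**Bootstrap.** Uncertainty in $\Lambda$ comes from a paired species-level
bootstrap: one resample of the species table per replicate, with the
size–density fit using the replicate's complete $(D_s, a_{gc})$ cases and
the pore-size fit its complete $(a_{gc}, a_{max})$ cases. This is the
reading that makes a "paired" bootstrap of two fits with different
complete-case sets meaningful — the dependence is preserved through the
shared resample; independent resampling is available behind
`paired = FALSE`. $\Lambda$ is computed per replicate at the replicate's
own geometric-mean density (a fixed reference is available via `d_ref`).
Summaries are linear-interpolation percentiles; replicates at the $S = -1$
boundary are counted (`n_boundary`) and excluded from interpolation. The
conventional production setting is 10 000 replicates; tests and examples
use a few hundred, which stabilises the 95% CI width to well within 25%.

**Phylogenetic controls.** Independent contrasts are computed by the
pruning recursion (contrast $(x_i - x_j)/\sqrt{b_i + b_j}$, ancestral
values $1/b$-weighted, ancestral branches extended by $b_i b_j/(b_i+b_j)$),
after an optional logarithmic branch-length transform
$b \mapsto \log_{10}(b/b_{floor} + 1)$ with $b_{floor}$ defaulting to
$10^{-6}$ of tree depth (base and floor are not canonical; both are
configurable). Polytomies are resolved deterministically to zero-length
branches. Contrasts are positivized on $x$ with $y$ following; the
through-origin slope magnitude is invariant to this convention (tested).
Blomberg's $K$ uses the phylogenetic GLS mean and the Brownian-motion
expectation of the MSE ratio; Pagel's $\lambda$ maximises the profiled
Gaussian likelihood of $V(\lambda) = \lambda V_{off} + \mathrm{diag}(V)$
over $[0, \lambda_{max}]$ by 1-D bounded search (tolerance $10^{-6}$),
with $\lambda_{max}$ the largest value keeping $V(\lambda)$
positive-definite for the tree at hand. Both are cross-checked against an
independent reference implementation in the test suite.

**Group comparisons.** Clade differences in $g_{smax}$ (square-root
transformed), $f_{gc}$ and $a_{gc}$ (log10 transformed) use a one-way
ANOVA followed by all pairwise Welch $t$-tests (unequal variances,
Welch–Satterthwaite df) with a Bonferroni factor equal to the number of
pairwise tests (3 for three groups). A "two-sided ANOVA" specification is read as a standard one-way ANOVA
with two-sided post-hocs — the only coherent reading, since the ANOVA $F$
is inherently one-tailed.
Compact letter displays are assigned greedily over the graph of
non-significant pairs.

## Data ingest rules

`ingest_traits()` reproduces the compilation conventions for literature
data: arithmetic means within source, grand means across sources; species
with densities on both leaf surfaces at an adaxial:abaxial ratio above
0.05 flagged amphistomatous with density averaged over the two surfaces;
$a_{gc} = (\pi/2)\,l_{gc} w_{gc}$ when only dimensions are reported;
$a_{max} = (\pi/4) f_{lw} l_p^2$ from pore length with a shape fraction
$f_{lw} \in [0.4, 1]$ by morphology class (unknown classes fall back to
the mid-range 0.5 with a warning); and species whose averaged $a_{max}$
reaches $a_{gc}$ keep the record but lose the implausible $a_{max}$, with
a warning naming them. $f_{gc} > 1$ warns rather than errors — synthetic
extremes can produce it and no hard cap is part of the model. Internal
units are strictly SI; the CSV reader accepts conventional field units
(stomata mm$^{-2}$, µm, µm$^2$) and converts exactly. Defaults
$d_{H_2O} = 2.49\times10^{-5}$ m$^2$s$^{-1}$ and
$w_v = 2.45\times10^{-2}$ m$^3$mol$^{-1}$ correspond to 25 °C and
101.3 kPa; $r_{wl} = 0.36$ is the cross-species mean guard-cell
width:length ratio. All are configurable, and every qualitative result in
the package is invariant to the two physical constants (they scale
$g_{smax}$ without touching signs or exponents).

## The synthetic generator

`generate_traits()` draws clade-structured tables with the statistical
skeleton the analysis assumes: a latent $\log_{10} D_s$ uniform in a
clade window, exact latent allometries, and independent log-normal
observation noise on each trait column. The noise is split across columns
in the ratio the symmetric estimator assumes — SDs
$\sigma/(\sqrt{2}|S|)$ on $\log_{10} D_s$, $\sigma/\sqrt{2}$ on
$\log_{10} a_{gc}$ and $|P|\sigma/\sqrt{2}$ on $\log_{10} a_{max}$ — so
that the SMA exponents are statistically consistent for the generating
$S$ and $P$. (With response-only noise the SMA slope converges to
$\sqrt{S^2 + \sigma^2/\mathrm{Var}(x)}$, and no estimator of this family
would recover the truth; the symmetric error model is the regime in which
parameter-recovery claims are meaningful.) A consequence is a single
scatter dial per clade: the pore-area column SD is pinned at $|P|$ times
the guard-cell column SD by the same consistency requirement.

Defaults emulate the study conditions: angiosperms
($n = 927$, $S = -1.05$, $b_s = 0.17$), gymnosperms
($n = 38$, $S = -1.25$, $b_s = 12$), pteridophytes
($n = 67$, $S = -0.58$, $b_s = 3\times10^{-5}$), a generic pore-size
relation ($P = 0.92$, $b_p = 0.05$) in every clade, $a_{max}$ observed
for roughly a quarter of records, scatter of 0.25 dex, and density
windows placing pteridophytes at few large stomata
($\log_{10} D_s \in [6.8, 8.0]$) and angiosperms across a wide range
($[7.3, 9.3]$); the window constants are fixtures of the generator, not
empirical claims. Records violating $a_{max} < a_{gc}$ are redrawn rather
than truncated, keeping the log-linear model clean while mirroring the
exclusion rule applied to real compilations.

What the generator does *not* emulate: the field data's much larger
scatter ($r^2 \approx 0.37$–$0.58$ versus $\approx 0.85$ here at 0.25
dex), phylogenetic correlation between related species (trait draws are
independent given the clade), uneven taxon sampling, within-species
variance heterogeneity, and measurement error correlated across traits
from a shared source. Passing recovery tests therefore demonstrate
correctness of the estimators under the assumed error model, not
robustness to everything real compilations contain.

`generate_tree_and_traits()` supplies the comparative fixtures: a Yule
pure-birth tree with exactly the requested number of tips and a
Brownian-motion trait simulated edge by edge from a root value of 0.

## Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; generators and the
  bootstrap restore the caller's RNG state.
* Zero-variance inputs to a fit, all-zero contrast sets, constant traits
  for signal statistics, and missing tip values raise informative errors;
  bootstrap replicates that fail refit are dropped, counted, and warned
  about above a 5% rate.
* $S = -1$ is compared exactly (the generator and bootstrap can hit it);
  region labels at floating grid points are taken at face value — a grid
  intended to show the boundary must include $-1$ exactly.
* Percentiles are quantile type 7 (linear interpolation), the convention
  most software defaults share; no other convention is canonical here.
* Problem sizes in the shipped tests (hundreds of species, hundreds of
  replicates, 50-tip trees) were chosen as the smallest sizes at which the
  statistical assertions are stable; production analyses can scale all of
  them up through the exported parameters.

## Known limitations

* The closed form of $\Lambda$ is derived here from the composed model and
  pinned by finite-difference and secant oracles; no external symbolic
  derivation is bundled.
* Region labels can genuinely depend on the evaluation density when the
  derivative's two coefficients differ in sign; the package reports
  instability instead of resolving it.
* The amphistomatous variant of the conductance model beyond density
  averaging (two independent epidermes) is out of scope, as are tree
  inference and dating — a dated tree is an input.
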