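---
title: "An individual-based model of generalized transduction and lysogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of generalized transduction and lysogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetrans)
```

## The model

`phagetrans` simulates bacteria and bacteriophage as discrete individuals
on a toroidal `W x H` lattice. Each site holds at most one bacterium and any
number of free virions; free space is the bacterial resource. The
environment is well mixed: all positions are re-randomized every iteration,
so the lattice provides carrying capacity and local competition rather than
spatial structure.

**Genomes.** Each bacterium carries an explicit circular genome of gene
slots holding essential genes, accessory genes and antibiotic-resistance
genes. A resistance gene is either active (it confers phenotypic resistance
to its drug) or inactive (present but silent). There is no mutation:
activity can only arrive horizontally, with a transduced active copy, which
confers resistance even alongside an inactive native copy. Every gene keeps
a provenance tag naming its strain of origin, preserved through packaging
and recombination, so genome snapshots can colour DNA by origin.

**Phage.** A phage genotype is temperate or virulent, with burst size $B$,
headful capacity $h$ (in gene slots), transducing-particle probability
$p_{GT}$, and a superinfection immunity group. When a cell lyses, each of
the $B$ progeny is independently a *generalized transducing particle* with
probability $p_{GT}$: instead of phage DNA its capsid holds the $h$
consecutive non-prophage slots starting at a uniformly random position of
the circular host genome. On a genome with $L$ non-prophage slots and a
single marker gene, the probability that a transducing particle carries the
marker is therefore exactly $h/L$ (the package tests verify this against
exhaustive window enumeration). Transducing particles are defective: they
inject their cargo — bypassing repressor-mediated immunity, since they
carry no phage genome for the repressor to act on — but can never
replicate, lyse or lysogenize, so a pure transducing inoculum can only
shrink.

**Lysis versus lysogeny.** An infecting temperate phage lysogenizes with
probability
$$P_{lys}(n) = p_{lys}\,\frac{n}{n + K_{lys}},$$
where $n$ counts free virions in the Moore neighbourhood (the 8 surrounding
sites) of the infected cell — a saturating response to local phage
pressure. Virulent phage always lyse. A lysogen carries the prophage in its
chromosome (at an attB site at the genome start; prophage DNA is excluded
from headful packaging) and is immune to functional virions of the same
immunity group; such virions are adsorbed and destroyed.

**Induction.** A lysogen is induced with per-iteration probability
$$P_{ind}(s) = \frac{1}{1 + \alpha\,e^{-\kappa s}},$$
where $s$ is the cell's stress level. At zero stress this equals
$1/(1+\alpha)$, so $\alpha = 10^5$ corresponds to a spontaneous induction
rate of about $10^{-5}$ per lysogen per iteration and $\alpha = 10^3$ to
about $10^{-3}$; the sigmoid form was chosen to make these equivalences
exact at $s = 0$. Antibiotic exposure sets $s$ to `stress_on_exposure` for
*every* exposed cell (resistant or not — the stress response models
DNA-damage signalling, not killing), and $s$ resets to 0 on iterations
without exposure.

**Antibiotics.** A cell lacking an active resistance gene for an applied
drug accumulates unprotected exposures. It tolerates `drug_delay` of them —
stressed but alive and *not dividing* — and is killed with probability
`p_kill` on each further exposed iteration. This pharmacodynamic lag is a
deliberate design choice with two consequences that the modelled biology
requires. First, killing of unrescued populations is still certain: an
exposed sensitive population stops reproducing immediately and dies
deterministically a few iterations later (with instantaneous reproduction
allowed under the drug, lattice regrowth — up to eight offspring around
each survivor — outruns any per-iteration kill probability below ~0.9 and
no antibiotic would ever clear a population). Second, the lag opens the
window in which the SOS-like stress response acts: stressed lysogens induce,
release transducing particles, and can hand a resistance gene to a
neighbour *before* that neighbour is killed — the rescue channel that
drives the two-lysogen gene-shuffling experiment. With instant kill the
rescue is impossible; with delayed kill but continued reproduction the
controls never go extinct; the combination reproduces both regimes.

**Reproduction and death.** Free sites are filled by roulette-wheel
competition among the living Moore neighbours, with weight
$w = (1-c)^k$ for a cell with $k$ active resistance genes ($c$ =
`cost`, default 0.05); the offspring is an exact genome copy. Parents are
the occupants at the start of the phase, so offspring do not reproduce in
the iteration of their birth. Cells also die intrinsically with probability
`p_death` per iteration; free virions decay with probability `p_decay`.

**Iteration order.** Each iteration executes: (1) well-mixed shuffling;
(2) antibiotic action; (3) prophage induction and lysis; (4) adsorption —
each co-located virion adsorbs with probability `p_ads`, with superinfection
blocking, transducing injection (all injections are processed; a cell hit
by several particles integrates them sequentially, injections on a cell
preceding its lysis because DNA injection is fast relative to the lytic
cycle), and at most one *productive* functional infection per cell per
iteration (further functional virions on that cell are lost); (5) virion
decay; (6) intrinsic death; (7) reproduction; (8) recording. The biological
ingredients fix the phases; this particular order is the package's
documented convention.

## Parameters

| parameter | default | units / meaning |
|---|---|---|
| `width`, `height` | 50, 50 | lattice size (2500 sites) |
| `occupancy` | 0.1 | initial bacterial density |
| `moi` | 1 | virions per bacterium in the inoculum |
| `p_ads` | 0.5 | adsorption probability per co-located virion per iteration |
| `p_decay` | 0.2 | free-virion decay per iteration |
| `p_death` | 0.01 | intrinsic death per iteration |
| `cost` | 0.05 | fitness cost per active resistance gene |
| `p_GT` | 0.4 | transducing-particle probability |
| `p_lys`, `K_lys` | 0.8, 2 | lysogeny saturation parameters |
| `burst_size` | 50 | virions per lysis |
| `L`, `headful` | 100, 10 | genome size and capsid capacity (slots) |
| `alpha`, `kappa` | 1e5, 0.4 | induction curve (spontaneous rate ~1e-5) |
| `stress_on_exposure` | 20 | stress set by antibiotic exposure |
| `p_kill`, `drug_delay` | 1.0, 2 | kill probability after the tolerance window |
| `drug_duration` | 10 | iterations an antibiotic dose persists |
| `n_sample` | 500 | virions sampled between the two phases |

The intermediate rates of a system like this are rarely measurable
directly; what is observable are outcomes (survival percentages, extinction
patterns, importance rankings). The defaults above are therefore
calibration choices, fixed against those outcome-level anchors and then
frozen, that place the model in its target regime: a two-phase run with a
temperate transducing phage ends with
bacteria and phage jointly alive in roughly 98% of replicates, while the
non-transducing and virulent variants always collapse. Within that
constraint the values are biologically conventional — burst sizes of tens,
a headful of ~10% of the genome, a few-percent resistance cost, MOI 1 at
10% occupancy. Three values deserve notes. `p_decay = 0.2` is anchored on
the extinction pattern of the modelled system: when the hosts die, the
phage population must follow within the run, so a hostless pool of
$10^4$–$10^5$ capsids has to decay to zero over ~80 iterations; slower
decay leaves inert capsids
"alive" at the end of every run and erases the extinction contrast between
the scenarios. `p_GT = 0.4`: wet-lab lysates carry roughly one transducing
particle per 700 infective ones, but at desk scale (hundreds of sampled
virions rather than $10^9$) the transfer channel must be proportionally
stronger to exist at all; 0.4 keeps the expected number of marker-carrying
particles in a 500-virion sample near 20, comfortably above the
stochastic-extinction threshold of the channel under the fast decay.
`stress_on_exposure = 20` makes the stressed induction probability
$1/(1+10^5 e^{-8}) \approx 0.029$, strong enough that a stressed lysogen
population releases a rescue wave of transducing particles within the
drug-tolerance window. `drug_duration` is finite (a pulse) so that, by the
end of a surviving scenario-1 run, the trickle of free phage is governed by
*spontaneous* induction alone — antibiotic-associated stress has subsided
well before the run ends.

## The experiments

**Two-phase protocol (four scenarios).** Phage propagate for 10 iterations
on a resistant strain (active chloramphenicol marker at the slot
diametrically opposite the prophage integration site); all free virions are
collected and `n_sample` of them transferred to a fresh lattice of sensitive
bacteria (inactive marker copy); the drug is applied from phase-2 iteration
7. The four scenarios differ only in the phage: temperate/transducing,
temperate/non-transducing, virulent/transducing, virulent/non-transducing.
Long-term joint survival requires both lysogeny (protection from the phage)
and transduction (acquisition of the active marker); only scenario 1 has
both.

**Gene shuffling.** Two strains, each lysogenic for the same temperate
transducing phage, one with active erythromycin and inactive
chloramphenicol resistance, the other the complement; both drugs at
iteration 10. Rescue proceeds through stress-driven induction and
cross-strain transduction; the surviving population is double resistant.
Controls: no prophages (extinction), and no antibiotics at $\alpha = 10^5$
versus $\alpha = 10^3$ (double resistants emerge spontaneously only when
spontaneous induction is high).

**Sensitivity analysis.** Random parameter combinations (drawn within
declared ranges, plus a dummy parameter from {1,2,3} that the simulator
ignores) are each run in replicate; the response is the fraction of
replicates with surviving phage. A random-forest regression
(`randomForest`) of the response on the parameters yields permutation
importances (%IncMSE); the dummy provides the noise floor. The default
design varies the biological transfer and decision parameters — the
transduction probability, the lysogenization probability, the burst size,
the between-phase sample size and the antibiotic timing — with the
probability parameters sampled log-uniformly across orders of magnitude
(`p_GT` over $10^{-3}$–$1$, `p_lys` over $10^{-4}$–$1$), since their
response transitions live at small values; the infection-machinery
constants (adsorption, decay) stay at their calibrated defaults, where
varying them widely only modulates raw predation pressure and pool
persistence and masks every biological effect, and the donor genome size is
treated as a separate sweep axis rather than a design parameter. At the
package's analysis scale (300 combinations x 10 replicates on a 30x30
lattice, 10,000 trees) the transduction probability ranks first and the
lysogenization probability second, both far above the dummy.

**Sweeps.** Joint survival as a function of $p_{GT}$ crossed with donor
genome size, burst size, or sample size, 5x5 grids summarised per bin by
the replicate median (majority survival). In the strong-transfer regime
(upper $p_{GT}$ rows) survival falls with genome size (marker capture
$\propto h/L$), rises with burst size (more transducing particles), and
rises then plateaus with sample size. At mid-range $p_{GT}$ the cells sit
mid-transition and are dominated by sampling noise at this analysis scale;
there, larger samples can even depress survival slightly, because a larger
inoculum also means more functional phage and harder predation.

**Lysate capacity.** `lysate_capacity()` is the worked arithmetic: at
$10^9$ PFU/ml, one transducing particle per 700 infective and 43 kbp per
capsid, a millilitre of lysate carries ~$6.1\times10^{10}$ bp of bacterial
DNA, about 22,000 genome equivalents at 2.8 Mbp per genome.

## What the generator emulates — and what it does not

The scenario initializers are the package's synthetic-data layer: they
build founder populations with explicit genomes (20 essential, 10 accessory
slots, the configured markers, optional prophage) and phage inocula in the
configured states. They emulate the *structure* of the modelled community —
gene-level genomes, provenance, activity states, prophages — under
idealized conditions: clonal founders, a single phage genotype per
experiment, uniform adsorption, no nucleotide-level sequence, no lateral or
specialized transduction, no plasmid replication (plasmid markers are
treated as chromosomal loci), no restriction or CRISPR defence, no phage
evolution. Passing tests therefore demonstrate the joint operation of
lysogeny, headful transduction and selection in this idealized community;
they do not calibrate rates against any particular wet-lab system beyond
the qualitative regime described above.

## Numerical and implementation choices

Simulations are exactly reproducible from `(configuration, seed)`;
replicate seeds are drawn deterministically from a master seed so any
replicate can be re-run in isolation. Genomes are stored once in a
registry and referenced by id: reproduction copies an id, and the only two
genome-modifying events (prophage integration, recombination of a
transduced headful) create new entries whose metadata (length, active
resistance genes, drug and immunity bitmasks) update incrementally. The
packaging substrates of all genomes live in one concatenated buffer so a
whole batch of simultaneous transductions is executed with vectorized
gathers; full locus arrays are reconstructed on demand (for genome
snapshots) by replaying the event chain. Degenerate inputs are defined
conservatively: a temperate phage with no local free phage never
lysogenizes ($P_{lys}(0)=0$); an empty phase-1 lysate yields an empty
sample with a warning rather than an error; ties in the roulette wheel
cannot occur (weights are perturbed by continuous Gumbel noise).

Problem sizes in the shipped tests — 100 replicates per scenario on the
50x50 lattice, 300x10 sensitivity runs on 30x30, 5x5 sweep grids at 10
replicates — are the package's analysis scale, chosen so the full suite
runs comfortably on a laptop; all are configuration keys, and nothing in
the code caps them.

## Known limitations

* The lattice is well mixed by construction; spatially structured
  (biofilm-like) dynamics are out of scope.
* Time is discrete with a fixed phase order; burst is instantaneous (no
  latent period), and at most one productive functional infection per cell
  per iteration resolves the double-lysis ambiguity by fiat.
* Induction uses the first prophage of a cell; multi-prophage cells of
  *different* immunity groups are representable but their joint induction
  is not modelled.
* The stress response is a single scalar set by exposure; pharmacokinetics,
  dose response and resistance mechanisms that avoid stress altogether are
  not distinguished.
* Quantitative wet-lab observables (transduction frequencies per ml, CFU
  counts) are outside the model's units; only the qualitative regime is
  comparable.
* Phage survival is highly redundant in the lysogenization probability:
  with abundant infections, even very small `p_lys` eventually produces a
  protected lysogen, so the survival response transitions only below
  `p_lys` of a few per mille (and dips again at very high `p_lys`, which
  starves the phase-1 lysate). Sensitivity statements about `p_lys`
  therefore depend on exploring it across orders of magnitude.
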