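---
title: "Methods: cooperative phenotypes and social assortment"
author: "coopassort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperative phenotypes and social assortment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopassort)
```

# The scientific question

Theory on the evolution of non-kin cooperation predicts that cooperation can
persist when individuals (i) differ consistently in how cooperative they are —
a *cooperative phenotype* — and (ii) assort socially by that phenotype, so that
cooperators interact mostly with other cooperators. In Trinidadian guppies the
cooperative context is predator inspection: approaching a predator yields
threat information shared by the whole shoal, at personal risk, and joint
inspection dilutes that risk. The fitness stakes of inspection differ between
populations under high (HP) and low (LP) predation pressure, which motivates
comparing assortment between regimes.

This package implements the complete analysis chain for that question —
phenotype repeatability, association networks, permutation null models and
assortment tests — together with a synthetic-data generator whose ground truth
is known, so every stage can be validated without access to field data.

# Cooperativeness scores and repeatability

An individual's cooperativeness in one trial is its mean distance from the
refuge over the tracked frames (`trial_score()`); individuals sitting in the
refuge score 0, individuals at the predator end score the arena length. The
overall phenotype is the mean of the (two, by default) trial scores
(`overall_cooperativeness()`).

A *cooperative phenotype* exists when scores are repeatable. With a balanced
design of $n_0$ measures per individual, the one-way ANOVA with individual
identity as the factor gives mean squares among ($MS_A$) and within ($MS_W$)
individuals, and

$$R \;=\; \frac{(MS_A - MS_W)/n_0}{MS_W + (MS_A - MS_W)/n_0}
      \;=\; \frac{F - 1}{F - 1 + n_0},$$

which for $n_0 = 2$ reduces to $(F-1)/(F+1)$. $R$ is the intraclass
correlation: the fraction of score variance attributable to differences among
individuals. It reaches 1 only with no within-individual variation and is
negative when $F < 1$ (the estimator overshoots zero when individuals are
*less* consistent than chance).

Trial scores are distances and typically non-normal, so p-values come from a
Monte-Carlo permutation test (`permutation_anova_p()`): scores are reshuffled
uniformly across all individual-by-trial slots — the exchangeability null of
no individual effect — and the p-value is the add-one-corrected proportion
$(b+1)/(N+1)$ of permutations with $F$ at least as large as observed. A fixed
permutation count (default 10 000) with this estimator is deterministic in
cost, unbiased and seed-reproducible; sequential-stopping schemes found in
permutation-ANOVA software are an implementation detail we deliberately avoid.

Testing three batches (all individuals, females, males) across several
populations inflates the false-positive rate, so each batch is corrected by
Benjamini–Hochberg FDR control (`fdr_control()`, level 0.05). On the bundled
reference table of eight wild populations (`reference_repeatability_table()`),
BH at 0.05 applied to the recorded p-value batches reproduces the recorded
significance pattern row for row — 7 of 8 populations significant for all
individuals, 6 for females, 2 for males — which is what pinned BH as the FDR
procedure. Detection-floor entries ("<0.0001") are encoded as 0.0001; the BH
decision is insensitive to any value at or below that floor.

Applying $(F-1)/(F+1)$ to the table's printed $F$ ratios reproduces the
printed repeatabilities. Two of the 24 rows differ in the second decimal by
about 0.005–0.006; both are double-rounding cases, where the $F$ ratio printed
to 2 d.p. is consistent with a true value on either side of the rounding
boundary of $R$. The tests therefore demand agreement within half an ULP of
the printed $R$ plus the propagated half-ULP of the printed $F$,
$0.005 + 2\cdot 0.005/(F+1)^2$ — printed-precision agreement, not a loosened
band.

# The association network

Shoal observations arrive in long group-by-individual form: each sample is a
partition of the individuals observed at that moment into shoals. The network
edge weight is the simple ratio index,

$$w_{ij} = \frac{x_{ij}}{n_{ij}},$$

where $x_{ij}$ counts samples with $i$ and $j$ in the same shoal and $n_{ij}$
counts samples where at least one of them was observed — including samples
where both were seen in *different* shoals, the literal reading of the index
definition. $w_{ij} \in [0,1]$, with 1 meaning the dyad was together whenever
either was seen. Individuals seen in fewer than `min_sightings = 4` distinct
samples ("more than three times") are removed before network construction;
because sighting counts are invariant under the permutation null, the filtered
node set is identical across the whole null ensemble.

# Null models and the two-tailed decision

Two permutation nulls, matched to the question being asked:

* **Data-stream permutation** (`datastream_permute()`): independently within
  each sample, the identities of the observed individuals are uniformly
  permuted among themselves. This preserves each sample's shoal-size multiset
  and each individual's number of sightings exactly (asserted on every draw in
  the tests, not assumed), while destroying any preference structure. The SRI
  network is rebuilt from each permuted stream
  (`permuted_sri_ensemble()`, streamed — null matrices are never all held in
  memory, and each draw has a deterministic seed derived from the master
  seed).
* **Edge-weight permutation** (`edge_weight_permute()`): the multiset of
  dyadic weights (zeros included) is shuffled over dyad slots. This keeps the
  weight distribution and asks only whether *which* dyads carry the strong
  ties is informative.

`two_tailed_test()` compares an observed statistic to its null sample: the
result is significant when the observed value lies strictly inside the top or
bottom `alpha_tail` (default 2.5%) of null values, decided directly on the
empirical null; null values tying the observed count as equally extreme in
both tails, which is conservative. Alongside that decision the function
reports the add-one-corrected two-tailed p-value
$2\min\{(b_{\ge}+1), (b_{\le}+1)\}/(N+1)$ (never exactly zero, unlike raw
proportions, which are also reported as `p_raw`) and the null median, the
conventional reference value quoted next to an observed coefficient.

# Assortativity

For a continuous trait $x$ the weighted assortativity $r^w$ is the weighted
Pearson correlation of trait values across edge endpoints, over all ordered
pairs $(i,j)$, $i \ne j$, with weights $w_{ij}$; for a categorical trait it is
the Newman coefficient $r = (\sum_c e_{cc} - \sum_c a_c b_c)/(1 - \sum_c a_c
b_c)$ on the weight-normalised mixing matrix. The unweighted coefficient
$r^u$ replaces every positive weight by 1 (edge presence means $w_{ij} > 0$
exactly; no threshold). Both are invariant to affine maps of the trait and to
uniform weight rescaling, and both are pinned in the tests by brute-force
ordered-pair oracles on small networks and, for the unweighted continuous
case, cross-checked against igraph.

One finite-size fact matters when reading null distributions: on a complete
graph with equal weights the coefficient is exactly $-1/(n-1)$, not 0,
because endpoint pairs are drawn without replacement. The data-stream null
mean sits at the same baseline (empirically $-1/(n-1)$ to three decimals).
This is behaviour of the coefficient itself, shared by the observed value and
its null ensemble, so the permutation test is unaffected; but a lone
coefficient near $-1/(n-1)$ on a small network should not be read as
disassortment.

`assortment_test()` combines the pieces: observed coefficient versus the
data-stream ensemble. For within-sex tests the network is restricted to one
sex *after* each permutation (restriction before permutation would freeze the
sex composition of every shoal into the null, destroying the group-size
structure the null is supposed to preserve). Nodes missing the tested trait
are dropped from that test only, with a logged count; a test aborts if the
coefficient is undefined in more than 1% of null draws.

`dyadic_correlation_test()` covers the two dyad-level questions: the Pearson
correlation over *all* dyads (zero-weight dyads included — the reference
dyad counts 1830 and 5151 equal all unordered pairs) between edge weight and
(a) the dyad's summed cooperativeness, against the edge-weight-shuffle null —
do strong ties concentrate among cooperative pairs? — and (b) the dyad's
relatedness, against the data-stream null — does association follow kinship?
Relatedness enters only as a precomputed matrix; estimating it is out of
scope. Scalar companions: Spearman rank correlation for body length versus
cooperativeness and a Mann–Whitney U test for sex differences, both via the
standard library routines.

# The synthetic-data generator

The generator exists to make every stage testable with known ground truth; it
emulates the *structure* of field data, not fish behaviour.

* `simulate_phenotypes()` draws latent values $a_i \sim N(\mu, \sigma^2_A)$
  and trial scores $y_{it} = a_i + e_{it}$, $e_{it} \sim N(0, \sigma^2_W)$, so
  the true repeatability $\sigma^2_A/(\sigma^2_A+\sigma^2_W)$ is known
  exactly. Defaults ($\mu = 30$ distance units, $\sigma^2_A = 30$,
  $\sigma^2_W = 40$, $n = 100$, two trials) sit at the high-predation scale:
  $R_{true} \approx 0.43$, the largest all-individuals repeatability in the
  reference table. Scores are truncated at zero (they are distances); with
  these defaults truncation is negligible, and recovery of $R_{true}$ over
  the grid $\{0.1, 0.3, 0.5, 0.7\}$ is unbiased within Monte-Carlo error.
  Body length is drawn jointly normal with $a_i$ at a configurable
  correlation, $N(25, 3^2)$ mm by default — adult guppy scale.
* `simulate_observations()` takes 6 days × 5 samples/day by default,
  mirroring a riverside photographic sampling protocol, with per-sample
  detection probability 0.8 and mean shoal size 4 (small fission–fusion
  shoals). Grouping is by a latent position $z_i = \sum_t s_t\,
  \tilde{x}_{t,i} + N(0,1)$: observed individuals are sorted by $z$ and cut
  into consecutive shoals with shifted-Poisson sizes. This mechanism is an
  invention — the field data are observed networks, not a generative model —
  chosen because strength 0 gives exchangeable (null-true) grouping and
  increasing strength gives monotonically stronger assortment. At strength 3
  on cooperativeness ($n = 60$, 30 samples) the weighted assortment test at
  200 permutations detects a positive high tail in essentially every
  replicate; at strength 0 it rejects at the nominal 5% rate.
* `simulate_relatedness()` builds a block kin matrix: full-sib families
  (within-family $r = 0.5$) and zero-mean background noise. Because the
  grouping mechanism never reads the kin matrix, the relatedness test is
  null-true by construction, giving a clean type-I check.
* `simulate_track()` is a reflected mean-reverting walk whose stationary mean
  distance equals the target cooperativeness; at the default 30.1 frames/s
  for 5 minutes (9 030 frames) the realised score is within 1 cm of target.

Samples are independent by construction — no temporal autocorrelation of
shoal membership, no fission–fusion dynamics within a day, no behavioural
realism in the tracks. Passing tests therefore validate the *statistical
machinery* under the stated sampling model; they cannot certify performance
under temporally correlated field sampling.

# Numerical and design choices

* All randomness flows through per-call seeds; no function touches the global
  RNG state, and ensembles derive per-draw seeds deterministically from the
  master seed, so identical configurations are bit-identical (report files
  are rounded to 6 significant digits to make that comparable byte-wise).
* Degenerate inputs are flagged rather than silently propagated: all-equal
  scores give a 0/0 F ratio and an explicit error from `repeatability()`;
  $MS_W = 0$ returns $R = 1$ with a degeneracy attribute; zero-variance
  traits and single-class label vectors return `NA` with a warning.
* The balanced-design requirement is enforced; individuals with missing
  trials are excluded (with a log message) rather than imputed, since the
  repeatability formula assumes equal $n_0$.
* Monte-Carlo problem sizes in the validation suite — 500 replicates at
  $n = 100$ for repeatability recovery, 100 replicates × 200 permutations for
  the assortment operating characteristics — were fixed in advance as the
  smallest sizes at which binomial error bands are meaningfully narrow.

# Worked example

```{r example, eval = FALSE}
sim <- simulate_population(
  phenotype_model(n_individuals = 60),
  observation_model(assort_strength = 3,
                    traits = "overall_cooperativeness"),
  kin_model(family_size_mean = 4),
  seed = 7)

cfg <- run_config(seed = 2, n_permutations = 1000)
report <- run_full_analysis(cfg, sim$individuals, sim$trials,
                            sim$observations, sim$relatedness)
print(report)
summary(report)
plot(report$assortment$overall_cooperativeness_w_all)
```

# Known limitations

* Only balanced designs; variance-component (mixed-model) repeatability for
  unbalanced data is out of scope.
* Only the two nulls described; no Bejder-style sequential swaps, no
  restricted permutations by time or location class.
* The SRI is the only association index (no half-weight or twice-weight
  variants), and the network is static — no temporal or multilayer structure.
* Assortativity for a trait with near-zero variance among the few nodes of a
  small subnetwork is numerically unstable; subnetworks below 3 nodes warn
  and within-sex tests return `NA` coefficients for such draws, which count
  toward the 1% undefined-draw abort threshold.
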