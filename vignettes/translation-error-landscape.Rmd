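---
title: "Modeling codon-specific translation errors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling codon-specific translation errors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtel)
```

## The problem

During translation, the ribosome occasionally accepts a tRNA whose
anticodon does not correctly pair with the codon in the A-site, producing
an amino acid misincorporation — a *phenotypic* mutation that changes the
protein population without touching the genome. Reported per-codon rates
are on the order of 10^-4 to 10^-3, several orders of magnitude above
genetic mutation rates, so a substantial fraction of all protein molecules
carries at least one wrong residue. `mtel` implements three connected
layers for studying this process:

1. a **mechanistic model** of tRNA incorporation at each sense codon,
   driven by diffusion-limited tRNA arrival competition and an effective
   codon/anticodon binding affinity, fitted to observed misincorporation
   counts by MCMC;
2. an **empirical detection layer** that calls amino acid substitutions
   from open-search proteomics PSM tables and turns them into per-codon
   error detection rates;
3. a **population-genetics layer** that combines incorporation
   probabilities with variant-effect scores into site- and protein-level
   fitness burdens and relative fixation probabilities.

A synthetic-data module generates tRNA pools, ground-truth parameters,
multinomial counts, PSM fixtures and variant-effect score tables so that
every stage can be exercised and validated without any external data.

## The mechanistic model

### Arrival

tRNAs are assumed to move by diffusion only. The cell of volume $V$ is
discretized into $n = V/l^3$ sites of tRNA size $l$; a molecule hops
between sites with transition time $\tau = l^2/(6D)$, where $D$ is the
tRNA diffusion coefficient. A species with abundance $[tRNA_i]$ occupies
any given site with probability $[tRNA_i]/n$ and arrives at the ribosome
at rate

$$\lambda_i = \frac{[tRNA_i]/n}{\tau}.$$

Arrival times are exponential, so the probability that species $i$ arrives
before species $j$ (or before any set of competitors, by summing their
rates) is $\lambda_i/(\lambda_i+\lambda_j)$, and the probability of
arriving first in the whole pool is
$P^{first}_i = \lambda_i / \sum_k \lambda_k$. The expected number of
arrivals of a competitor $k$ per arrival of the focal species is
$\lambda_k/\lambda_i$, used below as a continuous exponent. Presets carry
the published constants ($V = 0.6\times10^{-18}\,m^3$ for *E. coli*,
$4.2\times10^{-17}\,m^3$ for *S. cerevisiae*; shared
$l = 1.58\times10^{-8}\,m$ and $D = 8.42\times10^{-11}\,m^2/s$, giving
$\tau \approx 4.94\times10^{-7}\,s$). The printed unit of $D$ omits the
per-second; we read it as a diffusion coefficient in $m^2/s$, the only
dimensionally consistent choice.

### Binding

The effective binding affinity of codon $i$ and anticodon $j$ is a
positionally additive score

$$\Delta A_{i,j} = \sum_{k=1}^{3} a\!\left[c_k, ac_k\right] s_k,$$

where $a$ is a 4×5 matrix of per-nucleotide-pair affinities (codon
nucleotide × anticodon nucleotide, with lysidine `L` as a fifth anticodon
symbol permitted only at the anticodon wobble slot) and $s_1, s_2$ are
site importance weights relative to the wobble position ($s_3 \equiv 1$).
Both sequences are stored 5'→3' and aligned antiparallel: codon position
$k$ pairs with anticodon position $4-k$, so the wobble interaction is
codon position 3 against anticodon position 1. The affinity is
*effective*: it absorbs proofreading and conformational contributions, not
just base-pairing energetics, and is unit-less with lower values meaning
stronger binding. Given a pool, binding probabilities are the per-codon
softmax $P^b_{i,j} \propto \exp(-\Delta A_{i,j})$, computed with
max-subtraction and log-space complements so that saturated competitions
remain finite.

### Incorporation

Incorporation of species $i$ at a codon combines two branches by total
probability: if $i$ arrives first it binds with probability $P^b_i$; if it
does not, every competitor $k$ is expected to have arrived
$\lambda_k/\lambda_i$ times beforehand and must have failed to bind each
time,

$$P^{I|\overline{first}}_i = P^b_i \prod_{k \neq i}
  \left(1-P^b_k\right)^{\lambda_k/\lambda_i},$$

$$P^I_i = P^b_i\,P^{first}_i + P^{I|\overline{first}}_i
  \left(1 - P^{first}_i\right).$$

The raw $P^I$ do not sum to one by construction; since observed counts are
modeled as multinomial draws, we renormalize across species per codon to
obtain proper category probabilities. The implementation is vectorized
over all codons and species and is verified in the tests against an
independently coded brute-force transcription of the formulas (tolerance
$10^{-10}$).

### Two views of the landscape

Aggregating normalized incorporation probabilities by the amino acid each
species carries yields the error landscape. Two matrices are kept
deliberately:

* the **mechanistic** 61×20 matrix over true amino acids, used by the
  fitness layer, which needs per-amino-acid probabilities;
* the **observable** 61×19 matrix with leucine and isoleucine merged into
  a single `I/L` category, used by the likelihood, because the two
  residues are isobaric and mass spectrometry cannot separate them.

A codon's *error probability* is the summed normalized incorporation
probability of all species carrying an amino acid different from the
codon's translation. Under site independence, a protein's error-free
translation probability is the product over its codons of the per-site
complements, $P_f = \prod_s (1 - P^{err}_s)$.

## Identifiability and the affinity gauge

Because binding probabilities are a softmax *per codon*, adding a constant
to an entire codon-nucleotide **row** of $a$ shifts $\Delta A$ of every
anticodon at a given codon by the same amount and changes nothing
observable. There are therefore four independent flat directions — one per
codon nucleotide — not merely the single uniform shift one might expect.
We anchor the Watson-Crick entry of every row at zero
($a[A,U]=a[C,G]=a[G,C]=a[U,A]=0$), so each fitted mismatch entry reads
directly as a binding penalty relative to the row's Watson-Crick pair.
This was established empirically: with a single anchor, fits recover each
row of the truth only up to a row-constant offset, with tiny posterior
spread around the offset values.

Entries can also be *data*-unidentifiable: a pairing that only occurs in
species that can never compete (for example, the lysidine column's G and U
rows, exercised by a single anticodon) has a one-sided likelihood — the
data only bound it from below, and the posterior is flat above the bound.
Parameter-recovery experiments therefore use lysidine-free pools.

## Inference

Observed counts per codon (total observations and error counts per
destination category, leucine/isoleucine merged) are modeled as one
multinomial per codon with probabilities from the observable landscape.
The multinomial coefficient is included, so an empty observation set has
log-likelihood exactly zero. Destination categories that are
observationally indistinguishable from PTMs can be masked; masked
categories are removed and the remainder renormalized at likelihood time
only — the forward landscape is never altered.

Sampling is Metropolis-within-Gibbs: one Gaussian random-walk update per
scalar parameter per sweep, under flat priors on a wide box (±50 on
affinities, [0, 50] on the site weights; posteriors of identified
parameters sit far from these bounds). The default configuration is
10,000 sweeps with a 5,000-sweep burn-in, thinning every 10th post-burn-in
sweep and retaining the last 500 thinned samples. Proposal scales adapt
during burn-in only, so the retained chain has a fixed kernel.

Two design choices make short chains converge reliably:

* **Initialization at the mode.** Chains start from a box-constrained
  quasi-Newton (L-BFGS-B) ascent of the log-likelihood. The optimizer works
  on a floored-probability surrogate (probabilities bounded below at
  $10^{-12}$) so that line searches never encounter $-\infty$; the exact
  likelihood is used to accept or reject the optimum and for all MCMC
  decisions. Starting instead from all-zero affinities declares every
  pairing equivalent — a region from which chains can settle into
  secondary, clearly inferior modes.
* **Curvature-informed proposal scales.** Initial per-parameter scales are
  set from the diagonal of the negative observed information at the
  starting point.

Known limitation: at short chain lengths the central credible intervals
under-cover (the scalar kernel mixes slowly along correlated
affinity/site-weight directions), so interval-based conclusions need
longer chains than point-estimate conclusions. Posterior means are
accurate: on synthetic counts (10^5 observations per codon) fits recover
the free affinities with Pearson $r \ge 0.95$ across seeds in the test
suite's recovery experiment, at 2,000 sweeps.

A diagnostic (not an error) warns when the post-burn-in acceptance rate
leaves [0.1, 0.6].

## The empirical detection layer

Substitution calling from open-search PSM tables applies, in order:

1. drop peptides matched to several proteins;
2. classify mass shifts: within ±5 mDa of zero is *unmodified* (these
   provide coverage), all else *modified*;
3. keep a modified peptide only if its position is covered by an
   unmodified peptide from the same dataset and raw file;
4. require an unambiguously localized shift (a single reported position;
   ties count as unlocalized);
5. require the shift to match the monoisotopic residue-mass difference
   from the database residue to some other amino acid within the same
   ±5 mDa tolerance (one coherent tolerance for both uses, exposed as an
   argument);
6. drop calls whose shift and localized residue also match a listed PTM —
   for example, a +0.98402 Da shift on asparagine is both N→D and
   deamidation and is therefore excluded.

Every input PSM is attributed to exactly one outcome, and the per-filter
counts are returned with the calls. The shipped PTM table contains common
Unimod entries; reproducing any specific published analysis exactly
requires that analysis's own exclusion list. Datasets are curated by two
rules: at least 10 detected substitutions, and at most 10% of detected
misincorporations carrying isotopic-label-indicative shifts (SILAC-style
defaults, configurable).

Error detection rates divide PSM-level substitution observations by
PSM-level coverage of positions with that codon — never unique peptides —
and report codons with zero coverage as missing, not zero. Relative
synonymous codon usage is computed with `seqinr`'s codon-usage machinery
on pooled coding sequences, optionally restricted to the top 5% expressed
genes.

## The fitness layer

Given variant-effect scores $\Delta E$ (0 for the encoded residue, lower =
more severe), the expected cost of misincorporation at a site is the
probability-weighted sum over amino acids,
$\Delta x_{s,p} = \sum_a P_{s(c),a}\,\Delta E(\sigma_a^{s,p})$, using the
mechanistic (unmerged) probabilities. Protein burdens weight the summed
site costs by the protein's proteome fraction $\phi_p$:
$\Delta x_p = \phi_p \sum_s \Delta x_{s,p}$. Fitness differences map to
relative fixation probabilities via the Sella-Hirsh form

$$\Theta = \frac{2S}{1 - e^{-2S}}, \qquad S = q\,N_e\,\Delta x,$$

with presets $N_e = 10^8$ (*E. coli*), $8.6\times10^6$ (*S. cerevisiae*)
and $q = 4.19\times10^{-7}$. $\Theta(0)=1$ by the limit; evaluation uses
`expm1` and switches to $-2S\,e^{2S}$ below $S = -350$, so extreme
selection coefficients underflow gracefully instead of producing NaN.
Effects within 5% of neutral fixation ($|\Theta - 1| \le 0.05$, with a
$10^{-12}$ slack so exact band edges classify as neutral) are called
neutral; the neutral/deleterious/advantageous classes partition
$[0,\infty)$ exactly. Site-cost distributions of synonymous codons are
compared by Wilcoxon rank-sum tests, reported raw and
Benjamini-Hochberg-adjusted, with RSCU-preferred annotation.

Missing scores at amino acids with nonzero incorporation probability are
an error by default; an explicit `renormalize` option drops them while
preserving the total error mass.

## The synthetic-data module and what it does (not) show

The generators define the conditions under which the package validates
itself:

* **tRNA pools**: 42 species drawn from the Watson-Crick anticodons of the
  sense codons, covering all 20 amino acids, with log-uniform abundances
  between 10^3 and 10^5 molecules per cell — the span of RNA-seq-derived
  tRNA abundance estimates. Bacterial-style pools replace the AUA-reading
  anticodon with lysidine-modified `LAU`.
* **Ground-truth affinities**: Watson-Crick strength 6 (in the canonical
  gauge, mismatch penalties of roughly 5–10), chosen so the median
  per-codon error probability lands at ~1.5×10^-3, the documented
  10^-4–10^-3 scale of proteome-wide misincorporation. Site weights are
  drawn uniformly in [0.5, 3]. When a drawn weight is below 1, mismatches
  at that position are cheaper than wobble mismatches and a few codons
  served only by wobble pairing become error hotspots; this is a property
  of the drawn parameters, kept rather than tuned away.
* **Counts**: one multinomial draw per codon from the observable
  landscape; frequencies converge to the generating probabilities by the
  law of large numbers (verified at depth 10^6).
* **PSM fixtures**: peptides sampled abundance-weighted from a random
  proteome; true substitutions drawn from the landscape's per-codon error
  probabilities (inflated by a documented factor of 10 so small fixtures
  contain enough events), with Gaussian 1 mDa mass jitter, plus PTM
  decoys, multi-protein decoys and unlocalized shifts. Substitutions whose
  mass shift collides with a listed PTM on the original residue are not
  injected: they are undetectable by design, and counting them against
  recall would only restate the PTM-exclusion rule. Every injected
  substitution is accompanied by a covering unmodified peptide.
* **Variant-effect scores**: a two-component mixture per site and amino
  acid — near-neutral Gaussian mass (weight 0.7, sd 0.05) and a
  deleterious negative log-normal tail — loosely shaped like published
  distributions of fitness effects, with no claim of equivalence.

Passing tests on these fixtures demonstrates internal correctness —
formulas match independent oracles, the fitted model recovers known
parameters, the caller applies its filters exactly — not fidelity to real
mass-spectrometry data, which carries detection biases, intensity effects,
FDR contamination and dataset heterogeneity that the generators
deliberately omit.

## Problem sizes used by the test suite

The suite validates parameter recovery at 10^5 observations per codon with
2,000-sweep chains on five seeds, caller precision/recall on 2,000-PSM
fixtures across three seeds, Monte-Carlo agreement of arrival probabilities
at 10^5 exponential races, and per-protein error-free probabilities against
10^4 simulated translations per protein. These sizes are the package's
validation design: large enough for the stated tolerances, small enough to
run in minutes.

## Limitations

* tRNA mischarging, ribosome stalling, frameshifts, premature termination
  and drop-off are outside the model; all observed misincorporation is
  attributed to mispairing.
* The affinity model is positionally additive; base-stacking and
  neighbor effects are not represented, and affinities are unit-less
  effective quantities, not physical free energies.
* The multinomial likelihood treats pooled counts as one homogeneous
  sample; per-dataset error structure is not modeled.
* Credible intervals from short chains under-cover (see Inference); use
  longer chains where interval statements matter.
* RNA-seq-based tRNA abundances stand in for charged-tRNA concentrations.
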