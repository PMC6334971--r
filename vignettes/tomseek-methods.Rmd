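---
title: "Methods: profile search, enrichment filtering and gain/loss profiling in tomseek"
author: "tomseek maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile search, enrichment filtering and gain/loss profiling in tomseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomseek)
```

# The problem

Organisms with highly reduced mitochondria — hydrogenosomes and mitosomes —
import every organellar protein through a translocase of the outer membrane
(TOM) whose subunits have diverged so far that ordinary sequence searches
fail. Identifying such subunits combines several independent lines of
evidence: sensitive profile-HMM homology search, a degenerate C-terminal
β-signal shared by mitochondrial β-barrel proteins, membrane topology
(tail-anchored vs signal-anchored), quantitative co-immunoprecipitation
enrichment, intersection with an organellar membrane proteome, domain
architecture, sequence-similarity clustering, and the phylogenomic
distribution of candidates across eukaryotic lineages. `tomseek`
implements this whole in-silico chain as composable, seeded, testable
pieces, together with synthetic-data generators that emulate each input so
that every stage can be validated without downloading external resources.

# Profile HMMs

`buildProfileHMM()` constructs a local-mode protein profile from a gapped
alignment. Columns whose non-gap fraction reaches the occupancy threshold
(default 0.5, an hmmbuild-like heuristic) become match states. Match
emissions are background-mixture pseudocounted,
$e_k(a) \propto c_k(a) + w\,q(a)$ with weight $w = 1$ per column; the
background $q$ is the Laplace-smoothed residue frequency of the alignment
itself, falling back towards uniform for sparse alignments. Insert
emissions equal the background, so insertions are score-neutral.
Transitions are estimated from the implied state path of each alignment
row with +1 pseudocounts.

The search model is deliberately simple and fully specified:

* entry is uniform over match states ($P(B \to M_k) = 1/m$);
* an exit probability of $1/m$ is folded into every match transition row
  (the last match state exits with probability 1);
* delete states are interior only — paths enter and leave at match
  states, so a reported alignment span is always match-bounded;
* all dynamic programming is in log2 space; scores are log-odds in bits
  against the background null. Unknown residues (e.g. `X`) are
  score-neutral.

`viterbiScore()` is the best local path, `forwardScore()` the log-sum over
all paths; forward ≥ Viterbi holds identically, and on models with up to
three match states both equal an exhaustive enumeration of every legal
path (this is a test fixture, not an approximation). Dirichlet-mixture
priors, glocal mode, multi-domain envelopes and iterative (jackhmmer-style)
profile refinement are out of scope: a single search round suffices to ask
whether the planted or annotated family member is retrieved first.

Because the HMMER-style internal calibration is not reproduced,
`calibrateEvalues()` fits a Gumbel distribution by maximum likelihood to
forward scores of seeded i.i.d. background decoys;
$E(s) = N \exp(-\lambda (s - \mu))$, clipped to $[0, N]$. The
self-consistency property — about one decoy in a decoy-sized database
reaches $E \le 1$ — is tested rather than assumed.

# β-signal motif scanning

The degenerate β-barrel sorting signal is expressed over residue classes:
`PxGxxHxH`, with P = polar, G = glycine, H = hydrophobic, x = any.
The class sets are configurable (`residueClassTable()`); the defaults put
serine among the polar residues, which is what makes the one barrel
paralogue carrying a terminal hydrophobic→serine substitution
motif-negative. Because no sequence coordinates exist for "the last
β-strand", hits are flagged when they fall entirely inside a C-terminal
window (default 40 residues — generous for a terminal strand plus the
short C-tail; configurable). The scanner reports all overlapping hits and
is property-tested against a naive regular-expression oracle.

# Transmembrane segments and anchor topology

The published workflow used a trained membrane-topology HMM with a relaxed
posterior cutoff of 0.3. That cutoff is a property of a model we do not
possess and is not numerically transferable; it is recorded in the run
configuration for provenance only. The operative predictor here is an
explicit hydropathy profile: Kyte–Doolittle values averaged in a sliding
window (default 19, the canonical helix-spanning width; windows shrink at
the ends), affinely rescaled to $[0, 1]$. Spans are maximal runs above the
cutoff (default 0.8; "relaxed" preset 0.7), merged across gaps of at most
3 residues, and discarded under 15 residues. Note the window smears block
edges: a pure 25-residue poly-Leu block between strongly polar flanks
yields an above-0.8 run of only ~11 residues, so span counts must always
be reasoned through the run-length rule (the test oracle), not through the
block length.

A single span ending within the last 35 residues is tail-anchored; a
single span starting within the first 35 residues is signal-anchored; two
or more spans are polytopic; anything else is unclassified. The counts of
TMD-bearing proteins produced by a trained predictor cannot be matched
exactly by a hydropathy proxy, so they are treated qualitatively.

# LFQ co-IP enrichment

Intensity tables carry four test and four control log2 intensities
(replicates A–D). The enrichment rule is implemented literally: a protein
is enriched if it is present only in the test arm and absent in the
control, or if its fold change $2^{n}$ with
$n = \overline{\text{test}} - \overline{\text{control}}$ exceeds 1. Means
are taken over quantified replicates only; there is no imputation and no
moderated statistics, because the source procedure uses none. "Present"
defaults to quantified in ≥ 2 of 4 test replicates and "absent" to 0
control replicates; both are exposed knobs.

The literal "> 1-fold" reading accepts any positive difference, so under
symmetric replicate noise a null protein is "enriched" with probability
≈ 0.5. That is a property of the rule, not a bug, and the generators
demonstrate it. For recovery benchmarks the package therefore evaluates
the rule at its discriminative setting, the documented `fcScale = "log2"`
switch (n > 1, i.e. linear fold > 2), where sensitivity and specificity
against planted truth both exceed 0.95 at the default effect size. The
default for `computeEnrichment()` remains the literal reading.

# Triage, architectures, Tom22-like features

`vennRegions()` decomposes 2–3 accession sets into exact membership
regions. `triageCandidates()` ranks candidates: tier 1 = enriched under
both crosslinking-like and native-like conditions and present in the
membrane proteome; tier 2 = crosslink-only membrane hits (how loosely
associated receptors surface); tier 3 = native-only. The membrane
proteome is consumed as a plain accession list — its membership comes
from an external study, and the synthetic generator provides one.

`classifyArchitecture()` assigns non-overlapping domain hits greedily by
descending bit score above a per-domain E-value cutoff (default 0.01),
using the package's own profile engine with packaged synthetic Hsp20/TPR
seed consensus segments, and renders strings such as `Hsp20-TPR(3)-TMD`.

The Tom22-like feature report anchors the conserved TMD motif at the TMD
start: tryptophan expected at position 2, at least one hydroxylated
residue (S/T/Y) within three residues after the tryptophan, serine at
W+4, and an invariant proline anywhere in the TMD. The anchoring is an
interpretation (the source text states positions without an origin) and
the offset is configurable. Because a hydropathy span often starts a few
residues downstream of the biological TMD start (the motif's own polar
residues depress the profile), feature checks on synthetic data use the
generator's designed TMD coordinates from the truth table.

# Similarity networks

All-against-all Smith–Waterman scores (delegated to Biostrings; BLOSUM62,
gap open 11 / extend 1 by default) are converted to p-values with the
Karlin–Altschul form $p = 1 - \exp(-K m n e^{-\lambda S})$ using the
documented constants $\lambda = 0.267$, $K = 0.041$. Pairs with
$p < 0.1$ become edges (the inclusion rule used to assemble such data
sets); attraction is $-\log_{10} p$ capped at 200. The layout places
nodes uniformly at random in the unit square (seeded) and iterates
attraction ∝ attraction × distance along edges against 1/distance
pairwise repulsion, with a damped update: step 0.1 decayed by 0.999 per
iteration, per-node displacement clipped to the current step. The default
10,000 iterations reproduce the published protocol's iteration count.

Two calibration caveats are deliberate and documented. First, these
constants assume natural residue composition; random-sequence behaviour
is therefore exercised with Robinson–Robinson frequencies, and the fixed
family templates are Robinson-composed. Second, a correctly calibrated
p-value is uniform for unrelated pairs, so at the permissive 0.1
inclusion cutoff roughly 10% of unrelated pairs form edges; with dozens
of decoys, connected components at that cutoff merge by chance. Family
membership readout via components therefore uses a stringent cutoff
(e.g. $p < 10^{-4}$), where true family p-values (≪ $10^{-30}$) are
untouched and random edges vanish; the 0.1 cutoff remains the default for
data-set assembly, and the display rule keeps only the strongest edge
fraction (default 20%).

# Gain/loss profiling

Presence/absence profiles (states 1/0/?) over species-tree leaves are
mapped under Dollo parsimony: each component is gained exactly once — at
the most recent common ancestor of its present leaves — and lost on the
minimal set of edges below the gain, one per maximal subtree containing a
confident absence but no presence. Uncertain leaves are free and resolve
toward fewer losses. On a polytomy each lost child clade counts one edge.
The inference is tested against an exhaustive oracle (all gain placements
× loss-edge subsets) on all presence patterns of trees up to 8 leaves.
Single-gain is an assumption, matching reasoning about "secondary loss";
lateral-transfer scenarios are annotations, not inferences, and
maximum-likelihood ancestral reconstruction is out of scope.

# Synthetic data: what it emulates, and what it does not

`simProteome()` plants mutated copies of fixed templates among i.i.d.
decoys: seven β-barrel paralogues (exactly one carrying the
motif-breaking terminal serine — the template's last 40 residues contain a
single glycine, so the terminal window is the only possible motif match by
construction), three Hsp20–TPR(3)–TMD receptor-like tail-anchored
paralogues, one short (~6.4 kDa) Tom22-like protein whose TMD carries the
W/hydroxylated/S(+4)/P motif, and one domain-less tail-anchored protein.
Templates are fixed synthetic consensus sequences built once from an
internal constant seed with Robinson–Robinson composition; they are
stand-ins carrying the diagnostic features, not copies of any database
entry. Designed TMD blocks are 29 hydrophobic residues so that the
19-residue window leaves a ≥ 15-residue super-threshold run after edge
smearing. Mutation is per-site substitution from the background with the
diagnostic windows preserved; there is no indel model, no rate
heterogeneity, and no phylogenetic correlation between family members —
passing recovery tests therefore demonstrates the machinery, not
performance on real divergent proteomes.

`simLfq()` draws protein baselines from Uniform(20, 30) log2 units and
replicate noise with sd 0.5; bait-complex members get a +3 log2 test-arm
shift (a strong but typical co-IP enrichment) and their control cells are
censored with probability 0.7. Background missingness, intensity-dependent
censoring and peptide-level effects of real LFQ data are not modelled.

`simTreeProfile()` draws a random rooted tree, places one gain per
component (root gains for ancestral components, random nodes otherwise),
and loses the component independently on edges below the gain
(default 0.2–0.25 per edge). Histories are redrawn until canonical — the
gain is the MRCA of the surviving present leaves and every loss edge's
parent keeps a present descendant through a sibling — checked with set
operations on the simulated events, independent of the inference code.
This makes "exact recovery of the simulated history" a well-posed
statement; with `lossProb = 1` the degenerate all-lost history is
returned flagged instead.

# Pore-class bookkeeping

`classFractions()` converts per-class particle counts into fractions and
nearest-integer percents, rounding half away from zero, and always reports
the raw fractions alongside because published rounding conventions vary
(a count of 1,175 of 3,412 is 34.4%, which some reports print as 35%).
Percent sums land within 100 ± 2 by construction.

# Problem sizes and determinism

All randomness flows through explicit integer seeds (`withSeed()`
restores the caller's RNG state); the pipeline driver `runPipeline()`
derives one sub-seed per stage from the master seed and writes
byte-identical outputs on re-run. Default benchmark sizes — 100-decoy
proteomes, 200-protein LFQ tables over 100 seeds, 15+15-member families
at 10,000 layout iterations, 8-leaf trees over 100 histories — were
chosen so the full validation suite completes in a few minutes on a
single core while keeping every rate estimate stable to a percent or two.

# Known limitations

* The profile engine scores single domains in local mode only; it will
  not resolve repeats of a domain in one pass (the architecture
  classifier re-scans remaining segments instead).
* E-values from the decoy Gumbel fit are comparable within a run, not
  with HMMER's.
* Hydropathy thresholding cannot reproduce trained-HMM topology counts;
  anchor categories are robust, exact span boundaries are not.
* Karlin–Altschul p-values here use fixed constants without
  composition- or length-correction; orderings are reliable, absolute
  values are approximate.
* HMM–HMM comparison (the most sensitive published search mode) is
  approximated by profile-to-sequence search throughout; e-values from
  HMM–HMM tools are not reproducible and are never asserted.
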