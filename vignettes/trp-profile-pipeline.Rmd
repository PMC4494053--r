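---
title: "Profile-based subfamily classification of TRP channels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based subfamily classification of TRP channels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Transient receptor potential (TRP) channels form a superfamily of
six-transmembrane cation channels whose metazoan subfamilies (TRP-A, -C,
-M, -ML, -N, -V, -PKD) are too divergent for a single generic ion-channel
profile to separate. `trpprof` rebuilds, from first principles, the
computational toolbox needed to study such a superfamily:

* position-specific **profile models** with local Viterbi log-odds scoring
  and Gumbel-calibrated E-values;
* an **iterative inclusion search** that grows a family model from a single
  transmembrane seed;
* **subfamily detection** by agglomerative encoding-cost clustering, and
  one discriminative profile per major subfamily plus a pooled
  "unspecific" model;
* **competitive best-hit classification** with unspecific-model exclusion
  and E-value/coverage filters;
* **tandem ankyrin-repeat counting** by greedy non-overlapping profile
  tiling, with a fragmented-gene-model flag for the long-repeat (TRP-N-like)
  family, whose ~28-unit array is thought to act as the gating spring of a
  mechanosensitive channel;
* **redundancy reduction** by greedy centroid clustering at a sequence
  identity threshold;
* **mechanism-specific position analysis**: per-column physico-chemical
  conservation (0–11), a two-group multi-Relief (mR) statistic with a
  permutation z-test, a complete-disjunctness filter, and push/pull/neither
  classification of query sequences.

Because the real superfamily lives in external databases, the package
ships a seeded synthetic generator that emulates the statistical structure
of the data — six divergent subfamilies over a shared transmembrane core,
family-specific N-terminal ankyrin arrays, unrelated decoys, fragmented
variants, and a push/pull alignment with planted discriminative columns —
so that every stage is testable with known ground truth.

# Profile models

A profile is built from an alignment by treating every column with at most
50% gaps as a match column. Match emissions use a single
background-mixture pseudocount weight $w$ (default 2 effective counts):

$$ e_j(a) = \frac{c_j(a) + w\,q(a)}{n_j + w} $$

where $c_j(a)$ counts residue $a$ in column $j$, $n_j$ is the number of
residues in the column and $q$ the background (uniform by default).
Transitions among match/insert/delete states are estimated from the
observed state paths with the same scheme ($w/3$ per outgoing edge).
Dirichlet-mixture priors are deliberately avoided: a single-weight mixture
is transparent and lets every emission be recomputed by hand in tests.

Scoring is **local Viterbi log-odds in bits**: the best-scoring local
alignment path (entry into and exit from any match state is free, insert
emissions equal the background, deletes are silent). Viterbi rather than
forward scoring keeps the score a deterministic function of a single path,
which makes an exhaustive path-enumeration oracle possible; the trade-off
is that scores are not comparable to forward-algorithm scores of other
software, and the package never pretends they are. The reported envelope
is the residue span of the optimal path, and model coverage is the number
of match states used divided by the model length.

E-values come from a Gumbel law fitted to the scores of `n_samples`
(default 200) random background sequences by the method of moments
($\hat\lambda = \pi/(s\sqrt 6)$, $\hat\mu = \bar x - \gamma/\hat\lambda$);
then $E = N \exp(-\hat\lambda(S - \hat\mu))$ for a database of $N$
sequences. The method-of-moments fit is closed-form and seed-deterministic,
which matters more here than the small efficiency gain of maximum
likelihood.

The iterative search starts from a single-sequence profile of the seed
(pseudocounts only), scans the database, includes every hit with
$E < 10^{-20}$ (strict inequality, default 5 iterations), realigns the
included set to the model and rebuilds. The transmembrane seed itself is
the Kyte–Doolittle predicted membrane region (window 19, threshold 1.6,
runs of ≥6 qualifying windows merged) plus 20 flanking residues on each
side. The flank is configurable because two conventions (20 and 25) are in
circulation for this kind of seed; the default is 20 and the two are not
silently reconciled. The hydropathy predictor is a deliberately simple,
fully reproducible stand-in for dedicated TM-topology tools.

# Subfamily detection

Detection is agglomerative: start from singletons, always apply the merge
with the smallest increase in total encoding cost (ties broken by the
lexicographically smallest pair of cluster labels), record the whole
trajectory down to one cluster, and return the partition at the global
cost minimum.

The encoding cost of a cluster is the column-wise negative log marginal
likelihood of its residues under a symmetric Dirichlet–multinomial with
concentration $\alpha = 1/20$ per residue (one pseudo-observation per
column in total):

$$ \mathrm{cost}(\mathcal C) = -\sum_j \log
   \frac{\Gamma(A\alpha)}{\Gamma(n_j + A\alpha)}
   \prod_a \frac{\Gamma(c_j(a) + \alpha)}{\Gamma(\alpha)}, \qquad A = 20 $$

This is an MDL-style criterion in the spirit of Bayesian subfamily
encodings: the marginal likelihood itself pays for model complexity, so no
explicit per-cluster parameter penalty is added. We initially considered a
BIC-style cost (per-cluster penalty $\tfrac12(20{-}1)K\log n_c$), but a
short calculation shows that with ~19 free parameters per column the
penalty exceeds the maximal attainable likelihood gain of any split unless
clusters hold more than roughly two dozen members — such a cost can never
separate small planted families, and an exhaustive check over all set
partitions at $n = 8$ confirms it. The Dirichlet–multinomial cost
separates the planted families at four members per family while still
collapsing a homogeneous family into one cluster, and remains closed-form
and exhaustively checkable (the test suite enumerates all 4140 partitions
of 8 sequences and compares costs).

Major subfamilies are the clusters holding at least 5% of the sequences
(the threshold separates real families from spurious dust in the synthetic
regime; it is a config knob). One profile is built per major cluster; the
**unspecific model** is built from *all* rows pooled and plays the role of
a generic ion-channel family model that matches members of every
subfamily.

# Classification

Scans emit hits passing `E < threshold` (strict) with model coverage at
least the coverage threshold; coverage is measured on the model, not the
protein, so a short fragment can still achieve full coverage of the domain
model. Two named threshold profiles exist: `"census"`
($E < 10^{-25}$, coverage ≥ 80%) for database-wide surveys and
`"genome"` ($E < 10^{-10}$, no coverage term) for per-genome scans; both
mirror common practice of using a stricter filter when the database is
large and redundant.

Per protein, the **best hit** is the smallest E-value (ties: larger bit
score, then lexicographic model name — toy models can tie exactly, real
ones essentially never). If the best hit is the unspecific model the
protein is *excluded* (it is more likely a distant non-TRP channel than a
member of any subfamily); with no hits it is *unclassified*; otherwise the
verdict is the best hit's subfamily. Benchmarking reports per-family
sensitivity and selectivity with absent (not zero) metrics for empty
families, plus macro averages.

# Repeat counting

The ankyrin unit profile (33 columns by default, the canonical repeat
length) is scanned against the protein; the best local hit ending at every
sequence position is a candidate. Candidates matching fewer than 80% of
the unit model's columns are discarded *before* counting — this
operationalizes the "report the lower number" convention for tandem
repeats, where trailing half-units must not inflate the count. Greedy
tiling accepts candidates in decreasing bit-score order, rejecting any
that overlaps an accepted unit by more than 10% of the unit length
(tandem units abut tightly; forbidding all overlap undercounts at noisy
boundaries). Because a strong unit's extended alignment can shadow a
weaker neighbour's own best path, intervals still uncovered after a tiling
round are re-scanned until no new hit clears the threshold; the default
per-unit threshold is the 99th percentile of the model's calibrated
random-score distribution.

A TRP-N-like verdict with fewer than 27 counted units is flagged as a
fragmented gene model; 27 itself is not flagged. The rule is scoped to the
long-repeat family only — short-repeat families legitimately carry few
units.

# Redundancy clustering

Pairwise identity is computed from a global Needleman–Wunsch/Gotoh
alignment (match +1, mismatch −1, gap opening 10, gap extension 1, a gap
of length $g$ costing $10 + g$), as 100 × matches / alignment columns,
excluding columns inside terminal gap runs of either sequence so that a
fragment can be 100% identical to its full-length parent. The alignment
kernel is compiled code; the test suite cross-checks its optimal scores
and identities against an independent aligner.

Greedy clustering processes sequences longest-first (ties by id); each
sequence joins the *first* centroid with identity strictly above the
threshold (80% by default), else founds a new cluster — first-match
semantics, matching the behaviour of the standard centroid-clustering
tools this emulates. Two contract properties follow by construction and
are audited on every output: members exceed the threshold to their
centroid, and centroid pairs do not. At the exact threshold boundary the
strict `>` rule governs: a pair at exactly 80% identity does not join.

# Mechanism-specific positions

The conservation score counts, out of a fixed table of ten
physico-chemical properties (hydrophobic, polar, small, tiny, aliphatic,
aromatic, positive, negative, charged, proline), how many have a uniform
status across the column — possessed by all residues or by none — with 11
reserved for a perfectly conserved, gap-free column and any gap forcing
the score to 0.

The multi-Relief statistic is computed in its deterministic all-pairs
form: per column, the mean residue-mismatch over cross-group pairs minus
the mean over within-group pairs (gaps count as a 21st symbol), giving
$\mathrm{mR} \in [-1, 1]$. The original multi-Relief formulation weights
by nearest neighbours; in the two-group, well-separated regime used here
the all-pairs form ranks columns identically while being exhaustively
checkable by pair enumeration, and that is the property the test suite
asserts. Significance uses a label-permutation z-test (default 1000
shuffles, seeded): columns with $z > 3$ (strict, one-sided, no
multiple-testing correction — a deliberate mirror of the filtering
practice this reimplements, noted rather than "fixed") pass; columns with
zero permutation spread have no z and never pass. Significant columns are
then kept only if **completely disjunct** — the observed push and pull
residue sets share no symbol, gaps included.

Queries are excluded from all group statistics. At each disjunct site a
query residue votes push, pull, or neither (gaps vote neither —
conservative); the overall call is push or pull only if *every* site
agrees, otherwise ambiguous.

# The synthetic generator

The generator defines the study conditions, and its defaults were fixed
before any acceptance measurement:

* **Six subfamilies, 30 members each**, over a 240-residue transmembrane
  core with six 21-residue membrane helices; subfamily consensus at
  per-site divergence 0.5 from a common ancestor, members at 0.10 from
  their consensus. The real subfamilies are ancient and highly divergent;
  0.5 vs 0.10 gives the same qualitative regime — between-family identity
  near the twilight zone, within-family identity around 80% — without any
  claim to match real TRP divergence statistics, which are not known in a
  form usable here.
* **Substitutions only**, uniform over the 19 alternatives — except inside
  membrane helices, where replacements are drawn from the hydrophobic
  alphabet {A, C, F, I, L, M, V}. Membrane spans conserve hydrophobicity in
  real proteins, and without this constraint the hydropathy of diverged
  members decays to the detection threshold, which no real superfamily
  does. No indels occur inside the core, so planted alignments stay
  column-addressable; indels enter only through fragmentation.
* **Ankyrin arrays**: family 1 carries 28 units (TRP-N-like gating
  spring), family 2 carries 11 (TRP-A-like), families 3 and 4 carry 6 and
  4; units are 33 residues, each a copy of one unit consensus mutated at
  0.15 per site — within-protein repeat units are noticeably divergent in
  real proteins, and 0.15 keeps per-unit signal unambiguous.
* **Decoys** are i.i.d. uniform-background sequences of length 100–800.
  Uniform background is the simplest null; real composition can be passed
  as a config option.
* **Push/pull preset**: 10 push, 10 pull and 4 query rows over 300
  columns; 17 planted completely disjunct columns whose per-group residue
  sets have size 1 or 2 (specificity-determining positions are
  near-invariant within groups); other columns carry a shared consensus
  with noise 0.1; queries copy pull-set residues at every planted site,
  emulating paralogs that all comply with the pull mechanism.
* **Fragmentation** removes at least two whole units from the N-terminus
  of selected records, leaving the core intact — the signature of gene
  models with missing exons or misannotated start codons.

What the generator does **not** emulate: realistic amino-acid
composition, site-rate heterogeneity, indels within domains, phylogenetic
correlation among members (members are i.i.d. around their consensus), or
repeat-unit homogenization by concerted evolution. Passing tests therefore
demonstrate the correctness and internal consistency of the algorithms
under a clean planted model, not their performance on real proteomes,
where alignment quality and gene-model errors dominate.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in every in-memory object; files use
  0-based conventions only where the format demands it (BED-like repeat
  tables, specificity column tables) and say so in a header line.
* Emission/transition vectors are checked to sum to 1 within 1e-9 in the
  test suite after every build and rebuild.
* A sequence with no predicted membrane helix yields a "no TM region"
  signal (`NULL`), distinct from an error; an all-gap column has an absent
  conservation score; a family with no records reports absent metrics; a
  permutation-degenerate column has an absent z.
* Merge ties in subfamily detection and score ties in classification and
  tiling all have deterministic, documented tie-breaks, so a seed fully
  determines every output.
* All randomness (generation, calibration, permutation, fragmentation)
  flows from explicit integer seeds; the pipeline derives stage seeds from
  one top-level seed.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes in a few minutes on one core: the six-family
benchmark trains on 15 and holds out 15 members per family (90 held-out
proteins); subfamily detection runs on up to 180 rows × 240 columns;
specificity uses 1000 permutations over 300 columns; redundancy
clustering uses 200 channel regions; repeat counting uses the full
28-unit, 1164-residue TRP-N-like protein. The exhaustive oracles
(path enumeration, all set partitions, all pair mismatches, all hit
subsets) are run at the largest sizes where enumeration is exact and
fast (3 model columns, 8 sequences, 5 hits).

# Known limitations

* Viterbi bit scores are not forward scores; E-value calibration absorbs
  part of the difference but values are not interchangeable with other
  software's.
* The Gumbel fit uses random sequences of one fixed length; scores of much
  longer targets are slightly conservative (more chances for a high local
  score), which is acceptable at the thresholds used here.
* The unspecific model is a pooled profile over the detected subfamilies,
  not an independently curated generic channel model; its exclusion
  behaviour therefore reflects the pooled training set.
* Greedy centroid clustering is order-dependent by design (longest-first,
  first-match); it guarantees the two audit properties, not a globally
  optimal clustering.
* The multi-Relief all-pairs form and the nearest-neighbour original can
  rank columns differently when groups are internally heterogeneous; the
  package targets the well-separated two-group regime.
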