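---
title: "Fragment-based structural motif prediction: models, parameters, and design choices"
author: "pentascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based structural motif prediction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentascan)
```

## The problem and the model

A transcription factor bound to DNA in a crystal structure encodes, in its
atomic contacts, a preference over DNA sequences. Threading makes that
preference explicit: replace the DNA bases with a candidate sequence while
keeping backbone and protein fixed, score the interaction, repeat for every
candidate. Exhaustive threading costs `4^L` energy evaluations for an
`L`-bp site and stops being practical around `L = 8`; TF dimer sites of 12
bp would need 16,777,216 evaluations. `pentascan` instead scores every
5-bp window of the site under all `4^5 = 1024` permutations —
`(L − 4) × 1024` evaluations in total — and reconstructs the full-length
preference from the fragment tables. The package also implements the
exhaustive algorithm (`score_full_length_direct()`), capped at a
configurable site length, as the internal reference.

The core modelling assumptions are:

1. **Rigid threading.** Base replacement is a rigid superposition of a
   standard-geometry base onto the old base's reference frame (least-squares
   frame fit on the ring atoms: origin at the glycosidic nitrogen, x toward
   the C1' attachment, z along the base-plane normal). The backbone, sugar,
   and protein are untouched, and the paired strand always carries the
   complement. DNA deformation in response to sequence is ignored.
2. **Window-local energetics.** A fragment's score depends only on the 5
   threaded positions (multibody triplets fully inside the window;
   electrostatic pairs restricted to the window's base pairs). This is what
   makes fragment scores composable and is also the approximation the
   pentamer algorithm makes relative to full-length threading: interactions
   spanning fragment borders are seen by several overlapping windows rather
   than once.
3. **Additive reconstruction.** The composed score of a full-length
   sequence is the sum of its overlapping pentamer scores (Kmer-Sum), or,
   at the PFM level, the sum of per-fragment column counts (PWM stacking).

## The integrative energy

`E_IE = W_MB·E_MB + W_E·E_E` with both components min–max normalized over
the permutation set they belong to. Defaults `W_MB = 1`, `W_E = 0.5`: the
electrostatic channel is down-weighted because a knowledge-based potential
already captures electrostatics implicitly, and with only dozens of
non-redundant TF–DNA complexes available there is no training set large
enough to fit the weights. Lower `E_IE` is more favorable: mean-force and
Coulomb scores of favored contacts are negative, min–max normalization is
monotone, so significance selection takes the **low** tail.

**Multibody potential** (`train_mb_potential()`): counts of
(amino-acid type, forward-strand trinucleotide, distance-bin) observations
over a training set, converted by
`−ln((observed + q)/(expected + q))`. Choices that the potential's
published description leaves open, fixed here and recorded in the
potential's metadata:

- *Binning*: 0–15 Å in 1-Å bins. The triplet center (mean of the three
  glycosidic-N positions) sits 4–12 Å from contacting residues' Cβ in
  typical interfaces; 15 Å keeps a margin without counting bulk.
- *Reference state*: product of the (AA, triplet) marginal and the
  distance marginal — the conditional-frequency ratio standard for
  mean-force potentials. A cell observed exactly as often as the marginals
  predict scores 0.
- *Pseudocount*: `q = 0.5` keeps every cell finite under the severe
  low-count regime of small training sets.
- *Strand convention*: forward-strand triplets read 5'→3' only, so a
  fragment's multibody term is a function of the fragment sequence alone.
- *Glycine*: a virtual Cβ is built from N, Cα, C by standard tetrahedral
  placement, so every residue type contributes.

**Electrostatics** (`score_electrostatic()`): Coulomb's law per atom pair,
`k_e N_A (q_a e)(q_b e)/(ε d)`, in J/mol (the scale is irrelevant after
normalization). Two channels:

- *Hydrogen bonds*: hydrogen-to-acceptor pairs with
  `1.5 ≤ d ≤ 2.9 Å` — the typical H···acceptor distance range. Acceptors
  are O/N/S atoms with lone pairs per standard residue templates. No
  angular criterion is applied; the distance window alone defines the
  channel, which keeps the term cheap and parameter-free. Input structures
  are assumed protonated (hydrogens are *not* placed by this package).
- *π interactions*: an aromatic residue (Phe/Tyr/Trp/His) and a base whose
  rings approach within 4.5 Å (any ring-atom pair) are scored **once** per
  residue–base pair, using the summed ring charges at the
  centroid–centroid distance — a deliberate, documented simplification of
  electron delocalization. An atom pair lying inside both windows
  contributes to both channels.

The dielectric constant defaults to `ε = 4.0`, a common effective value
for a partially buried protein–DNA interface; it is configurable
(`physical_constants(epsilon = )`) and, like every purely multiplicative
constant, cancels in the normalized scores.

Partial charges are read from a plain-text table
(`residue atom charge` rows plus a `[pi_atoms]` section). The packaged
default is a force-field-inspired set authored for this package covering
the 20 amino acids and four deoxyribonucleotides; users with their own
charge derivation substitute their file. Atoms missing from the table are
skipped with one aggregated warning (or, on request, a hard error).

## Fragment scoring and its exact factorization

Because threading leaves every glycosidic nitrogen and all backbone atoms
in place, triplet centers are sequence-independent and the energy of a
window decomposes exactly: the multibody term over (triplet position,
triplet identity) and the electrostatic term over (position, base
identity) — each base identity at each window position is evaluated once
(20 structures instead of 1024) and the 1024 scores are composed by index
arithmetic. This is an implementation device, not an approximation: the
test suite threads sampled permutations explicitly and verifies equality
to machine precision, and the full-length direct path always uses explicit
threading.

Normalization is **per fragment**: each pentamer's raw components are
min–max normalized over its own 1024 permutations before weighting. A
joint normalization across fragments was considered and rejected as the
default because fragments differ in contact density, and per-fragment
normalization gives each window the same dynamic range; composed Kmer-Sum
scores are used as-is without re-normalization.

## Motif reconstruction and significance

"Statistical significance at 0.01 normalized by the length" is read as a
Bonferroni-style `α = 0.01 / L` on one-tailed lower-tail p-values, with two
distribution models: a normal fit to the empirical score distribution
(default) and an empirical-percentile mode. Per-pentamer selection in PWM
stacking uses `0.01 / 5` for symmetry. The selection is never empty — a
degenerate (zero-variance) distribution or an empty tail returns the single
best-scoring sequence with a warning. Selected sequences enter the PFM
unweighted, one count each; a score-weighted PFM was considered and left
off by default since the selection step already conditions on score.

Kmer-Sum keeps the full `4^L` composed-score vector in memory for
`L ≤ 16`; scores are indexed lexicographically and sequence strings are
only materialized for selected entries.

## PWM evaluation

Information content per column, `2 + Σ m_B log2 m_B` bits (base-2
throughout; the "2 +" offset only makes sense in bits). IC-weighted column
correlation `PCC × IC(ref)/2` with the 0.25 correctness cutoff; a uniform
column has undefined correlation, which is defined here as value 0,
incorrect, and flagged — a prediction with no signal should not count as
correct. Alignment of predicted to reference PWMs is not specified by the
metrics themselves; this package slides the prediction over the reference
at all offsets and both orientations (reverse complement = reversed
columns + A↔T/C↔G row swap), maximizes the summed IC-weighted PCC,
requires ≥ 5 overlapping columns, and breaks ties toward the smaller
|offset|, then forward orientation. The averaged Kullback–Leibler
divergence over the aligned columns uses a `1e-4` frequency pseudocount and
is reported both summed (primary) and per column.

## The synthetic fixture generator

`build_bdna()` constructs a rigid, straight, idealized B-DNA duplex (rise
3.38 Å, twist 36°/bp) from idealized nucleotide geometries expressed in
the package's base reference frame, with Watson–Crick partners placed by
transforms fitted once to canonical heavy-atom hydrogen-bond distances
(N1–N3 2.82 Å and N6–O4 2.95 Å for A:T; O6–N4 2.91, N1–N3 2.95, N2–O2
2.86 Å for G:C; C1'–C1' 10.44 Å). `build_toy_complex()` adds minimal
protein "probe" residues whose interaction atoms sit at exact prescribed
distances from named base atoms; the placement direction is chosen
deterministically to maximize clearance from all other partner atoms, so a
probe prescribed at 2.0 Å contributes exactly one hydrogen-bond pair and
one at 3.0 Å contributes none.

What the fixtures emulate: duplex pairing and complementarity, realistic
helix dimensions, analytically known contact geometry, and planted
sequence preferences (`plant_landscape()`: Gaussian baseline noise minus a
per-matching-position bonus). What they do not emulate: sequence-dependent
DNA shape, bending, groove-width variation, crystallographic disorder,
chemically complete side chains, or realistic charge environments. Passing
tests therefore demonstrate the *correctness of the machinery* — parsing,
threading, window logic, composition, selection, metrics — not the
*biological accuracy* of predictions on real complexes, which depends on
the training set behind the multibody potential and the quality of the
input structure.

## Numerical and interface choices

- **Indices are 1-based and inclusive** on the forward strand everywhere,
  the R convention; the reverse strand is addressed only through the
  pairing map.
- Contact detection counts a position as TF-contacted if either base of
  the pair has a heavy atom within the 5-Å cutoff (hydrogens excluded).
  Flanking bases (default 2 per side, so an *n*-bp core becomes *n* + 4)
  are taken from the solved duplex; if the structure runs out, the site is
  truncated with a warning — no DNA is built de novo.
- Duplex pairing on input is inferred geometrically (complementary
  identities, glycosidic N within 10 Å, minimal distance, antiparallel
  order enforced) across the two largest DNA chains; modified residues are
  skipped with a warning.
- Min–max normalization of an all-equal score vector returns zeros with a
  warning rather than dividing by zero.
- Fragment score tables can be cached as CSV keyed by complex, offset, and
  an energy-configuration hash, separating the energetics from motif
  post-processing; results are invariant to fragment and permutation
  evaluation order (everything is evaluated serially and deterministically).
- The direct-enumeration cap defaults to `L = 12` (the largest size the
  method's own comparisons contemplate); beyond it the function refuses
  and points to the pentamer path.

## Problem sizes used in the checks

The packaged checks run on deliberately small instances chosen to keep the
whole suite interactive while still exercising every code path at full
combinatorial width: 7–12-bp duplexes with 1–2 probe residues, complete
1024-permutation fragment tables, an exhaustive 16,384-sequence (L = 7)
comparison of composed versus in-place scores, and planted-motif recovery
at L ∈ {6, 8, 10} with a bonus-to-noise ratio of 10 — the regime where
recovery must be exact and any failure indicates a defect rather than
noise.

## Known limitations

- Rigid threading ignores induced fit and sequence-dependent DNA shape; the
  idealized fixture helix compounds this for synthetic tests.
- The multibody potential shipped untrained is a zero table; meaningful
  predictions require training on a curated non-redundant complex set,
  which is the user's responsibility (and the dominant accuracy factor).
- The hydrogen-bond channel has no angular term and assumes the input is
  protonated; structures without hydrogens silently lose that channel.
- The default charge set is a pragmatic force-field-inspired compilation,
  not a fitted model; per-study charge derivations should replace it.
- TF dimers with variable spacers are handled by running each half-site
  separately; no spacer model is provided.
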