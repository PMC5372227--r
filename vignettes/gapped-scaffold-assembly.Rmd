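---
title: "Gapped scaffold assembly from top-down sequence tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapped scaffold assembly from top-down sequence tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tagstitch)
```

## The problem

De novo sequencing of intact proteins from top-down MS/MS data yields
accurate but fragmentary sequence reads: long stretches of the protein are
reconstructed, but they rarely join into a complete sequence. `tagstitch`
addresses the next step: deciding whether two reconstructed fragments
belong to the same protein and, if so, estimating the monoisotopic mass of
the unobserved subsequence separating them, so that fragments can be
chained into long *gapped scaffolds* — alternations of confident sequence
stretches and mass-annotated gaps.

The raw material is a set of *k-tags*: short amino-acid words (default
`k = 4`) read off `k + 1` spectrum peaks whose consecutive neutral-mass
differences each match a residue mass within `2 * epsilon`. A tag carries
an *offset* — the mass of its leftmost peak — which locates it on the
(unknown) protein's mass axis up to a constant shared by all tags of one
spectrum.

## Tag generation

Deconvoluted spectra (msalign-style neutral-mass peak lists) are
preprocessed by removing water-loss peaks (a peak is dropped when a peak
one water mass above it is at least as intense) and then reflecting every
peak about the precursor mass, so that prefix- and suffix-type fragment
series reinforce each other. The order — losses first, reflection second —
prevents loss artifacts from being duplicated into the reflected series;
the definition of a water loss as the *less intense* member of the pair
keeps the rule from deleting real signal. Both choices are ours: the
underlying procedure fixes neither.

Each preprocessed spectrum becomes a *spectrum graph*: one vertex per
peak, scored by intensity, and an edge wherever two peaks differ by a
residue mass within `2 * epsilon` (isoleucine/leucine are isobaric and
always labeled `L`). From every weakly connected component we extract the
single directed path maximizing the summed vertex scores, by exact dynamic
programming over the mass-ordered DAG; ties are resolved toward the
smaller starting mass, then the lexicographically smaller label string, so
results are reproducible. Every window of `k` consecutive edges of such a
path yields one tag.

## Tag and string convolution

For two k-mers, the *tag convolution* is the multiset of offset
differences `o(t2) - o(t1)` over all tag pairs matching them — restricted,
for top-down data, to pairs from the same spectrum, because offsets of
different spectra do not share a constant. The *string convolution*
`T(s1, s2)` extends this to whole fragments: every pair of k-mer windows
contributes its tag convolution shifted by minus the mass of `s1` from the
window onward and minus the mass of `s2` before the window. With these
shifts, a tag pair bridging two genuine fragments of one protein
contributes exactly the mass of the separating subsequence, regardless of
which windows the tags hit. Contributions from the reversed pair
(`rev(s2)`, `rev(s1)`) — the natural home of suffix-series tags — are
accumulated and merged, which makes `T` symmetric under double reversal:

```{r}
tags <- tibble::tibble(
  spectrum_id = "sp1",
  sequence = c("SGAT", "GATF"),
  offset = c(500, 500 + residue_mass("S"))
)
conv <- string_convolution(tags, "SGAT", "GATF")
tally_differences(conv)
```

Raw differences are kept exact; no tolerance grouping happens at this
stage, so no double rounding can occur before binning.

## Gap estimation

Offset differences can be large, and deconvoluted masses carry the
well-known ±1 Da monoisotopic-assignment errors, so raw differences are
*scaled* by `10^h` (default `h = 4`) and rounded, and independently
*binned* to integer daltons. Candidate gaps are binned differences within
`[0, Gmax]` (default 3000 Da) with multiplicity at least `Bmin` (default
20). Among the candidates of maximal multiplicity, each is scored as
`Score(db) = mu(db) + mu(db - 1) + mu(db + 1)` — absorbing the ±1 Da
errors — and the top score wins (ties: smallest bin). The reported
estimate is the most frequent scaled difference inside the winning bin
divided by `10^h` (ties: smallest value). Rounding is half-away-from-zero
throughout; the choice matters only on exact half values and is documented
because the procedure does not fix it.

A candidate must finally pass a coverage *support check*: with
`m* = Amin - k + 1` (defaults give `m* = 3`), the supporting tag windows —
distinct k-mer start positions per string, counted once however many
spectra echo them — must number at least `m*` for each string, or `m* + 1`
for one and `m* - 1` for the other; failing that, if both counts are at
least `m* - 1`, a neighbouring bin supported at (`m* - 1`, `m*`) in either
assignment rescues the candidate. We apply the two-sided clauses
symmetrically in the string roles; the asymmetric reading is not better
determined by the rule's coverage rationale, and the symmetric one is the
weaker (more admissive) assumption. Only the single best candidate bin is
ever examined: if it fails support, the hypothesis is rejected rather than
falling through to weaker bins, keeping the decision rule monotone in
`Bmin` (raising `Bmin` can only turn accepts into rejects).

## Assembly

Gapped paths are initialized from the input fragment strings and examined
pairwise in a fixed scan order (ascending input index; rescan from the
start after every merge), so assembly is deterministic. For a pair we try,
in order, the four orientation combinations — as given, second reversed,
first reversed, both reversed — and within each: appending (gap estimation
between the last fragment of one path and the first of the other), then
embedding either path into a sufficiently large gap of the other. A gap
can accommodate a guest when its estimate covers the guest's total mass
within the relative tolerance `eps_abs` (default 10 ppm, taken of the
larger of the two offsets compared, since the rule specifies ppm but not
the reference magnitude); after placing the guest, its end offset must not
overrun the start of the fragment following the gap, again within the ppm
tolerance, and the remainder of the original gap becomes a trailing gap
(clamped at zero when within tolerance). The first success ends the
search for that pair.

## The synthetic-data generator

Because the method's natural inputs are large proprietary spectral
datasets, the package ships a generator producing every input with known
ground truth. A protein is drawn uniformly over the 19 mass-distinct
residues; each simulated spectrum covers a contiguous window of 50–100%
of the sequence (top-down spectra interrogate the whole precursor;
truncation emulates incomplete fragmentation coverage toward the termini)
and contains the cumulative residue-mass sums from the window start, each
cleavage site emitted with the coverage probability (default 0.8),
log-normal intensities, Gaussian mass error (default 1 mDa, well inside
the 4 mDa matching tolerance), and optionally an exact ±1 Da shift per
peak with configurable probability, emulating deconvolution errors.
Fragment strings are cut from the protein with configured lengths and gap
sizes (defaults: four 16-residue fragments separated by 5, 8 and 11
residues) and may be emitted reversed. The reference conditions — a
300-residue protein, 200 spectra — are the package's reproducible study
scale; the test suite uses scaled-down scenes (proteins of 50–160
residues, 30–70 spectra) where the property under test does not need the
full scale.

What the generator does *not* emulate: charge-state envelopes and
deconvolution beyond the ±1 Da shift model, chimeric spectra, intensity
physics, modified residues, and non-uniform residue composition. Passing
tests therefore demonstrate the correctness of the combinatorial and
statistical machinery under controlled conditions, not performance on
real instrument data.

## A known failure mode: reflected-series correlation

Peak reflection makes every spectrum contain, alongside each observed
fragment series, its mirror image. When a *wrong* hypothesis is tested —
e.g. a fragment against the reversed copy of a following fragment — pairs
of one direct-series and one mirror-series tag all contribute the *same*
shifted difference within a spectrum: a per-spectrum constant of the form
`Mass(window right of s2) + water − Mass(window left through s1)`. A
single well-covered spectrum can thus push a spurious bin past `Bmin`
with plausible window support. This is intrinsic to the method — real-data
applications of this kind of procedure occasionally accept such a join,
which is then recognized by visual inspection of the scaffold — and is
deliberately not "fixed" here. Two mitigating facts: the spurious constant must land inside
`[0, Gmax]` to be considered at all, which for fragments far from a
protein's mass midpoint it rarely does; and correct-orientation
hypotheses accumulate their true gap across *all* spectra, so when a
correct combination is tried first it wins. The orientation-logic tests
exploit the first fact by anchoring fragment blocks at a terminus of a
300-residue protein, where every spurious constant is provably out of
range; the cross-protein negative control, run at the reference
conditions, bounds the false-merge rate instead. Rare cross-protein false
merges through the combination of a chance k-mer collision and this
correlation remain possible at any scale.

## Parameter summary

| parameter | default | unit | role |
|---|---|---|---|
| `k` | 4 | residues | tag length |
| `epsilon` | 0.004 | Da | peak-difference tolerance (edges use `2*epsilon`) |
| `gmax` | 3000 | Da | maximum acceptable gap |
| `bmin` | 20 | count | minimum binned multiplicity of a candidate |
| `amin` | 6 | residues | minimum covered amino acids per string (`m* = amin - k + 1`) |
| `eps_abs_ppm` | 10 | ppm | offset-comparison tolerance in embedding |
| `h` | 4 | — | scaling exponent for scaled differences |

Defaults are the values used for top-down protein data at realistic
spectral depth; `bmin` should be lowered for small spectral sets and raised
for very large ones, since bin multiplicities grow with the number of
spectra spanning a junction.

## Worked example

```{r}
cfg <- sim_config(protein_length = 150, n_spectra = 60, coverage = 1,
                  mass_error_sd = 0,
                  fragment_lengths = c(12, 12, 12),
                  gap_lengths = c(4, 9), seed = 57)
protein <- simulate_protein(150, seed = 57)
sim <- simulate_spectra(protein, cfg)
tags <- generate_tags(sim$spectra)
frs <- simulate_fragment_strings(protein, cfg)

asm <- assemble_fragments(frs$strings, tags)
asm
glance(asm)
frs$gaps$gap_mass
```

The estimated gaps agree with the ground-truth separating masses to a few
mDa. The per-segment detail, including support counts for every accepted
gap, is available through `tidy()`:

```{r}
tidy(asm[[1]])
```
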