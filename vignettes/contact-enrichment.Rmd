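---
title: "Differential contact enrichment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential contact enrichment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`contactdelta` compares the amino-acid occupancy of residue–residue
contacts between two functional subgroups of an enzyme family — here
framed as hydrolases (H) versus transglycosidases (T) in glycoside
hydrolase family GH13, though nothing in the machinery is specific to
that family. The underlying assumption is evolutionary: residues in
spatial contact coevolve, so a contact that is structurally conserved
across the family but systematically occupied by different amino acids in
the two groups is a candidate determinant of the functional difference.

The pipeline has five stages.

**Contacts.** Residues $i$ and $j$ of one structure are in contact when
the minimum distance over all atom pairs is at most a cutoff $c$ and
$j - i \ge s_{\min}$. Two parameterizations are standard here:
$c = 5$ Å for amino-acid level work (enrichment, classification,
conservation) and $c = 6$ Å for pair-level and network work.

**Mapping.** Every dataset member is mapped onto a designated reference
structure position-by-position. Each reference contact is then, per
member, *shared* (mapped pair is a contact there), *absent* (mapped but
not a contact) or *unalignable* (an endpoint has no counterpart).

**Enrichment.** For a reference contact, endpoint and amino acid $aa$,
let $f_{aa,G}$ be the frequency of $aa$ at the mapped endpoint among the
group-$G$ members *sharing* the contact. The enrichment factor is

$$\Delta f_{aa} = f_{aa,T} - f_{aa,H} \in [-1, 1],$$

with the pair-level analogue defined over ordered amino-acid pairs at the
two endpoints. Because frequencies within a (contact, endpoint, group)
cell sum to one over observed amino acids, the deltas at a given endpoint
sum to zero, and swapping the group labels negates every delta — two
identities the test suite checks exactly.

**Classification.** A residue is transglycosidic if its $\Delta f > 0$,
hydrolytic if $< 0$, unclassified at exactly 0. A contact takes a group
label only when both endpoints agree; otherwise it is mixed (or
unclassified if either endpoint is). Each enzyme is then a point
$(n_H, n_T)$ — its hydrolytic and transglycosidic contact counts
normalized by its shared-contact count — and is assigned to the nearer
group centroid.

**Selection.** Mutation candidates must lie in conserved contacts, carry
a wild-type residue not enriched in the target group, and admit a
replacement that is. Pair-level selection further requires an extreme
pair enrichment and high betweenness centrality of both endpoints on the
α-carbon contact network, which prioritizes positions central to the
fold's interaction pathways.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cutoff` | 5 (aa-level), 6 (pair/network) | Å | the two standard contact-definition settings; inclusive comparison |
| `min_separation` | 2 | residues | drops $i,i{+}1$ bonded neighbours, which exist in every protein and carry no group signal; 0 restores the raw map |
| `scheme` | `all_atom` | — | side chains carry the signal; `ca` is available for coarse maps |
| alignment | BLOSUM62, open 10, extend 0.5 | score | needle-style defaults; a supplied FASTA alignment overrides the aligner and is the recommended path when an external (e.g. structural) alignment exists |
| `min_conservation_count` | 10 | members (of 14) | only contacts present in most of the family are interpretable across it |
| `wild_delta_max` | 0.0 | Δf | wild residue must not already be target-enriched; a stricter −0.2 reading is in circulation and exposed as a knob |
| `candidate_delta_min` | 0.2 | Δf | replacement must be clearly target-enriched |
| `pair_extreme_fraction` | 0.01 | fraction | pair-level candidates come from the extreme tails of the global pair-Δ distribution |
| `betweenness_fraction` | 0.10 | fraction | pair-level endpoints must be central; 0.20 is the wider screening setting, both are named in the criteria object |
| `denominator` | `sharing` | — | frequencies conditional on the contact existing; `group_size` is available and documented as changing Δ magnitudes |

# Numerical conventions and edge cases

* The distance cutoff is **inclusive** (≤); strictness is otherwise
  arbitrary at a measured boundary.
* Altloc duplicates resolve to the highest occupancy, ties to the first
  record in file; only the first model of multi-model files is read;
  waters are dropped everywhere; hydrogens participate in all-atom
  distances when present.
* Nonstandard residues with a standard parent (MSE→M, SEP→S, …) keep
  that identity; others become `X`, are retained for contact geometry,
  and are excluded from frequency counting without invalidating the
  contact for other members.
* A contact with no sharing member in one group has undefined
  frequencies: it is skipped and listed with a reason, never imputed.
  An amino acid unobserved in training has Δ = 0 and classifies as
  *unclassified* — the method never extrapolates beyond observed
  occupancies.
* Betweenness follows the unnormalized shortest-path definition over
  unordered pairs with endpoints excluded, computed by Brandes
  accumulation; correctness is anchored to an exhaustive
  path-enumeration oracle in the tests, not to any library.
  Disconnected pairs contribute zero. Top-percentile selection takes the
  $\lceil f n \rceil$ highest values and includes all boundary ties.
* Classification ties go to H, the conservative majority class in the
  datasets this method was designed around.
* Similarity coefficients are computed over the **intersection** of
  mapped shared contacts (absent/unalignable contacts are dropped, not
  imputed); fewer than 3 points or zero variance is *undefined*, reported
  as $r^2 = 0$ in the matrix ("no demonstrable similarity") so that
  outlier ranking is always well defined. One alignment is computed per
  unordered pair and inverted for the reverse direction, making the
  matrix exactly symmetric.
* The reference protein counts as a member of its own group and is
  included in the conservation denominator, so conservation scores lie in
  $(0, 1]$ and profiles are comparable across references.

# Open design choices

Several aspects of the procedure are genuinely underdetermined and were
fixed as follows:

* **Decision rule.** Group separation in normalized contact-count space
  does not by itself prescribe a classifier; nearest centroid is the
  simplest rule consistent with using the hydrolytic/transglycosidic
  contact relation, and a pure threshold on normalized $n_T$ (motivated
  by transglycosidic contacts being the dominant discriminator) is
  available via `rule = "t_threshold"`.
* **Conservation threshold reading.** "Above 10 of 14" is implemented
  inclusively (≥ 10); the knob accepts any count.
* **Pair extremes** are taken over the global distribution of pair
  enrichment values, not per contact.
* **Ligand proximity** is a soft preference: ligand-contacting positions
  are demoted to the bottom of the ranking rather than removed, since
  active-site positions can still be legitimate targets.
* **Ranking** is by enrichment gain (proposed minus wild, direction
  adjusted), ties broken by conservation then by distance to the active
  site (farther first, favouring non-obvious sites). The gain is the
  natural one-number summary of how strongly the evidence favours the
  swap; no canonical ranking exists for this problem.

# What the synthetic generator does and does not emulate

`synthetic_spec()`/`generate_dataset()` build two labelled groups
(default 4 T / 10 H, matching the canonical 14-member study design) of
60-residue structures on a serpentine-sheet scaffold: rows of residues
3.8 Å apart, rows separated by 4.5 Å, one α-carbon and one pseudo
side-chain atom per residue. Geometry is shared by all members, so
vertically adjacent residues across rows are in contact at 5 Å (the
diagonals appear only at 6 Å, giving the two cutoffs genuinely different
maps). Amino-acid identity is carried by residue names: a planted contact
endpoint receives the group's preferred residue with probability $p$
(the signal strength) and otherwise a uniform draw over the 18 residues
preferred by neither group, so $E[\Delta f] = \pm p$ exactly at planted
sites, $+1$/$-1$ at full signal, and the two groups are statistically
exchangeable at $p = 0$. Structural variation is emulated by contact
dropout: each non-planted contact is, with a configurable probability,
broken by displacing one endpoint residue out of the sheet plane (±6 Å,
sign chosen by grid parity so displaced neighbours cannot remain in
contact); the displacement also severs that residue's other scaffold
contacts, and the ground truth records the realized contact set of every
member. An optional outgroup protein uses a different serpentine geometry
and its own random sequence, standing in for the family outliers that
contact similarity should flag.

The generator validates the statistical machinery — frequency
normalization, signal recovery, classification separation, conservation
and similarity behaviour, selection logic — under known ground truth. It
does **not** emulate real side-chain packing, rotamers, insertions and
deletions (all sequences are equal length), domain architecture, or
phylogenetic correlation between members; passing tests therefore
demonstrate correctness of the computations, not biological performance
on crystal structures, which additionally depends on alignment quality
and dataset curation.

# Problem sizes in the test suite

The suite runs the study conditions at desk scale: the default 14-member
dataset for enrichment, classification and selection checks; 50 seeded
datasets for the normalization identity; 200 seeded replicates at
$p = 0.6$ for signal recovery (compared within three standard errors of
the closed form); 20 seeded datasets at $p = 0$ for the chance-level
classification null (a binomial test of prediction/truth independence at
$\alpha = 0.01$); 500 random graphs of up to 8 nodes against the
betweenness oracle; and a 200-per-group dataset for the large-sample
consistency of planted enrichment.

# Known limitations

* One chain per structure: the enzymes are treated as monomers, and
  multi-chain files are reduced to a selected chain.
* No phylogenetic down-weighting of redundant members and no
  pseudocounts; closely related members inflate frequency confidence.
* The built-in aligner is sequence-based; for distant homologs a
  structural alignment supplied as FASTA is preferable.
* No multi-site optimization: candidates are ranked individually even
  though specificity shifts may require coordinated substitutions across
  a contact network.
* Enrichment factors are qualitative guides, not quantitative activity
  predictions; they restrict the sequence space to explore, they do not
  replace experimental characterization.
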