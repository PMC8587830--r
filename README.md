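# contactdelta

Differential residue-contact enrichment analysis for decoding reaction
specificity in evolutionarily related enzyme families.

## The problem

Glycoside hydrolase family GH13 enzymes share a (β/α)₈ TIM-barrel fold and
cleave α-(1→4) glucan bonds through a double-displacement mechanism, but
they differ in what receives the cleaved glycosyl moiety: water
(hydrolases) or another sugar (transglycosidases). The residues steering
that choice are not confined to the active site, and picking mutation
targets outside it is hard. `contactdelta` implements a structure-based
answer: because residues in spatial contact coevolve to maintain structure
and function, the amino-acid composition of residue–residue contacts that
are *shared* across a family — but *occupied differently* by hydrolases and
transglycosidases — points at specificity determinants.

The package is aimed at protein engineers and structural bioinformaticians
who have a set of labelled structures (PDB/mmCIF) for two functional
subgroups of a family and want ranked, evidence-backed substitution
proposals for switching an enzyme's reaction preference in either
direction.

## The method

1. **Contact maps.** For each structure, residues i and j are in contact
   when their minimum interatomic distance (all atoms) is ≤ a cutoff —
   5 Å for amino-acid level analyses, 6 Å for pair/network analyses.
2. **Contact alignment.** Each structure is mapped onto a reference via a
   global affine-gap sequence alignment (BLOSUM62, gap open 10, extend
   0.5) or a user-supplied alignment; reference contacts are then
   *shared*, *absent* or *unalignable* per protein.
3. **Enrichment factors.** For contact endpoint (i,j) and amino acid *aa*,
   with f<sub>aaij,G</sub> the frequency of *aa* among group-G members
   sharing the contact:

   Δf<sub>aaij</sub> = f<sub>aaij,T</sub> − f<sub>aaij,H</sub>

   and analogously for ordered amino-acid pairs,
   Δf<sub>aapi</sub> = f<sub>aapi,T</sub> − f<sub>aapi,H</sub>.
   Positive values mark transglycosidase-enriched residues (pairs),
   negative values hydrolase-enriched ones.
4. **Classification.** Each contact is qualified transglycosidic (both
   endpoints Δ > 0), hydrolytic (both Δ < 0), mixed or unclassified; an
   enzyme's normalized (n_H, n_T) contact composition is assigned to the
   nearer group centroid.
5. **Conservation and similarity.** The conservation score of a reference
   contact is the fraction of dataset members sharing it; the squared
   Pearson correlation between two proteins' conservation-score vectors
   over their common contacts is a contact-similarity coefficient that
   separates family members from outsiders.
6. **Contact network.** The α-carbon contact graph is scored with
   unnormalized shortest-path betweenness centrality,
   BC(x) = Σ<sub>{u,v}</sub> σ<sub>u,v</sub>(x)/σ<sub>u,v</sub>,
   to prioritize structurally central residues.
7. **Site selection.** Substitution candidates must sit in conserved
   contacts (≥ 10 of 14 members by default), currently carry a residue
   with Δ ≤ 0, and admit an alternative with Δ ≥ 0.2 (signs mirrored for
   the opposite direction); pair-level selection additionally demands an
   extreme pair enrichment (top/bottom 1%) and both endpoints in the top
   betweenness decile. Ligand-contacting positions are demoted, not
   removed.

A synthetic-structure generator emits two-group datasets on a serpentine
sheet scaffold with amino-acid preferences planted at chosen contacts at a
tunable signal strength, so the whole pipeline is testable without any
structure downloads.

## Worked example

```r
library(contactdelta)

spec <- synthetic_spec(signal = 1, seed = 42)   # 4 T / 10 H, 60 residues
dsd  <- generate_dataset(spec, "demo")
structs <- read_dataset(dsd$manifest)
ds  <- prepare_dataset(structs, ref_id = "T01") # 5 A contact maps + maps
tab <- build_shared_table(ds)
#> shared_contact_table: 41 reference ('T01') contacts x 14 members (4 T, 10 H)

enr <- full_enrichment_table(tab)
enrichment_factor(tab, c(1, 20), "i", "W")$delta
#> [1] 1

loo <- classify_loo(tab, mode = "aa")
attr(loo, "accuracy")
#> [1] 1
head(loo[, c("id", "n_T", "n_H", "predicted", "truth")], 2)
#>    id n_T n_H predicted truth
#> 1 T01   7   0         T     T
#> 2 T02   7   0         T     T

cons <- conservation_profile(tab)
cand <- select_aa_level(tab, enr, cons, "H01",
                        selection_criteria("toT"), ds = ds)
head(cand[, c("position", "wild_aa", "proposed_aa", "wild_delta",
              "proposed_delta", "conservation_count")], 3)
#>   position wild_aa proposed_aa wild_delta proposed_delta conservation_count
#> 1        1       D           W         -1              1                 14
#> 2       11       E           Y         -1              1                 14
```

Reading: tryptophan fully replaces the hydrolase-preferred aspartate at
contact (1, 20) in the transferase group (Δf = +1), every enzyme is
classified correctly under leave-one-out, and the selector proposes the
planted transferase residues at fully conserved positions (14/14 sharing),
each with the maximal enrichment gain of 2.

The same steps are available from a shell via the installed `contactdelta`
dispatcher (`simulate`, `contacts`, `enrich`, `classify`, `conserve`,
`network`, `select`), e.g.
`contactdelta classify --manifest demo/manifest.tsv --ref T01 --out out/`.

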