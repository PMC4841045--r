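---
title: "Taxonomy-aware metaproteomics with peptax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomy-aware metaproteomics with peptax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptax)
```

## The problem

In shotgun metaproteomics a sample contains proteins from many organisms —
in an oral sample, human proteins next to proteins from dozens of bacterial
genera. Identification matches observed peptides against a concatenated
multi-organism database, and here taxonomy bites: closely related bacteria
share a large fraction of their tryptic peptides, and even human and
bacterial proteins occasionally contain identical sequences. A peptide
observed once cannot tell you *which* of its possible source organisms
produced it. Left unhandled, such peptides glue proteins from different
phyla into one protein group and donate intensity to organisms that may not
be present at all.

`peptax` implements a defensive analysis chain around this ambiguity:
restrict identification to peptides that are unambiguous at a chosen
taxonomic rank, place every peptide at the lowest common ancestor (LCA) of
its sources, and quantify taxa by a robust top-N intensity summary. A
built-in simulator provides ground-truth data so each guarantee can be
tested mechanically.

## The taxonomy model

A taxonomy is a rooted tree over the fixed rank order root, superkingdom,
phylum, class, order, family, genus, species. Two modeling choices matter:

* **Rank skipping is legal.** Real taxonomies jump ranks for some clades,
  so an edge phylum → genus is valid; only rank *inversion* is rejected at
  load time. Consequently the LCA is computed on actual nodes, never on
  ranks.
* **The host is an ordinary leaf** under its own superkingdom branch. A
  host/bacteria shared peptide then simply has LCA = root, and the
  phylum-level split rule below applies uniformly to host-vs-bacteria and
  bacteria-vs-bacteria sharing alike.

Because lineages that skip a rank have no node *at* that rank, the split
projection of a taxon is defined as the deepest lineage node whose rank is
at or above the split rank. For ordinary lineages this is exactly the
ancestor at the split rank; for skipping lineages it is the boundary node,
which keeps projections of different superkingdoms distinct.

Taxonomies are supplied as a flat TSV (`taxon_id`, `parent_id`, `rank`,
`name`) rather than parsed from a taxonomy dump: published trees for
specific studies are rarely distributed in dump form, and a flat dialect
keeps fixtures self-contained and versionable. Newick serialization is
included for interchange; it is implemented in-package because ranked
taxonomies contain unary internal nodes (root → superkingdom → phylum
chains), which the standard `phylo` representation of tree packages cannot
carry.

## In-silico digestion

`digest_protein()` enumerates every fragment whose boundaries are protein
termini or cleavage sites and whose internal cleavage-site count is at most
`max_missed_cleavages`. Defaults:

| parameter | default | why |
|---|---|---|
| `cleavage_residues` | K, R | trypsin/LysC chemistry |
| `block_proline` | `FALSE` | LysC cleaves K-P, and the common search-engine setting cleaves before proline; `TRUE` restores classical trypsin |
| `max_missed_cleavages` | 2 | standard search-space setting |
| `min_length` | 7 residues | shorter peptides are rarely identified confidently and dominate cross-organism collisions |
| `equate_il` | `FALSE` | database searching distinguishes I from L; MS cannot, so an I→L collapse is available for indexing |

Peptides containing ambiguous residues (B, J, O, U, X, Z) are excluded from
indexes — exact-string sharing logic is meaningless for them. Fragments
occurring at several positions of one protein collapse to a single
nonredundant index key. Overlap between databases is exact set arithmetic
on index keys with the union as denominator, which makes the shared
percentage symmetric and bounded by construction.

## Split-by-taxonomy identification

`group_proteins_split_by_taxonomy()` gives the package its central
guarantee. With split rank *r* (phylum by default):

1. every observed, matched peptide is projected to the split rank; peptides
   with ≥ 2 distinct projections are **discarded from identification**;
2. the remaining peptide→protein map is partitioned by the proteins' split
   taxon, so no later step can bridge taxa;
3. within a partition, proteins with identical identifying-peptide sets
   merge, and any protein whose set is a subset of a larger group's is
   subsumed into it (greedy, largest set first, lexicographic accession
   tie-break). This is the simplest parsimony scheme consistent with the
   protein-group concept and the unique/razor peptide distinction; search
   environments do not document their exact algorithm, so determinism and
   simplicity were preferred;
4. groups below `min_peptides_per_group` identifying peptides are dropped;
5. `unique_peptides` are those identifying exactly one surviving group.
   Quantification uses only these — razor-style assignment of shared
   peptides to the largest group would re-introduce exactly the
   cross-taxon leakage the split is meant to prevent.

Discarded peptides are *not* deleted: they remain in the LCA report (at
their shared ancestor) and in the genus pools of the quantification module,
because taxon-level quantification deliberately uses all peptides of a
taxon (see below). Peptides matching no database protein are returned in an
`unmatched` sidecar, never silently dropped.

The test suite asserts the guarantee exhaustively on simulated data with
planted cross-phylum duplicates: no group spans split taxa, no identifying
peptide is ambiguous at the split rank, and the discarded set equals an
independent projection oracle.

## LCA placement and the taxonomy-tree report

`assign_peptide_lca()` annotates each matched peptide with the LCA of its
source species; `build_taxon_peptide_tree()` counts every peptide exactly
once, at its LCA node. Peptides shared across superkingdoms land at the
root and contribute nothing below it, which preserves a simple conservation
law: node counts sum to the number of matched peptides. Counts are counts
of distinct peptide sequences, not of spectrum-level observations —
evidence tables may carry multiplicities, but distinct sequences are the
stabler unit for tree reports.

Genera with no peptide attributed at the genus node or below are pruned
together with their subtrees. Their peptides are reported in a side list
rather than re-attributed upward: re-attribution would silently inflate
family-level counts with evidence that supports no retained genus. Species
nodes inside a retained genus are kept even when they lack unique peptides,
since the genus-level filter is the decision criterion.

## Top-N genus quantification

The abundance of a genus in a sample is the sum of its `top_n` (default 10)
highest peptide intensities. Summing a fixed number of peptides rather than
all of them keeps the measure comparable between genera with very different
database sizes; taxa whose pool holds fewer than `top_n` peptides are
excluded rather than summed over a short pool, which would fabricate
comparability.

Conventions that matter in corner cases:

* **Pools use all peptides of a genus, not just unique ones** (default
  `pool = "all-peptides"`): restricting to unique peptides would punish
  genera with close relatives. The cost — a shared peptide contributes to
  several genera and can overestimate both — is accepted and documented;
  `pool = "unique-only"` quantifies the conservative alternative.
* **Zero intensity means "not observed"** and never occupies a top-N slot.
* **Two selection modes.** `per-sample` (default) picks the top `top_n`
  nonzero intensities independently per sample; `global-median` selects one
  peptide set by median intensity across samples (zeros included, since a
  non-detection is information about abundance) and sums that fixed set per
  sample. The per-sample mode is the default because it is robust to single
  samples missing individual peptides; the global mode gives a consistent
  peptide basis across samples. Results carry the mode used.
* **Ties** in intensity break by peptide lexicographic order; all orderings
  in the package are deterministic across platforms.

State comparisons (`fold_change_between_states()`) use arithmetic means of
abundances per state; genera with zero mean in either state are flagged
not-evaluable instead of producing infinities. Descriptive summaries —
donor-sharing histograms with the core set, cumulative abundance of the top
k entities, running bacterial fraction along an abundance ranking,
within-sample Z-scores (population convention, so a two-value column maps
exactly to ±1), and log10-scale R² restricted to entries positive in both
samples — follow the same determinism rules.

## The simulator

`simulate_dataset()` generates the three layers the analysis consumes:

* **Taxonomy**: a balanced tree of `n_phyla × genera_per_phylum` genera
  with `species_per_genus` species, phyla directly under the root, plus an
  optional host-like outgroup (own superkingdom → phylum → genus →
  species chain).
* **Database**: protein sequences drawn i.i.d. from a residue model with
  K/R boosted to ≈ 11 % combined frequency, so tryptic fragments average
  about 9 residues and length-7+ peptides are plentiful. With probability
  `cross_species_copy_prob` a protein is instead a point-mutated copy
  (per-residue rate `point_mutation_rate`) of a same-genus neighbor — the
  mechanism that plants realistic within-genus peptide sharing. Copy events
  and the peptides shared by construction are recorded as ground truth.
* **Evidence**: two states, `samples_per_state` samples each. A peptide's
  expected intensity is its genus's base abundance (log-normal around 10⁹,
  the scale of MS peptide intensities) × a fixed peptide-specific
  log-normal factor; state B multiplies the genus base by its planted fold
  change. Observed intensity adds multiplicative log-normal noise
  (`intensity_noise_sd`, default 0.2) and peptide-wise Bernoulli detection
  (`detection_prob`, default 0.9) — the simplest missingness model that
  exercises the pool-size exclusion path.

Everything is a pure function of `(config, seed)`; identical inputs yield
byte-identical bundles.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: realistic protein families and homology structure
beyond the genus level (cross-phylum sharing must be planted explicitly, as
the acceptance tests do), intensity-dependent missingness, chimeric or
modified peptides, FDR-controlled identification errors, and shared
peptides whose intensity genuinely sums over several source organisms (a
simulated peptide's intensity follows a single source genus). Conclusions
about identification error rates or absolute quantification accuracy on
real samples are outside what this test bed can certify.

## Numerical and design notes

* Default simulated study sizes (3 phyla × 3 genera × 2 species, 12
  proteins per species, 4 samples per state) describe a small but
  structurally complete study: every code path — shared peptides, pruning,
  exclusion, two states — is exercised while a full simulate–assign–quantify
  cycle stays in the low seconds.
* Fold-change recovery in the validation suite uses 8 genera, 4 samples
  per state, 90 % detection and noise sd 0.2 over 20 replicates; the
  noiseless configuration recovers planted ratios to 10⁻⁹, the noisy one
  to a median relative error well under 30 % per genus.
* Degenerate inputs fail loudly and specifically: constant columns in
  Z-scoring name the sample, all-zero abundance vectors are rejected,
  fewer than three shared-positive entries make log-R² an error, taxonomy
  violations (duplicate ids, rank inversion, multiple roots, cycles) are
  reported by taxon.
* `read_protein_database()` works without a taxonomy (`tree = NULL`) for
  sequence-only workflows (digestion, overlap); assignment and
  quantification require full taxon annotation and say so.
* Evidence rows sharing a peptide sequence aggregate by summing per-sample
  intensities on construction, matching how spectrum-level exports with
  charge and modification multiplicity are usually collapsed.

## Known limitations

* LCA and projection queries are exact but not optimized for very large
  taxonomies (lineages are materialized per taxon with memoisation);
  taxonomies up to tens of thousands of nodes are unproblematic.
* The grouping algorithm is greedy; like all parsimony-style protein
  inference it does not enumerate alternative optimal groupings.
* Quantification assumes intensities are comparable across samples;
  normalization beyond within-sample Z-scoring is left to dedicated tools.
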