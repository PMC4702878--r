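---
title: "Structural context of PTM substrate sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural context of PTM substrate sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmstructkit)
```

# The problem

Most of what is known about post-translational modification (PTM) sites
comes from sequence: a phosphoserine is reported as a position in a
protein, with at most a linear motif around it. Yet the chemistry of a
modification happens in three dimensions — the residues that pack
around a substrate site, how their side chains point at it, how
solvent-exposed it is, and whether a drug-like ligand binds nearby all
condition whether the site can be modified and what the modification
does. `ptmstructkit` implements that structural-context analysis as a
reusable toolkit, together with the two desk-scale companions such an
analysis needs: non-homologous benchmark construction for sequence-based
PTM-site predictors, and assembly of PTM regulatory networks from
pathway and protein–protein interaction (PPI) tables.

# Mapping sites onto structures

PTM site tables live in UniProt-style sequence coordinates; structures
live in PDB author numbering. The mapping step joins the two by exact
subsequence search: a modified peptide must occur at 100% identity in a
chain's ATOM-derived sequence before the site is localized, and a
peptide that occurs more than once (within or across chains) is reported
as ambiguous rather than silently assigned. We derive chain sequences
from resolved (ATOM) residues rather than SEQRES so that every mapped
site is guaranteed to have coordinates; unresolved loops therefore
simply cannot host a mapped site, which is the behaviour a structural
analysis needs. Only X-ray structures solved at better than 2.5 Å are
accepted by default (`max_resolution = 2.5`, strict `<`; structures with
no recorded resolution fail the filter unless it is disabled), because
side-chain orientations read from lower-resolution maps are not
trustworthy at the 1-degree scale the analysis reports.

Alternate locations are resolved before any geometry: for each atom name
within a residue the highest-occupancy conformer is kept, ties going to
the alphabetically first altloc code, so no residue ever carries two
atoms of the same name. Multi-model files contribute only their first
model. Author residue numbers (with insertion codes) are the coordinate
space reported to users throughout.

# Side-chain orientation geometry

For a substrate residue $p$ and a spatially neighboring residue $k$ the
package computes

$$S_k = X_p^{F} - X_k^{C\alpha}, \qquad
  V_k = X_k^{F} - X_k^{C\alpha}, \qquad
  \theta_k = \arccos\frac{S_k \cdot V_k}{\lVert S_k\rVert\,\lVert V_k\rVert},$$

where $X^{F}$ is the position of a residue's *functional atom* — the
terminal side-chain atom that carries its chemical business end (OG for
Ser, OG1 for Thr, OH for Tyr, NZ for Lys, SG for Cys, and so on; the
full table ships as `FUNCTIONAL_ATOMS` and can be overridden). $S_k$
points from the neighbor's Cα to the substrate's modified atom, $V_k$
along the neighbor's own side chain; $\theta_k$ therefore measures
whether the neighbor's side chain is presented *toward* the substrate
site. A neighbor with $\theta_k < 80°$ (strict) is classified as a
functional residue for the site. The same functional-atom table defines
the substrate's "modified atom", which generalizes the construction
uniformly across PTM chemistries (phospho-Ser/Thr/Tyr, N-linked Asn,
ubiquityl-Lys, …).

Numerical choices: the normalized dot product is clamped to $[-1, 1]$
before `acos` so numerically (anti)parallel vectors never raise domain
errors; a functional atom coinciding with its Cα (a degenerate,
physically impossible side chain) is an error, not a silent zero;
glycine has no side chain, so glycine neighbors receive a distance but
no orientation angle. When a residue's designated functional atom is
unresolved, the outermost resolved side-chain atom substitutes, flagged
as a fallback.

Spatial neighbors are all residues whose Cα lies within the cutoff
(default 10 Å, boundary inclusive, so the documented cutoff is itself
attainable) of the site's reference point. The reference defaults to the
site's functional atom — the natural origin for side-chain-centred
questions — with `calpha` and `any_sidechain_atom` exposed as
alternatives because the two conventions differ for elongated side
chains. Sequential context is reported separately for offsets −6…+6,
truncated at the termini.

The radial composition profile counts neighbor residues by amino-acid
type within each radius of a 2–10 Å grid, cumulatively, and normalizes
to relative frequencies per radius; empty shells yield `NA` frequencies
rather than 0/0. Raw cumulative frequencies are reported; a
background-corrected propensity normalization is a documented possible
extension, not implemented, because the appropriate background depends
on the user's corpus.

# Solvent accessibility

SASA is computed natively by the Shrake–Rupley method: each heavy atom's
solvent sphere (van der Waals radius + 1.4 Å probe) is sampled with a
deterministic golden-spiral point set (default 960 points) and points
buried inside any neighboring sphere are discarded. Radii: C 1.7, N
1.55, O 1.52, S 1.8, P 1.8 Å, all configurable; hydrogens are ignored.
Relative accessibility divides per-residue sums by the theoretical
Gly-X-Gly maxima of Tien *et al.* (2013, PLoS ONE 8:e80635); values
above 1.2 are flagged. Two properties bound the quadrature error and are
enforced by tests: an isolated atom recovers its analytic sphere area to
well under 1% at 960 points, and totals move by less than 2% between 960
and 4000 points. Note that the fixed point set does not rotate with the
molecule, so SASA is rigid-motion invariant only up to that same
quadrature error. DSSP-style areas computed from the same structures
will show small systematic differences; they are alternative estimates
of the same quantity.

# Drug-binding proximity

A PTM site is drug-binding-associated when its side chain lies within
10 Å of a bound ligand. The screen measures the minimum heavy-atom
distance from any side-chain atom of the site to any atom of each
ligand group — the strictest literal reading of "side chain within
10 Å" — with Cα as a flagged fallback for glycine. Ligand groups are
HETATM records partitioned by (het code, chain, residue number), after
removing waters and a shipped list of crystallization ions, buffers and
cryoprotectants (`EXCLUDED_HET`). Which ligands count as *drugs* is a
metadata question, not geometry: the screen accepts an optional
user-supplied het-code→drug-label table and otherwise reports all
non-excluded ligands. The boundary is inclusive (a contact at exactly
10.0 Å counts), and shrinking the cutoff can only remove contacts.

# Benchmark construction and evaluation

Positive examples are sequence windows of length $2n+1$ (default
$n = 10$, 21-mers) centered at annotated sites of the target residue;
negatives are windows at every *other* occurrence of that residue in the
same modified proteins — proteins with no annotated site contribute
nothing, since their unannotated residues are unverified rather than
negative. Termini are padded with `-`, and pads count as mismatches in
identity computations, with the full window length as denominator (a
conservative choice; the alternative of shrinking the denominator would
make short terminal fragments look artificially similar).

Redundancy is removed by greedy incremental clustering in input order: a
fragment joins the first cluster whose founder it matches at ≥ the
identity threshold (default 50%), else founds a new cluster, and
founders are the retained representatives. This guarantees the
non-homology invariant — no two retained fragments within a set at or
above threshold — which is the property the benchmark needs;
agreement with any particular external clustering tool's cluster
boundaries is not claimed. Finally negatives identical to any positive
(cross-set identity 1.0) are purged, removing label contradictions.
Order-dependence is inherent to greedy clustering; the input order is
the dataset's row order and is preserved in the written FASTA files, so
the pipeline is reproducible end to end.

Evaluation reports TP/FP/TN/FN and Sn, Sp, Acc, MCC with the standard
formulas; when an MCC denominator term is zero (e.g. an all-positive
predictor) MCC is reported as 0 with an explicit `mcc_undefined` flag.

# Regulatory networks

`build_network()` implements the query-set semantics used in PTM
resource front ends: nodes are the queries, the full membership of every
pathway a query touches, and the PPI partners of queries; pathway edges
survive when both endpoints are included, PPI edges when at least one
endpoint is a query (so interaction partners can suggest new pathway
members). Node attributes record query status, pathway membership and
per-protein PTM types; edges carry their kind (`pathway`/`ppi`).
Assembly canonicalizes node and edge order, so it is idempotent and
independent of input row order. Pathway topology is taken as given
input — deriving edges from pathway-map drawings is a curation problem,
not an algorithm. Exports: lossless GraphML, and SIF/TSV edge lists for
the Cytoscape ecosystem.

# The synthetic-data generator

Every analysis is testable without downloads because the fixtures module
*constructs* inputs whose answers are known exactly.

`make_toy_structure()` builds a serine site residue and places each
requested neighbor so that its Cα sits at the planted distance from the
site's OG and its side chain realizes the planted orientation angle (the
side-chain direction is the substrate direction rotated by $\theta$
about a perpendicular axis); single-atom ligands are placed at planted
minimum distances in the hemisphere where OG is provably the nearest
side-chain atom. The construction is the inverse of the analysis, so
recovering the planted values to 1e−6 is a genuine end-to-end check.
The in-memory model carries full-precision coordinates; the written PDB
file is limited to the format's 3 decimals, which is what the round-trip
tests assert. Infeasible requests (overlapping atoms) are refused.

`make_synthetic_proteome()` draws random sequences (default 30 proteins
of 150–300 residues; target residue lysine at 8% frequency,
approximately its natural abundance, the rest uniform; 20 proteins carry
40 annotated sites — sizes chosen to give a few hundred fragments, large
enough for the counting invariants to be non-trivial and small enough to
scan all-pairs). Exact-duplicate fragments are injected on dedicated
carrier proteins whose flanks are free of the target residue: a
duplicate positive is a second annotated copy of a source window
(collapsed by within-set clustering), a duplicate negative is an
unannotated copy (removed by the cross-set purge). Carriers — rather
than in-place copying — are essential: overwriting a window inside an
existing protein would create partially overlapping negatives sharing
more than 50% identity with their source-side counterparts, breaking the
very invariant the tests check. Expected counts in the manifest are
computed by direct scanning and string set operations, never by running
the clustering pipeline, so they are an independent oracle; the
generator verifies the general-position assumption (all distinct
windows pairwise below 50%) by an all-pairs scan and redraws from a
derived seed in the vanishingly rare case it fails. A single integer
seed governs all randomness and the global RNG state is restored on
exit.

What the generator does *not* emulate: real backbone geometry, rotamer
libraries, crystal packing, residue-type spatial correlations, or the
compositional biases of real proteomes. Passing tests therefore
demonstrate the correctness of the computations — distances, angles,
areas, counts, set invariants — not biological conclusions about real
PTM sites; for those, point the same functions at real PDB files and
curated site tables.

# Problem sizes and verification scale

The verification suite runs the geometry against an all-pairs
brute-force oracle on 100 random structures of 60–1000 residues,
rigid-transform invariance over 1000 random rotations (max deviation
below 1e−9 degrees), SASA against analytic and quadrature oracles, the
benchmark pipeline against generator manifests with post-hoc all-pairs
identity scans, and a 10,000-fragment random predictor whose |MCC| stays
below 0.05. These sizes exercise every code path at full fidelity while
keeping the whole suite interactive-fast.

# Known limitations

- Only PDB-format input; mmCIF would need a reader extension.
- Secondary structure is treated as an optional external annotation; the
  package computes SASA natively but does not assign helices/strands.
- The 27.9°-scale agreement of orientation angles with published case
  studies depends on the (unstated, convention-dependent) choice of the
  substrate's modified atom; the functional-atom table is explicit and
  overridable for exactly this reason.
- Benchmark negatives follow the stated rule (unannotated same-type
  residues in modified proteins); no exclusion zone around positives is
  applied beyond the exact-duplicate purge.
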