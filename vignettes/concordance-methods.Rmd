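---
title: "Methods: cross-database concordance for metabolic pathway databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-database concordance for metabolic pathway databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathconcord)
```

## The problem

Two curated metabolic pathway databases describe overlapping but not
identical slices of metabolism, in different vocabularies. Before their
content can be compared — how many compounds they share, which pathway
classes one covers and the other does not, how many reactions are suitable
for flux-balance modelling — their compounds and reactions must be placed
in correspondence. `pathconcord` treats this as a record-linkage problem
with chemistry-aware features, plus the downstream statistics that a
database comparison needs: overlap coefficients, quality audits, sampling
accuracy estimation, and ontology enrichment.

## Data model

A database is a set of five attribute-value flat files (compounds,
reactions, pathways, pathway classes, taxonomy) in a BioCyc-style dialect:
`ATTRIBUTE - VALUE` lines, records separated by `//`. The dialect was
chosen for human diffability and a trivial streaming parse; reaction
stoichiometry uses `LEFT`/`RIGHT` participant lines with an optional
`COEFFICIENT` continuation line (default 1). Duplicate participant lines on
one side are merged by summing coefficients — tolerant ingestion beats
rejection here, since real flat files contain such redundancies. Writing is
deterministic (records sorted by id, fixed attribute order), so
serialization is reproducible byte for byte; `read(write(db))` is the
identity, which the tests exercise on generator output.

Pathways come in two kinds. `BASE` pathways (modules, in the terminology of
a KEGG-style database) carry reaction lists directly. `SUPER` pathways
(maps) aggregate subpathways plus extra reactions; wherever a pathway's
reaction set is needed (substrate sets, size statistics, link coverage,
enrichment) it is materialized as the *transitive closure* over
subpathways plus directly listed reactions. The closure choice is a design
decision: composite pathways are defined in terms of their components, so
statistics that ignored component reactions would systematically
understate super-pathway content.

## Compound matching

A candidate pair of compounds (one per database) is **accepted** iff all
three hold:

1. at least one *feature* fires:
   - `FINGERPRINT_STRUCT` — fingerprint Tanimoto coefficient strictly
     greater than 0.75 (bit sets; `|A∩B|/|A∪B|`) *and* equality of the
     protonation-invariant structure keys. The second conjunct realizes a
     structure matcher that tolerates protonation differences: two
     compounds differing only in their proton/charge layers share the
     invariant key even though their full structure strings differ.
   - `EXACT_STEREO` — byte-identical full structure strings (InChI-style,
     stereo and proton layers included).
   - `ALL_BUT_ONE` — for an already-matched reaction pair whose substrates
     are fully matched except one residual compound on each side, the
     residual pair is proposed, provided neither compound is linked to
     anything yet.
2. the canonicalized names agree. Canonicalization lowercases and strips
   every character outside `[a-z0-9]`, so punctuation and capitalization
   differences cannot block a match. The gate consults the common name
   *and all synonyms* on both sides — a deliberate choice: synonym lists
   exist precisely to capture alternative nomenclature, and restricting
   the gate to primary names would discard the information they carry.
3. the pair is contradiction-free. If any compound ends up with two or
   more distinct proposed partners, *all* implicated pairs are dropped and
   reported, none is chosen. With no principled tie-break available,
   discarding is the conservative reading of "no contradictory matches";
   precision is favoured over recall.

`ALL_BUT_ONE` runs after the direct pass and **iterates to a fixpoint**:
each accepted residual pair can complete the substrate matching of another
reaction pair, which can then propose its own residual pair. Proposals only
ever grow, so the iteration terminates. Curated or imported links supplied
as input are kept verbatim and never overridden; inference never relinks an
already-linked compound.

Within one database, duplicate compounds are clusters of records with
identical non-empty structure strings; the duplicate count follows the
cluster convention `Σ (cluster size − 1)`.

## Reaction matching

Both databases' reactions are entered as signed columns of one sparse
stoichiometric matrix (built with `Matrix`): reactant coefficients
negative, products positive. Compound pairs linked by the compound stage
share a row; unlinked compounds get database-private rows, so unmatched
substrates dilute, rather than fake, similarity. A pair is accepted iff
`|cos|` of its two columns strictly exceeds 0.6 — the absolute value makes
matching orientation-blind, because direction conventions differ between
databases and a reversed twin is still the same chemistry — *and* at least
one annotation feature fires (shared UniProt accession; exact EC-number
string equality, where partial forms like `1.1.1.-` only match the
identical partial string, never by prefix; canonicalized activity-name
equality), *and* the pair is contradiction-free (same rule as compounds).

After the main rule, an **EC fallback** considers the still-unmatched
reactions: an EC number mapping exactly one unmatched A-reaction to exactly
one unmatched B-reaction yields a match (flagged `EC_FALLBACK`).
Contradiction filtering runs *before* the fallback, and the fallback never
resurrects a voided pair — the fallback is a mop-up for pairs whose cosine
was degraded by missing compound links, not an override of evidence
conflicts.

Duplicate reactions are pairs with equal reactant and product coefficient
multisets, directly or after reversing one of them. Coefficient multisets
(not bare compound sets) are compared: `2A → B` and `A → B` are different
reactions.

The package's top-level `concordance()` alternates the two stages —
compound links feed the stoichiometric matrix, reaction links feed
all-but-one inference — until the link set stabilizes, typically within
three rounds.

## Balance auditing

A reaction's balance report sums coefficient-weighted atom counts per side
from the participants' molecular formulas (parsed with a small grammar:
element symbols, counts, parenthesized groups with multipliers; trailing
charge tokens are stripped because the audit is atom-based). `balanced_all`
demands a zero delta for every element; `balanced_no_h` ignores hydrogen,
since hydrogen imbalance often reflects inconsistent protonation
conventions rather than a wrong equation, so `balanced_all ⇒
balanced_no_h` by construction. A reaction with any unparseable or missing
formula is *skipped* — reported, but asserted neither balanced nor
unbalanced — because structureless compounds are common in real databases
and unverifiable is not the same as wrong.

The high-quality reaction count is the plain subtraction
`total − duplicates − unbalanced(counting H)`. A reaction that is both a
duplicate and unbalanced is subtracted twice; the overlap-aware variants
were considered and rejected because the plain subtraction is the
convention this summary statistic follows, and skipped reactions count as
balanced for the same reason they are not flagged.

## Sampling accuracy estimation

The audit design uses the normal-approximation binomial formula
`n = ⌈z² p₀(1−p₀)/h²⌉` with worst-case `p₀ = 0.5`. "Confidence interval of
10%" is read as half-width `h = 0.10`: at 90% confidence this gives
`n = 68`, whereas the full-width reading would give 385 — only the
half-width reading is consistent with an audit of 68 samples.

Rate estimates carry Clopper–Pearson intervals (beta-quantile inversion of
the binomial tails). Clopper–Pearson was chosen because it is exact and
conservative; the tests verify its endpoints against a direct root-search
on the binomial tail sums and its empirical coverage (at n = 68,
p ∈ {0.02, 0.13, 0.5}) over 10,000 simulated audits. The constructor also
accepts externally supplied interval endpoints, so accuracy arithmetic can
be run on audits whose intervals were computed elsewhere.

Overall accuracy combines the false-negative and false-positive audits as
`100 − FN% − FP%`, where each percentage is first rounded to one decimal —
the convention that reproduces accuracies quoted alongside one-decimal
audit rates (9/68 = 13.2%, 6/68 = 8.8% give 78.0%, where unrounded
subtraction would print 77.9%). Bounds substitute the interval endpoints
(upper endpoints for the lower bound and vice versa); unrounded variants
are returned alongside. Error-count extrapolation rounds
`rate × population` to the nearest integer.

## Enrichment, depletion and uniqueness

For one database, the background population is its set of pathway
reactions, with the linked ones marked. Each pathway class's reaction set
is the union over pathways assigned to the class or any descendant
(transitive over the acyclic class ontology). Enrichment and depletion are
one-sided hypergeometric tails (`stats::phyper`; the tests check exhaustive
enumeration equality for all populations up to 12), Bonferroni-corrected by
the number of classes tested per direction, and called at α = 0.025 on the
corrected p-value. The background restricted to pathway reactions is a
design decision: class reaction sets can only contain pathway reactions, so
a whole-database background would mix two reference populations.

A pathway is *unique* to its database if the best single other-database
pathway covers at most one third (inclusive) of its reactions through
links. The "best single pathway" operationalization resolves the
ambiguity of attributing a reaction link to a pathway context: coverage is
computed per candidate pathway and maximized. The taxon table counts a
base pathway under a taxon if any taxon in its taxonomic range equals or
descends from it, and keeps taxa with at least 50 pathways (configurable).

## The synthetic benchmark

`generator_config()` defines the study conditions; `generate_universe()` +
`derive_views()` produce two databases with known truth.

**What is emulated.** A shared universe viewed twice with controlled
overlap (default: half the content shared); name synonymy and
canonicalization-invariant name mangling (10%); protonation-state
divergence (10%): the view-B structure string gains a proton layer while
the protonation-invariant key, fingerprint and formula stay put; stereo
loss (10%): the stereo layer disappears from view B's structure string
*and* structure key, so the derived fingerprint changes too and only
all-but-one inference can recover the pair; fingerprint bit noise (2 bits
per view in a 256-bit space, leaving true-pair Tanimoto ≈ 0.89); duplicate
records (1%); mass imbalance (5%); EC/UniProt/activity annotations shared
with configured probabilities (0.7/0.5/0.5) plus EC collisions (2%); and
the two databases' pathway-size asymmetry (view-A base pathways average
4.37 reactions, view-B modules 6.22, with view-B maps aggregating more
modules than view-A super pathways aggregate base pathways).

**Construction guarantees.** Reactions are balanced *by construction*:
product formulas are obtained by multinomially re-partitioning the summed
reactant atom counts, so no chemistry simulation is needed and molecular
plausibility is explicitly a non-goal. Mass imbalance is injected by
appending a hidden view-local filler participant (formula `H` for
hydrogen-only imbalance, `C` for imbalance that survives the no-hydrogen
audit) rather than by editing a compound's formula — a formula edit would
cascade into every other reaction using that compound and destroy the
guarantee that exactly the logged reactions are unbalanced. For the same
reason the protonation variant alters the proton layer of the structure
string, not the atom-count formula: the logged injection set and the
balance checker's flag set must coincide exactly, and they do (this is an
acceptance property). Imbalance and duplication are kept disjoint so clones
remain true duplicates.

**Sharedness model.** Each reaction is shared with probability
`shared_reaction_fraction`; a shared reaction draws reactants from shared
compounds and creates its products shared, while seed compounds are shared
with probability `shared_compound_fraction`. The two Bernoulli processes
cannot be fully independent (a shared reaction forces its participants
shared), so the defaults keep the two fractions equal (0.5), under which
the realized compound overlap is binomial up to the small clustering of
products within a reaction (cluster sizes ≤ 3; the corresponding design
effect is bounded by 2 and accounted for in the property test).

**What is not emulated.** Real chemical structures and SMILES, curation
biases, correlated noise (all noise processes are independent per entity —
the simplest defensible model, and the one under which the test thresholds
can be set analytically), systematic naming conventions shared across
compounds, and cross-database pathway correspondences (views get
independent pathway structures). Passing the recovery tests therefore
demonstrates the machinery is correct under the stated noise model, not
that these precision/recall levels transfer to any real database pair.

**Problem sizes.** The benchmark runs at ~500 compounds / ~300 reactions,
the scale at which all matching stages (including the sparse-matrix cosine
sweep and the fixpoint iteration) are exercised in seconds; unit fixtures
are hand-built two-to-six-record databases where expected values can be
enumerated by hand.

## Numerical and degenerate-input choices

- Tanimoto of two empty bit sets and cosine of a zero vector are
  *undefined*: both return `NA` and can never produce a match.
- Thresholds are strict inequalities (Tanimoto exactly 0.75, cosine
  exactly 0.6 do not fire); the uniqueness boundary is inclusive (exactly
  one third is unique).
- Hypergeometric tails delegate to `phyper`, which computes in log space;
  Bonferroni caps at 1; a class can never be called enriched and depleted
  simultaneously at α < 0.5.
- Degenerate reactions (one empty side) are flagged and tolerated, not
  rejected; formula parsing is total on its grammar and rejects anything
  else with a position-annotated error.
- Mean comment length is averaged over commented objects only (the
  all-objects denominator would conflate prevalence with verbosity; the
  prevalence count is reported separately).
- Jaccard coefficients are reported to two decimals in reports; full
  precision is kept internally.

## Known limitations

- The compound-audit accuracy *upper* bound under the one-decimal
  convention is 99.8 with the audit endpoints used in the worked examples;
  quoted upper bounds for such audits vary with the (often unstated)
  interval method, so only the accuracy and lower bound are treated as
  reference arithmetic.
- Generic (compound-class) substrates are flagged (`is_class`,
  `is_generic`) and counted but never instantiated into concrete
  reactions.
- No charge-balance audit; protonation consistency relative to a defined
  pH is out of scope.
- Real BioCyc/KEGG flat files and KGML are not parsed; the package reads
  its own documented dialect (adapters would be straightforward).
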