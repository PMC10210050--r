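---
title: "Designing clade-specific primers and evaluating them by in silico PCR"
author: "cladeprimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing clade-specific primers and evaluating them by in silico PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeprimer)
library(dplyr)
```

## The problem

PCR on DNA extracted from a lichen thallus is PCR on a microbial community.
The extract contains the lichen-forming fungus (the mycobiont, usually the
organism of interest), its photobiont, and a halo of environmental and
lichenicolous fungi that co-inhabit the thallus. "Universal" fungal primers
for loci such as the mitochondrial small-subunit rDNA (mtSSU) sit in blocks
that are conserved across essentially all fungi, so in a community template
they amplify whichever fungal genome competes best — frequently not the
mycobiont. The observable symptoms are mixed or unreadable Sanger traces,
clean sequences of the *wrong* fungus, or no product at all, and the problem
is worst for herbarium specimens with degraded DNA.

The remedy implemented here is to turn the usual primer-design logic around:
instead of placing primers in the conserved blocks, search the
length-variable segments *between* them for windows where the target clade is
internally conserved but differs from the co-amplifying fungi, and place the
primer 3' end on those diagnostic positions. A candidate pair is then
screened in silico against a taxonomically labelled sequence database before
any wet-lab work.

`cladeprimer` packages this workflow into composable, pipe-friendly pieces:

* **Alignment statistics** (`build_coord_map()`, `count_variable_sites()`,
  `discrimination_profile()`, `region_report()`): per-column discrimination
  scores and variable-site tables over a labelled multiple sequence
  alignment.
* **Candidate design** (`consensus_with_degeneracy()`,
  `enumerate_candidates()`, `design_pairs()`, `name_primer()`): degenerate
  consensus primers from high-discrimination windows, filtered and ranked.
* **Physical chemistry** (`tm_nn()`, `tm_wallace()`, `three_prime_gc_run()`,
  `dimer_scan()`): melting temperature, 3'-run and dimer screening.
* **In silico PCR** (`find_binding_sites()`, `simulate_pcr()`,
  `summarize_specificity()`): ecoPCR-style amplification under explicit
  mismatch, protected-3'-window and product-length rules.
* **Synthetic data** (`fixture_spec()`, `make_alignment()`,
  `make_database()`): deterministic generators with planted ground truth.

## Coordinates and naming

All genomic coordinates are 1-based, inclusive, in *ungapped reference
numbering*: one alignment row is designated the reference, and
`build_coord_map()` maps alignment columns to positions along that row with
its gaps squeezed out. This matches how primer locations are conventionally
annotated against a reference accession (e.g. a forward primer at
"533–552").

Primers are named systematically as `<locus>-<pos>-5'` (forward) or
`<locus>-<pos>-3'` (reverse), where `<pos>` is the reference coordinate of
the primer's **5' end**. The payoff of 5'-anchoring is that the expected
product size is simply the difference of the two numbers in the names:

```{r}
predict_amplicon_length(581, 1345)
```

This coordinate-difference convention (rather than the inclusive span, which
would add 1) is used everywhere: in pair ranking, in the in silico PCR
length filter, and in reported hit tables. The inclusive primer-to-primer
sequence is nevertheless emitted for every hit, so the full product is
always available.

Reverse primers are annotated in descending style (`1345-1324`): their 5'
end is the *larger* coordinate because they anneal to the non-coding strand.

## Discrimination statistics

For a labelled alignment, `discrimination_profile()` scores every column by
the number of off-target rows that differ from the target-group consensus,
where the consensus is the set of unambiguous bases observed among non-gap
target rows. Two deliberate choices:

* An off-target **gap counts as a difference** whenever the targets have a
  consensus base there. A deletion under a primer footprint precludes
  binding just as surely as a substitution, and the length-variable
  inter-block segments — where indels concentrate — are exactly where
  clade-specific signal lives.
* A column where every target row is gapped scores 0 and is flagged rather
  than erroring; such columns are insertions private to the off-target set.

`count_variable_sites()` follows the conventions of per-genus variability
tables: a column is *variable* only if two or more distinct unambiguous
bases (A/C/G/T) occur within the group — ambiguity codes and gaps never
create variability — and the *total* for a group is the number of columns in
the interval where at least one group row has a base. The second convention
means two genera can have different totals over the same reference interval
(one may carry an insertion), which is the behaviour observed in published
variability tables; a `total_mode = "all"` switch selects the plain
column-count alternative.

The universal-region map (U1–U8) used to define inter-region segments ships
as an editable config block. Published figures give these block boundaries
only graphically, so the defaults are chosen to bracket the classical primer
sites inside U2 and U6 and are explicitly *not* ground truth; any analysis
that depends on exact boundaries should set its own.

## Candidate design

`enumerate_candidates()` slides windows of the requested lengths along the
alignment and keeps a window when:

1. its summed discrimination score meets `min_discrimination`;
2. its ends lie on mapped reference coordinates;
3. all target rows are gap-free across it (`min_gapfree_frac`, default 1);
4. the minimal degenerate consensus over the target rows has total
   degeneracy at most `max_degeneracy` (default 16);
5. the nearest-neighbor Tm of the consensus lies in `tm_range`;
6. the 3'-terminal G/C run is at most `max_gc3_run` (default 3).

Both orientations are emitted per window: the forward candidate is the
consensus itself (3' end at the window's downstream edge) and the reverse
candidate its reverse complement (3' end at the upstream edge).

Scoring emphasises the 3' end: the `weighted3p` score is the minimum over
off-target rows of the mismatch count with the last `w3p = 5` positions
weighted `omega = 4`-fold. A mismatch at the extension terminus is worth far
more specificity than one in the primer body, but no published weighting
exists for this locus, so both knobs are config-exposed and the defaults are
simply a moderate emphasis chosen once. `design_pairs()` ranks crossed F/R
combinations by (pair `weighted3p` sum descending, minimum target coverage
descending, |ΔTm| ascending, product length ascending), with a final
deterministic tie-break on coordinates — repeated runs are bit-identical, as
there is no randomness anywhere in design.

The long-run 3'-G/C filter deserves a note: a primer ending in four or more
consecutive G/C (e.g. the classical reverse primer of this locus, whose
terminus ends `...GCCC`) binds over-stably at its 3' end and is prone to
non-specific extension. `three_prime_gc_run()` measures the maximal suffix
over G/C/S, and the default cap of 3 excludes such candidates.

## Melting temperature

`tm_nn()` computes duplex Tm from a nearest-neighbor ΔH/ΔS sum,

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C/4)} - 273.15,$$

with $C$ the total primer concentration (the self-complementary case uses
$C$ rather than $C/4$). Two published parameterizations are built in:

* `breslauer1986` (default): the classic Breslauer stack table with the
  melting-point salt adjustment $+11.7\log_{10}[\mathrm{Na}^+]$;
* `santalucia1998`: the unified duplex table with its canonical entropy
  correction $\Delta S \mathrel{+}= 0.368\,(N-1)\ln[\mathrm{Na}^+]$.

Defaults are 50 mM monovalent salt and 250 nM primer. The Breslauer set is
the default because it reproduces, within about 2 °C, the values printed by
the widely used vendor primer-analysis tools for typical 18–22 nt primers —
the values practitioners actually tune their touchdown programmes against.
Those web tools do not publish their exact formula, so bit-exact agreement
is documented as out of reach; the package instead treats agreement as a
tolerance property (±3 °C over the shipped reference panel, enforced in the
test suite) and pins its own arithmetic exactly (deterministic to well below
0.1 °C, verified against an independent hand-summed oracle).

Degenerate primers are scored as the arithmetic mean over all expansions,
refusing beyond degeneracy 16 — panels in this domain carry at most a
position or two of degeneracy, and averaging 4^k expansions for large k
would be silently meaningless.

`dimer_scan()` is a screening-level check: best ungapped antiparallel
complementarity over all offsets, reporting the longest run and the longest
run anchored at the 3' terminus. No loops, bulges or free-energy
minimisation — those belong to dedicated secondary-structure tools; the
exhaustive-offset model has the virtue of an exact brute-force oracle.

## In silico PCR

`simulate_pcr()` applies ecoPCR-style rules:

* at most `max_mismatch` mismatches **per primer** (default 3);
* a hard zero-mismatch window over the last `protected_3prime = 2` primer
  positions, counted from the 3' end regardless of strand — one mismatch
  there abolishes the site even when the total is otherwise allowed;
* product length (5'-anchored difference) within `[min_len, max_len]`,
  default 200–2500 bp.

Matching is IUPAC-aware in both directions: a primer code matches a template
base when their base sets intersect. Template ambiguity codes (N runs in
low-quality database entries) therefore match anything by default; a
`strict` mode counts any template ambiguity as a mismatch, since tools in
this family differ on the point and the choice materially changes off-target
counts on real databases.

All convergent site pairs are reported, in both product orientations, and
nested or overlapping amplicons are *not* deduplicated — a template that
yields several products is flagged (`multi_amplicon`), because multi-banding
is precisely the failure signal read off a gel. Output ordering is fully
deterministic.

`brute_force_pcr()` implements the same contract as a naive per-offset scan
sharing no code path with the engine (letter-set table versus bitmask
arithmetic), and the test suite holds the two equal over hundreds of
randomized instances up to 5 kb. `summarize_specificity()` rolls hits up
into per-allowance counts of amplified templates, split target clade versus
other (plus a per-family breakdown); a template counts at allowance *k* when
some product has at most *k* mismatches on *each* primer, which makes the
amplified sets nested in *k* by construction. Both template-level and
family-level counts are exposed rather than guessing which one a given
published bar chart used.

## The synthetic-data generator

`fixture_spec()` describes a synthetic locus as alternating conserved blocks
and length-variable segments — the architecture of ribosomal loci — with
discriminating windows planted inside chosen conserved blocks. At each
planted position every off-target row carries one and the same alternative
base, so planted truth is exact: a window of length 20 at
`planted_divergence = 0.45` carries exactly 9 differences, and its
discrimination-profile sum is exactly 9 × (number of off-target rows).

The default geometry places two such 20-column windows so that their
5'-anchored span is 764 bp — the geometry of the mycobiont-specific pair
this package was developed around — between a forward window in the second
conserved block and a reverse window in the fourth, separated by a variable
core. Group sizes default to 10 target + 6 off-target rows plus a gapless
reference row, echoing the modest alignments (tens of rows) from which such
primers are designed in practice. Substitution rates default to 2 % within
the target group and 5 % for off-target rows, confined to the variable
segments; deletions (one per row per segment with probability 0.5, up to
30 % of the segment) are likewise confined there, so that planted
coordinates never shift. An optional intron insertion (e.g. 2.3 kb between
the planted sites) reproduces the failure mode of intron-rich lineages,
where a structurally present primer pair yields no product because the
predicted amplicon exceeds the length cutoff.

What the generator deliberately does **not** emulate: phylogenetic
correlation (rows are i.i.d. around one ancestor, not a tree), insertions
relative to the reference, compositional bias, and sequencing artefacts.
Passing the planted-truth tests therefore demonstrates that the statistics,
the design ranking and the amplification engine are internally consistent
and correct on known ground truth — not that any particular biological
alignment will contain windows as clean as the planted ones.

## Numerical and degenerate-input choices

* All randomness in the generators flows from one integer seed through R's
  Mersenne-Twister; design and simulation are randomness-free.
* Ranking ties break on coordinates, making every ordering total.
* `success_rate()` rounds half-up to one decimal (matching how such rates
  are conventionally printed); R's own `round()` rounds half-to-even and
  would print 12.4 where 12.5 is expected every other time.
* Degenerate cases error loudly and early: empty groups, all-gap reference
  rows, orientation typos, amplified > sampled rows, unknown config keys,
  primers longer than templates (empty result, not an error), reverse
  coordinate not downstream of forward.
* `U` in input sequences is mapped to `T` with a warning (rDNA is sometimes
  deposited as RNA); gaps are legal only in alignments, never in template
  databases.

## Problem sizes in the shipped tests

The test suite validates the engine against the brute-force oracle on 200
randomized instances (templates 0.4–5 kb, primers 15–25 nt, all mismatch
allowances and both ambiguity modes), checks nesting and strand symmetry on
the same instances, and runs the full design-to-simulation loop on the
default fixture geometry (17 rows × ~1.4 kb alignment). These sizes were
chosen to exercise every code path at the scale the design workflow actually
operates on (single-locus alignments), while a database-scale screen of a
primer pair against millions of archived sequences is explicitly out of
scope for the package's own tests — the engine is linear in total database
length, and nothing in it is specific to small inputs.

## Known limitations

* The Tm model is duplex-only: no hairpins, no mismatch-dependent NN terms,
  no divalent-cation correction. It ranks candidates and matches vendor
  printouts; it does not replace a thermodynamics suite.
* In silico specificity counts binding-rule violations only; it knows
  nothing of extension efficiency, template secondary structure, or
  competition between templates in a multi-template reaction, so it
  predicts *possible* amplification, not yield.
* The dimer model is ungapped.
* Alignment quality is the user's responsibility: the toolkit treats the
  input alignment as given and never re-aligns.
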