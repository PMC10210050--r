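# cladeprimer

Design PCR primers that amplify one fungal clade and not its neighbours, and
test any primer pair in silico before ordering oligos.

## The problem

DNA extracted from a lichen thallus is a community sample: the lichen-forming
fungus (mycobiont) plus environmental and lichenicolous fungi. "Universal"
primers for markers such as the mitochondrial small-subunit rDNA (mtSSU) sit
in blocks conserved across all fungi, so on community templates they amplify
whichever genome competes best — often the wrong one, which shows up as mixed
Sanger traces or clean sequences of a contaminant. The fix is to design
primers in the *length-variable* segments between conserved blocks, at
positions where the target clade is internally conserved but differs from the
co-amplifying fungi, with the diagnostic differences placed at the primer 3′
end — and then to screen the pair against a taxonomically labelled sequence
database by in silico PCR.

`cladeprimer` implements that workflow end to end:

* **discrimination statistics** on a labelled multiple sequence alignment:
  per-column scores counting the off-target rows that differ from the
  target-group consensus (`discrimination_profile()`), variable/total site
  tables per inter-region segment (`region_report()`);
* **candidate design**: minimal degenerate consensus primers from
  high-discrimination windows, filtered by Tm, degeneracy and 3′ G/C run,
  ranked with 3′-weighted off-target mismatch scores
  (`enumerate_candidates()`, `design_pairs()`);
* **primer physical chemistry**: nearest-neighbor melting temperatures
  (Breslauer 1986 or SantaLucia 1998 unified parameters, salt-corrected),
  Wallace rule, 3′ G/C-run measurement, screening-level dimer scan;
* **in silico PCR**: IUPAC-aware binding-site search on both strands under a
  per-primer mismatch cap with a protected 3′ window (no mismatch in the
  last two positions), amplicon length bounds (default 200–2500 bp), and
  per-mismatch-allowance specificity summaries split target clade vs. other
  (`simulate_pcr()`, `summarize_specificity()`), with an independent
  brute-force oracle (`brute_force_pcr()`) for validation;
* **synthetic fixtures** with planted, exactly-known discriminating windows
  (`fixture_spec()`, `make_alignment()`, `make_database()`).

Key conventions: coordinates are 1-based ungapped-reference positions;
primers are named `<locus>-<pos>-5'`/`-3'` by the reference coordinate of
their 5′ end, so the expected product size is the difference of the two
coordinates — `predict_amplicon_length(581, 1345)` is `764`.

## Worked example

Design a clade-specific pair on a synthetic alignment with two planted
discriminating windows (each carrying 9 target/off-target differences,
placed 764 bp apart), then verify the pair in silico:

```r
library(cladeprimer)
library(dplyr)

spec <- fixture_spec(seed = 42)        # 10 target + 6 off-target rows + REF
fx   <- make_alignment(spec)

cands <- enumerate_candidates(fx$alignment, fx$target_ids, fx$offtarget_ids,
                              constraints = design_constraints(min_discrimination = 20))
pairs <- design_pairs(cands)
pairs |> select(fwd_name, rev_name, amplicon_bp, pair_specificity,
                target_coverage, delta_tm) |> head(3)
#> # A tibble: 3 × 6
#>   fwd_name      rev_name       amplicon_bp pair_specificity target_coverage delta_tm
#>   <chr>         <chr>                <int>            <dbl>           <dbl>    <dbl>
#> 1 mt-SSU-213-5' mt-SSU-973-3'          760               38               1   0.598
#> 2 mt-SSU-212-5' mt-SSU-973-3'          761               38               1   1.30
#> 3 mt-SSU-200-5' mt-SSU-973-3'          773               34               1   0.0404
```

The top pair sits on the planted windows (`pair_specificity` 38: summed
3′-weighted off-target mismatches of both primers; `target_coverage` 1:
every target row matches both primers exactly). Simulating PCR against the
de-gapped, lineage-labelled database built from the same specification:

```r
dbx  <- make_database(spec)
hits <- simulate_pcr(pairs$fwd_seq[1], pairs$rev_seq[1], dbx$db, pcr_params())
summarize_specificity(hits, dbx$db, c("family", "Parmeliaceae"))
#> <specificity summary: target family 'Parmeliaceae', 17 templates>
#> # A tibble: 4 × 5
#>       k n_target n_other n_unclassified n_total
#>   <int>    <int>   <int>          <int>   <int>
#> 1     0       11       0              0      11
#> 2     1       11       0              0      11
#> 3     2       11       0              0      11
#> 4     3       11       0              0      11
```

All 11 target templates amplify with zero mismatches and no off-target
template amplifies even when 3 mismatches per primer are allowed — the
designed pair is clade-specific by construction. `autoplot()` on the summary
draws the per-allowance stacked bars; `autoplot()` on `hits` draws the
amplicon-length spectrum ("virtual gel").

Screening existing primers works the same way on any FASTA + taxonomy TSV
via `read_sequences()`; the shipped panel of published mtSSU primers is
available as `mtssu_primers()`:

```r
tm_nn("GGAGGAATGTATAGCAATAG")                  # 53.3 °C (Breslauer, 50 mM Na+, 250 nM)
three_prime_gc_run("ATGTGGCACGTCTATAGCCC")     # 4 — risky 3' G/C run
success_rate(22, 24)                           # 91.7
```

A thin command-line wrapper with subcommands
`{fixtures, regions, tm, design, pcr, report}` is installed at
`system.file("cli", "cladeprimer", package = "cladeprimer")`.

## Documentation

The methods vignette (`vignettes/cladeprimer-methods.Rmd`) describes the
model and its assumptions: the discrimination statistics, the design
constraints and their defaults, the melting-temperature parameterizations,
the in silico PCR rules, what the synthetic generator does and does not
emulate, and known limitations.
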