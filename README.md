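# mdlink — linking medical-device safety notices to a device registry

Post-market surveillance of medical devices depends on aggregating
published safety notices (recalls, field safety corrective actions) by
device category. The notices published by national authorities are
free-text records: manufacturer and device names are typed inconsistently,
and only a minority carry the registry identifier (BD/RMD) that would link
a notice directly to the national device register and hence to its
hierarchical EMDN/CND nomenclature code. `mdlink` recovers those missing
links with a two-phase entity-resolution pipeline and turns the linked
notices into surveillance summaries, for regulatory scientists and health
informaticians who need category-level signal counts from incomplete
public data.

## Method

For a notice *n* and a registry *D*:

1. **Direct link (Case 1).** If *n* carries a BD/RMD identifier, link to
   the registry row whose progressive registration number equals it (after
   stripping thousands separators) and read off its EMDN code.
2. **Manufacturer blocking (Case 2, phase 1).** Otherwise, restrict the
   candidate devices to manufacturers similar to the notice's. Names are
   normalized (punctuation removal, whitespace/specials cleanup,
   lowercasing) and legal suffixes stripped; each canonical name is a
   TF-IDF document with smoothed idf
   `idf(t) = ln((1+N)/(1+df(t))) + 1` and L2-normalized weights, and a
   registry manufacturer enters the block when
   `cos(q, d) ≥ 0.90`. An alternative blocker demands equality of
   named entities extracted from the raw strings (deterministic
   capitalized-run heuristic by default, pluggable backend); an empty
   extraction falls back to an un-blocked global search.
3. **Fuzzy device matching (phase 2).** Each candidate is scored 0..100 by
   a Levenshtein token-set ratio on two field pairs — notice device name
   vs registry commercial name, and notice commercial-name field vs
   registry catalogue code — combined by max. A threshold `S_th` walks
   95, 90, …, 60; at the first rung any candidate reaches, the
   highest-scoring candidate is accepted (ties to the smallest
   progressive identifier). Below 60 the notice stays unmatched.
4. **Validation.** Notices that do carry an identifier form a free
   reference standard: hide it, resolve by ER alone, then score
   manufacturer accuracy, identifier accuracy, and EMDN accuracy at
   levels 1–4 (agreement of hierarchical level prefixes), plus the same
   per level on the wrong-identifier subset. Two blocking methods are
   compared by the mid-P McNemar test on paired per-item flags:
   `midp = 2·P(X ≥ max(b,c)) − P(X = max(b,c))`, `X ~ Bin(b+c, ½)`.

Because the same physical device can be registered twice under different
progressive numbers, an "incorrect" identifier can still carry a fully
correct EMDN code — the level-wise EMDN accuracies, not the raw
identifier accuracy, are the quantity that matters for surveillance.

A synthetic-data generator (`simulate_pms()`) emulates both schemas with
known ground truth — about 32 % of notices carrying the identifier,
controllable typos, token reordering, legal-suffix and casing variants,
and duplicate registrations — so the entire pipeline is testable offline.

## Worked example

```r
library(mdlink)

sim   <- simulate_pms(generator_config(n_manufacturers = 20,
                                       notice_count = 60, seed = 7))
idx   <- build_registry_index(sim$registry,
                              extra_manufacturers = sim$notices$manufacturer)
links <- resolve_all(sim$notices, idx, method = "cos")
#> resolve_all: 60 notice(s): 19 direct, 30 er, 11 unmatched (0.21 s)

run_validation(sim$registry, sim$notices, method = "cos")
#> <validation_report> n = 19
#>   manufacturer accuracy: 78.95%
#>   identifier accuracy:   68.42%
#>   nomenclature level 1:  78.95%  (wrong-id subset: 33.33%)
#>   nomenclature level 2:  78.95%  (wrong-id subset: 33.33%)
#>   nomenclature level 3:  78.95%  (wrong-id subset: 33.33%)
#>   nomenclature level 4:  78.95%  (wrong-id subset: 33.33%)

summarize_links(links, sim$notices, emdn_level = 1)
#> <surveillance_summary> 60 notice(s)
#>   by year: 2009=4, 2010=2, 2011=4, 2012=7, 2013=3, 2014=4, 2015=7, ...
#>   top nomenclature buckets: G=14, B=11, unassigned=11, S=10, J=7
```

The 19 notices that carried an identifier were re-resolved blind: 79 %
were matched to a device of the correct manufacturer and EMDN code at
every level, and 68 % to the exact registry row. On the wrong-identifier
subset, a third still received the correct code — in this run the wrong
rows were other devices of the right manufacturer; with duplicate
registrations enabled the conditional accuracy rises to 100 % by
construction. Unmatched notices appear in the reserved `unassigned`
bucket of the summary.

A command-line front end wrapping the same functions is installed under
`inst/cli/mdlink.R`:

```sh
Rscript "$(Rscript -e 'cat(find.package("mdlink"))')/cli/mdlink.R" \
  simulate --out-dir data/ --seed 7
Rscript .../cli/mdlink.R resolve  --devices data/dod.csv \
  --notices data/don.csv --method cos --out links.csv --summary summary.json
Rscript .../cli/mdlink.R validate --devices data/dod.csv \
  --notices data/don.csv --method cos --report report.json
Rscript .../cli/mdlink.R report --links links.csv --notices data/don.csv \
  --level 2 --html report.html
```

## Package layout

| Area | Contents |
| --- | --- |
| `R/records_io.R` | CSV schemas, identifier canonicalisation, link table |
| `R/textprep.R` | cleaning operators, tokenization, POS tagging, suffixes |
| `R/emdn.R` | nomenclature grammar and level-wise agreement |
| `R/manufacturer_match.R` | TF-IDF cosine blocking, NER blocking |
| `R/device_match.R` | edit distance, token-set ratio, threshold schedule |
| `R/pipeline.R` | orchestration, summaries, JSON/HTML reports |
| `R/validation.R` | four validation tests, mid-P McNemar |
| `R/synthetic.R` | ground-truth generator |
| `vignettes/linkage-methods.Rmd` | model, parameters, design rationale |
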