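---
title: "Linking safety notices to a device registry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking safety notices to a device registry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdlink)
```

## The problem

National authorities publish safety notices for medical devices as
semi-structured web records. A notice names a manufacturer and a device in
free text; only a minority carry the registry identifier (BD/RMD) that
pins the notice to one row of the national device register, and therefore
to the hierarchical EMDN/CND nomenclature code under which surveillance
counts are aggregated. For the remaining notices, the link must be
recovered by entity resolution between two inconsistently-typed string
sources. `mdlink` implements that recovery, its validation, and a
synthetic world in which every stage can be exercised with known truth.

## The linkage model

Resolution of one notice proceeds through at most three stages.

**Direct lookup.** A notice with an identifier is linked by exact key
equality after canonicalising identifiers to bare digit strings (printed
sources use `.` or `,` thousands separators; both are stripped at ingest
on both sides). A present-but-unknown identifier yields an explicit
`unmatched(no_bdrmd_in_registry)` outcome rather than a fallback to
fuzzy matching, so data errors stay visible.

**Manufacturer blocking.** Pairwise comparison of every notice against
every registry row is quadratic and infeasible at registry scale (order
10^6 devices), so candidates are blocked by manufacturer. Names are
normalized — punctuation removed, whitespace collapsed, specials such as
`*` dropped, lowercased — and trailing corporate legal forms (`spa`,
`gmbh`, `ltd`, ...) stripped token-wise, repeatedly, never emptying the
name. Each canonical name is a bag-of-words document; term weights are
raw counts times a smoothed inverse document frequency
$\mathrm{idf}(t)=\ln\frac{1+N}{1+\mathrm{df}(t)}+1$, vectors are
L2-normalized, and a registry manufacturer joins the block when the
cosine with the notice name reaches the threshold (default **0.90**).
The document universe for idf is the union of unique canonical names
from registry and notices, so query and corpus weights are consistent.
Out-of-vocabulary query terms get zero weight; a fully out-of-vocabulary
query produces an empty block with reason `oov`.

The alternative blocker extracts a named entity from the *raw* name
(legal suffixes left in the input — they are informative context for
extraction — but excluded from the entity itself) and demands exact
equality of normalized entities. The bundled extractor is a deterministic
heuristic — the longest run of capitalized non-suffix tokens — chosen so
tests are reproducible without a statistical model; the backend is
pluggable. When extraction fails (all-lowercase or empty input), the
block deliberately becomes the whole registry: an un-blocked search is
slow but mirrors how extraction failure behaves in a production system,
and explains why the cosine method is both faster and more accurate on
this task.

**Fuzzy device matching.** Within the block, each candidate is scored by
a Levenshtein-based token-set ratio. The plain ratio of two strings is
$\mathrm{round}\bigl(100\,(|a|+|b|-d_2)/(|a|+|b|)\bigr)$ with $d_2$ the
edit distance under substitution cost 2 (100 when both strings are
empty). The token-set construction splits both normalized strings into
de-duplicated token sets, forms the sorted intersection $I$ and sorted
remainders $R_a, R_b$, and returns the maximum pairwise ratio among
$\mathrm{join}(I)$, $\mathrm{join}(I,R_a)$, $\mathrm{join}(I,R_b)$. It
is invariant to token order and repetition and returns 100 whenever one
token set contains the other — exactly the robustness needed when a
short catalogue code is embedded inside a long commercial-name field.
Two field pairs are scored — notice device name vs registry commercial
name, and notice commercial-name field vs registry catalogue code — and
combined by maximum ("best evidence"; the sources list both comparisons
without a combination rule). The acceptance loop starts at
$S_{th}=95$ and iteratively lowers by 5 until a candidate reaches the
threshold or the floor of 60 is passed; the highest-scoring candidate at
the first firing rung wins, with ties broken by the smallest progressive
identifier for determinism. Candidates are scored once: the iterative
schedule is extensionally identical to "argmax, accepted iff
$\ge 60$" (a tested invariant), and the rung is recorded as the
`accepted_threshold` of the link.

## Tunable parameters

| Parameter | Default | Meaning |
| --- | --- | --- |
| `cos_threshold` | 0.90 | manufacturer cosine acceptance; higher = stricter blocking |
| `sth_start` / `sth_step` / `sth_floor` | 95 / 5 / 60 | device-match threshold schedule (score points, 0..100) |
| suffix list | 16 common legal forms | token-wise suffix stripping; loadable from a one-entry-per-line file |
| punctuation / specials sets | ASCII punctuation; `*` + non-alphanumeric symbols | cleaning operators; configurable because no source pins the exact sets |
| `emdn_level` | 1..4 | aggregation depth for surveillance counts |

## Validation

Notices carrying an identifier are the reference standard. The evaluator
*hides* the identifier, resolves by pure entity resolution, and scores:
manufacturer correctness (canonical-name equality with the true device's
manufacturer — not raw string equality), identifier correctness (exact
progressive-number equality), nomenclature correctness at levels 1–4
(agreement depth of level prefixes $\ge k$, not full-string equality,
because codes differ in depth), and the same level-wise accuracies on
the wrong-identifier subset. Unmatched notices count as incorrect under
every criterion, so failure modes depress accuracy rather than shrink
the denominator. Methods are compared by the mid-P McNemar test on the
discordant counts $b, c$: with $n=b+c$, $m=\max(b,c)$ and
$X\sim\mathrm{Bin}(n,\tfrac12)$, $\;p_{mid}=\min(1,\,2P(X\ge m)-P(X=m))$,
and 1 when $n=0$. The mid-P variant keeps the power of the exact
conditional test while controlling type-I error better; it is strictly
smaller than the classical exact p whenever discordant pairs exist (a
tested property).

The identifier criterion deliberately understates practical performance:
the same physical device can be registered more than once under distinct
progressive numbers with identical names and code. A prediction hitting
the *other* registration is wrong on the identifier and fully right on
the nomenclature — which is what surveillance aggregation consumes. The
duplicate-registration invariant (identifier accuracy may drop below 1
while code accuracy stays exactly 1) is reproduced as an acceptance
property on synthetic data with forced duplicates.

## The synthetic world

The generator states one fixed world; its defaults were chosen once and
are not tuned against test outcomes.

* **Identifier fraction 0.32** — the share of real notices observed to
  carry the registry identifier in the national dataset this design is
  modelled on (2440 of 7622).
* **Registry shape** — manufacturers as two wordlist tokens plus a legal
  suffix; commercial names of one to three device words plus a unique
  model token (so two devices of one manufacturer are never token
  subsets of each other — real catalogues disambiguate lines with model
  codes); catalogue codes unique alphanumeric strings; nomenclature
  codes drawn from a full product tree with per-level branching factors
  (default `5,4,3,2`, depth 4, the depth at which validation scores).
* **Corruption** — applied in the fixed order token shuffle → suffix
  add/drop/swap → casing change → per-character typos (uniform
  substitution/insertion/deletion, matching the edit model the matcher
  assumes). Defaults: typo rate 0.02 per character, suffix variants 0.2,
  shuffles 0.2, casing 0.3 — mild transcription noise between two
  administrative sources. A trailing legal suffix stays trailing under
  shuffle: real word-order variants permute the core name, not the legal
  form, and letting the suffix migrate would defeat suffix-stripping in
  a way no real source exhibits.
* **Duplicate registrations** — with probability 0.05 by default a
  device is re-registered under a second progressive number with
  identical names and code.

What a green test establishes, and what it does not: the generator's
names are English wordlist compounds with uniform, independent
corruption. Real notices are Italian, have correlated errors
(abbreviations, swapped fields, model-line renamings) and a heavy-tailed
manufacturer-size distribution. Clean-copy recovery at 100 % and smooth
degradation with typo rate validate the *mechanism* — blocking is lossless
when names agree, the matcher tolerates edits up to its floor — not the
headline accuracy one would obtain on any particular national dataset.

## Numerical and degenerate-input choices

* Ratio rounding uses base R `round` (half-to-even); the exact convention
  is stated so scores are bit-stable, and half-integer ratios are rare on
  token strings.
* Zero vectors (out-of-vocabulary names) have cosine 0 by definition, and
  empty blocks are recorded outcomes (`oov`, `no_block`), never errors.
* Empty fields contribute a pair score of 0 rather than being skipped, so
  a notice with only one usable field still matches through it.
* A matched device without a nomenclature code yields a link with an
  absent code (counted in the `unassigned` bucket downstream); the link
  itself is kept.
* One notice row is assumed to reference one device; sources that bundle
  several devices per notice must be exploded upstream.
* Duplicate notice reference numbers are kept-first with a warning;
  duplicate registry identifiers are retained (they are real) and
  surfaced in the ingest log.
* Determinism everywhere: fixed vocabulary order (first occurrence),
  smallest-identifier tie-breaks, seeded generation; two identical runs
  produce byte-identical link tables (a tested acceptance property).

## Known limitations

* Corporate hierarchies (subsidiary vs parent) are not resolved; a
  notice filed under a subsidiary will not block to its parent.
* The bundled POS tagger and entity extractor are deterministic
  heuristics adequate for blocking and testing, not linguistic tools;
  both are pluggable interfaces.
* Stemming and lemmatization are deliberately absent: the matched text
  is company and product names, where vocabulary normalization destroys
  information.
* No validation against the official nomenclature catalog; any
  letter-plus-digit-pairs code parses. Synthetic catalogs stand in for
  the versioned external resource.
* Accuracy figures quoted anywhere in this package are computed on the
  synthetic world by the test suite or the worked example, and should
  not be read as estimates for any real national dataset.
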