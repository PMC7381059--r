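---
title: "Privacy-preserving record linkage with hashed keys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving record linkage with hashed keys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hashlink)
```

## The problem

Sentinel surveillance systems pool electronic medical records (EMRs) from
many clinics and laboratories to monitor testing and diagnoses for
blood-borne viruses and sexually transmissible infections. One person
typically owns several EMRs — one per service attended, sometimes several at
one service when details change or an alias is used. Epidemiological
measures (testing frequency, positivity, incidence) are biased unless those
records are linked to individuals. The catch is that the pooled data must be
deidentified: names, dates of birth and health-card numbers cannot leave the
site.

`hashlink` implements the canonicalize-then-hash solution. At each site,
patient identifiers are normalized into canonical components and combined
into a small number of fixed component combinations; each combination is
hashed with a keyed cryptographic digest under a shared secret. Only the
record ID, the hashed keys and a minimal set of demographics (sex, year of
birth) travel to the data bank. There, records whose keys collide are
candidate matches; accepted matches are closed transitively into link-ID
clusters. Because equal hashes require *exactly* equal inputs, every kind of
tolerance the linkage should have must be built into the canonicalization,
not into the comparison.

## Canonicalization

All fuzziness is applied before hashing:

* **Name cleaning** — uppercase, strip non-alphabetic characters, drop
  titles (DR, MRS, JR, ...; an editable list), keep the longest remaining
  token. Keeping the longest token makes middle names and initials
  harmless; ties keep the first token, deterministically.
* **Nickname resolution** — a bundled table of ~210 common English
  nickname/formal pairs maps aliases (BILL) to formal forms (WILLIAM). The
  table is configuration, not code; production deployments would substitute
  a richer national list. Resolution is applied to *both* name fields: it
  must be symmetric, or the name-order invariance of the name-based key
  (below) would fail whenever a surname that doubles as a nickname (KENNY,
  RAY) swaps position. A side effect is that a misspelling of such a
  surname escapes resolution; the invariance the package guarantees is
  therefore *equality of the canonical phonetic code*, i.e. equality after
  clean → resolve → encode.
* **Phonetic encoding** — the primary Double Metaphone code of the
  canonical token, implemented in full from the published algorithm (the
  slavo-germanic branch rules included). Misspellings that do not change
  pronunciation (SMITH/SMYTH, JON/JOHN, STEPHEN/STEVEN) share a code. Only
  the primary code is used — one key per type per record keeps the keyset
  bounded; the alternate code would double the name-key space for a small
  recall gain and is left out.
* **Date-of-birth canonicalization** — calendar-validated; an impossible
  combination (31 February) drops the day and keeps a year-only date, which
  is logged. For the name-based key a transposition-canonical form places
  the smaller of day/month in the day slot whenever both are ≤ 12, so
  3/5/1990 and 5/3/1990 hash identically while 25/12 (unambiguous) is left
  alone.
* **Sex** — M / F / X (any other non-empty value) / missing.
* **Medicare number** — digits only; requires the full 10-digit card
  number, from which 5 digits are taken (offset configurable, first five by
  default — the choice is arbitrary but must be network-wide constant;
  validated length prevents hashing partial numbers).

Missingness is explicit (`NA`) everywhere; no sentinel values. A component
that is missing silently removes every key that needs it — a key is never a
hash of partial information.

## The four key types

| key | components | requires |
|-----|------------|----------|
| 1 | Medicare digits; full date of birth; sex | Medicare |
| 2 | Medicare digits; postcode; first 3 letters of first name; year of birth | Medicare |
| 3 | sorted pair of name phonetic codes; transposition-canonical date of birth | full DOB, both names |
| 4 | sorted pair of name phonetic codes; Medicare digits | Medicare |

Sorting the two phonetic codes makes first/last name order irrelevant for
keys 3 and 4. Key 3 is the only key that survives a missing Medicare
number, which is why sites that do not record it (anonymous or
government-funded testing) contribute records that can match on key 3 alone.

Hashing is HMAC-SHA256 under a non-empty secret seed; "salted cryptographic
hashing with a secret key" is exactly the construction HMAC standardizes.
Components are joined with the ASCII unit separator, which cannot occur in
any canonical component, so distinct component tuples can never concatenate
to the same message; the key-type number is hashed along with the
components so identical component sets under different types stay distinct.
Digests are emitted as lowercase hex, 64 characters by default and
truncatable (32 hex characters ≈ 128 bits still leaves collisions
negligible at any realistic scale).

## Linkage

1. **Candidate pairs.** An inverted index per key type (records grouped by
   key value) emits every pair agreeing on at least one present key, with
   the complete set of agreeing types. The output is provably identical to
   brute-force all-pairs comparison (tested against one); the index only
   changes the cost.
2. **Acceptance.** Six approaches filter candidate pairs: accept all;
   require equal year of birth; equal sex; both; at least two agreeing key
   types; or a key-3 match plus equal sex. A missing sex or year fails the
   comparison under the default strict policy — when a filter is chosen one
   presumably wants specificity, and treating "unknown" as "equal" would
   silently accept the weakest evidence. A lenient flag inverts this.
3. **Link IDs.** Accepted pairs are closed transitively (connected
   components); every record, including singletons, gets a link ID, and a
   component is labelled by its smallest member record ID so output is
   independent of input order and platform. Filtering happens *before*
   closure: a pair rejected by the approach cannot merge two clusters even
   if both ends share a third neighbour.

## Evaluation

Gold standards come from auxiliary deterministic identifiers:

* **Registry gold standard** — records sharing an enrolment/study ID form a
  cluster; everything else is a verified singleton. Supports all four
  metrics.
* **Specimen gold standard** — a clinic record and a laboratory record
  match when they share a laboratory specimen ID and year of birth with
  test dates at most 7 days apart (inclusive; recorded dates for one
  specimen genuinely drift by a few days). Unmatched records are *excluded*
  rather than called singletons: nothing verifies that they belong to
  distinct persons, so specificity is not estimable from this gold
  standard.

Scoring is record-level. A gold-linked record is correctly linked when the
tool puts it in one cluster with at least one of its true co-members; the
one-co-member definition (rather than all-co-members) is what makes "one
missed pair" cost exactly two records of sensitivity, consistent with how
such counts are reported in practice; a strict all-co-members variant is
available behind a flag. Percentages are rounded half-up to two decimals;
an empty denominator yields `NA` ("not estimable"), never 0 or 100.

### The discordant-serology audit

When specificity cannot be measured, wrong links can still be counted
biologically: HIV and hepatitis C antibody tests stay positive after
infection, so a negative antibody result at least 7 days after a positive
within one linked cluster implies two different people. The audit:

1. excludes records whose own pre-linkage history is already discordant;
2. retains linked clusters containing an antibody result after the
   cluster's initial positive (western blot for HIV, antibody for
   hepatitis C) — discordance is undefined without an initial positive;
3. flags a cluster discordant when any retained negative antibody falls ≥ 7
   days after a positive;
4. attributes the intruding records: when a strict majority of
   post-initial-positive antibody results are negative, the positive
   records are the intruders (one wrongly attached positive record inside a
   longer negative history); otherwise the discordant negatives are. Ties
   count as discordant without reattribution — a conservative reading of
   "most".

PPV is the concordant fraction of retained records. The 7-day window
absorbs specimen-date jitter: with jitter bounded by the window, a
pre-infection negative can never be pushed ≥ 7 days past a positive, so in
simulation every flagged cluster is genuinely a wrong link.

### Estimating specificity from PPV

With sensitivity from a gold standard, PPV from the audit, and the
prevalence of truly-linked records \(\pi\), the Bayes identity

\[ \mathrm{PPV} = \frac{Se\,\pi}{Se\,\pi + (1-Sp)(1-\pi)} \]

inverts to

\[ Sp = 1 - \frac{Se\,\pi\,(1-\mathrm{PPV})}{\mathrm{PPV}\,(1-\pi)} . \]

`estimate_specificity()` implements the inversion with an explicit,
user-supplied prevalence (clamped to [0, 1]); the package deliberately does
not guess \(\pi\), because on deidentified data the truly-linked fraction is
exactly what is unknown — in simulations it comes from the truth table, on
real data it must be argued for.

## The synthetic cohort generator

`generate_cohort()` emulates the data conditions the pipeline must survive,
with everything a pure function of the seed:

* persons with identities drawn from bundled name pools (~270 given names,
  ~340 surnames), uniform birth dates 1940–2005, postcodes 3000–3999, and
  unique 10-digit Medicare numbers;
* per-site EMR corruption, each with its own rate: Medicare blanking, name
  typos (split configurably into phonetic-preserving and phonetic-breaking
  edits — the two regimes are what separate fuzzy-match survival from
  sensitivity loss), nickname substitution, day/month transposition,
  year-only dates; duplicate EMRs within a site;
* clinic test events mirrored to laboratory records sharing a specimen ID
  with a date jitter of at most `specimen_date_jitter_days` (≤ 7, the gold
  standard tolerance);
* HIV / hepatitis C serology that follows infection status exactly:
  negative before the infection date, positive from it on, a confirmatory
  western blot accompanying the first positive HIV antibody, and *no assay
  errors* — so any post-linkage discordance is attributable to linkage, the
  assumption the audit rests on. A jittered laboratory date that would
  carry a pre-infection negative past the infection date is snapped back to
  the clinic date to keep the invariant exact.

The default site mix (an editable CSV) follows the qualitative pattern of a
mixed surveillance network: six general clinics with near-complete Medicare
recording, one sexual-health clinic recording it for roughly half of
patients, and four laboratories spanning a few percent to near-complete.
Duplicate-EMR rates are order-of-magnitude choices (3%) — published
site-level duplication rates are not available.

By default the generator resamples identities so that no two persons share
a (phonetic-name-pair, date-of-birth) signature or a Medicare number. Real
populations offer no such guarantee (twins, namesakes); the flag exists so
that the clean-data limit — complete identifiers, zero corruption implies
exact truth recovery at 100% sensitivity/specificity/PPV/NPV — is a theorem
about the pipeline rather than a statement about name-pool luck. Tests of
robustness to *shared* identities should disable it.

`inject_false_links()` perturbs a truth clustering with cross-person links
at a chosen rate, for estimator calibration.

## What the simulations do and do not show

The bundled studies (`inst/studies/studies.R`, driven by both the test
suite and `scripts/acceptance.R`) check three things:

* **Clean-data limit** (1,000 persons, ~3,700 records): all six approaches
  score 100% on all four metrics.
* **Missingness response** (1,200 persons, one laboratory blanking
  Medicare at 97%): the only-key-3 fraction at that laboratory matches the
  configured rate within binomial error, and multi-key matching loses the
  cross-site links that single-key matching keeps.
* **Estimator recovery** (10,000 records: 2,500 duplicated persons, all
  HIV-positive with an early confirmed positive and later positive
  antibodies, plus 5,000 singletons of mixed serostatus; false links
  injected only between serodiscordant persons whose discordance is
  observable, i.e. the negative's antibody test falls ≥ 7 days after the
  positive partner's initial positive): the audit PPV lands within two
  Monte-Carlo standard errors of the truth-measured PPV, and the Bayes
  inversion applied to (audit PPV, measured sensitivity, true prevalence)
  recovers directly measured specificity. The duplicated persons are made
  uniformly positive so that the *auditable* subset of clusters is not
  selected for correctness — with mixed serostatus among duplicated
  persons, correct all-negative clusters would drop out of the audit while
  false mixed clusters stayed, biasing the audited PPV downward relative to
  the population PPV that the specificity inversion needs.

These are simulations under the generator's assumptions. They do not show
robustness to shared real-world identifiers (twins, family Medicare cards
with adjacent reference numbers), to non-English name phonetics, to
systematic date errors beyond transposition, or to assay error; all of
those would need real linked data with an external truth.

## Numerical and degenerate-input conventions

* Percentages: half-up rounding to 2 decimals (`pct()`, `round_half_up()`);
  comparisons against published values use the published precision.
* Empty denominators: `NA`, reported as "not estimable".
* Invalid calendar dates: day dropped, year kept, record logged.
* Ties: longest-token ties keep the first token; cluster labels are the
  smallest member ID; the audit's majority rule treats a tie as discordant
  without reattribution.
* Record IDs are opaque and never derived from identifiers; they are stable
  across reruns only when supplied in the input file.

## Parameters that matter

| parameter | default | unit | why |
|-----------|---------|------|-----|
| `digest_len` | 64 | hex chars | full HMAC-SHA256; truncation configurable |
| `medicare_offset` | 0 | digits | which 5 card digits enter the keys |
| `date_tolerance_days` (specimen gold) | 7 | days | recorded-date drift for one specimen |
| `window_days` (audit) | 7 | days | minimum gap for biological discordance |
| `strict_missing` (filters) | TRUE | — | missing sex/year fails a filter |
| `all_comembers` (scoring) | FALSE | — | one true co-member suffices |
| `specimen_date_jitter_days` (generator) | 2 | days | must stay ≤ the audit window |
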