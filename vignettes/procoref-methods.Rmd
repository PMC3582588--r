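---
title: "Methods: rule-based protein coreference resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based protein coreference resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procoref)
```

## The task and its assumptions

Given an abstract, its gold protein mentions (`.a1` term annotations) and a
syntactic parse, the system links anaphoric expressions — pronouns and
definite noun phrases — to the preceding noun phrase they corefer with. The
task definition supplies three assumptions the design leans on:

* **Gold protein mentions are input.** Semantic classification of nominals
  can therefore be anchored on exact mention spans (ANTE-SEM) rather than
  on learned named-entity recognition.
* **Anaphoric coreference only.** Antecedents precede anaphors; cataphora
  is out of scope, so "preceding" is literal: a candidate's span must end
  before the anaphor starts.
* **Only protein references count.** The primary metric scores
  (anaphor, antecedent-protein) pairs derived by collecting every gold
  protein mention contained in the antecedent expression; links whose
  antecedent holds no protein are invisible to it.

The resolver is entirely deterministic: same parse, same configuration,
same output. There is no training step; the lexicons and rules are fixed.

## Pipeline

`resolve_document()` composes five stages. Parsing sits behind a backend
contract (tokens + POS + lemma, NP chunks with head tokens and a
subordinate-clause flag, labelled dependency edges); every test and the
synthetic corpus use gold-parse fixtures (`.parse.jsonl`), so correctness
of the *resolution* rules is measured independently of any parser's errors.

**Markables.** NP chunks without subordinate clauses, one per head token
(the longest chunk; equal lengths break to the earliest start purely for
stability), plus every pronoun token. Standalone demonstratives ("and
*this* is likely…") count as pronouns; determiners that open an NP do not.

**Anaphor selection.** Pronouns and definite NPs, with filters:

* first/second-person and gendered pronouns (POS/lemma based);
* pleonastic *it*, via four surface patterns ("It is clear that…", "It is
  important for X to…", "It seems/appears/means/follows…", "makes/finds/
  takes it … to …"). Optional slots are bounded at three tokens — the
  patterns state no bound, and unbounded gaps over-match;
* possessive pronouns whose context NP (the smallest NP the possessive
  determines) contains none of the 12 protein keywords (*binding,
  expression, interaction, regulation, phosphatase activity, localization,
  gene, sequence, region, phosphorylation, transactivation,
  transcription*) — PRO-ANA-SEM;
* definite NPs whose singular-normalized head word is outside the
  protein head-word list (*protein, gene, factor, molecule, element,
  family, inhibitor, receptor*) — DEFNP-ANA-SEM. The source list is
  announced as "top seven" but enumerates eight words; we ship all eight;
* definite NPs that themselves contain a gold protein mention ("the c-Myc
  protein"). This filter is not stated in the source method description,
  but its worked example treats such NPs as antecedent material only,
  which is also the sensible reading: an expression carrying its own
  protein mention is a self-contained reference with nothing to resolve.
  It is a config toggle (`exclude_self_contained_dnp`, default on).

Relative pronouns always pass selection. Demonstrative pronouns with
clausal antecedents also pass — their links simply contain no protein and
drop out of the primary metric.

**Candidate selection.** Markables ending before the anaphor, within
`window` sentences (default 2: the two preceding sentences plus the
anaphor's own — within which 97.0% of protein-link antecedents fall in
annotated training data). Excluded: pronouns that are themselves anaphors
or were person/pleonastic-filtered (they resolve to nothing); candidate
pronouns outside the anaphor's pronoun family (default families
it/its/itself, they/their/them/themselves, this/that/these/those — only
the first is fixed by the method description, the others are conventional
and configurable); arguments of dependency relations that cannot corefer
(default labels `poss-arg12`, `prep-arg12`; "a dominant negative form *of*
its …" blocks *form* as an antecedent of *its*), plus any candidate whose
span contains the anaphor. Dropping non-protein candidates of protein
anaphors is available as a hard filter
(`hard_semantic_candidate_filter`, default off) but is normally left to
Rule 2's preference, which degrades more gracefully when classification
errs.

**Prediction.** Relative pronouns link to the chunk the parser attached
the relative clause to; if the parser found none, no link is produced (the
fixed rule stands or falls with the parse). All other anaphors run a
nearest-first tournament: the nearest candidate is incumbent, each farther
candidate challenges under the decision list; a rule decides only when
exactly one candidate satisfies its condition.

* Rule 1, number agreement: "no conflict" is the condition; `unknown`
  number (foreign-word heads, unrecognized forms) never conflicts. This is
  deliberate — annotated data contains genuine agreement violations, so
  unknown must not behave like a mismatch.
* Rule 2, semantic constraint: applies only when the anaphor is classified
  PROTEIN; candidate classes come from ANTE-SEM for nominals and
  PRO-ANA-SEM for possessives.
* Rule 3, discourse preference: "prefer the farther" for anaphor types
  mapped to far-preference; default map covers personal and demonstrative
  pronouns. The method description says only that the preferred direction
  depends on the anaphor type and that the rule helps pronouns, so the map
  is configuration (`disc_pref_map`), and the default rule stays fixed at
  closer-preference.
* Default: closer candidate; closeness is end offset (ties: the inner,
  later-starting chunk), so the default never ties.

With transitive preferences — which a lexicographic decision list is —
the tournament is order-independent; tests assert the winner beats every
other candidate pairwise and survives a reversed visiting order.

Presets `rb-min` … `rb-full` toggle Rules 1–3; `rb-full-no-pro-ana-sem`
and `rb-full-no-defnp-ana-sem` ablate the Step-2 semantic filters, which
all presets otherwise keep on.

## Scorers

`score_protein_links()` deduplicates both sides, matches response to gold
links (same protein id; anaphor spans equal under `strict`, overlapping
under `lenient` matching — the default, since shared-task practice allowed
boundary leniency), and credits each gold link at most once via maximum
bipartite matching (igraph).

The partition metrics operate on `mention_partition` objects built from
links by transitive closure. MUC counts recovered spanning links per key
chain; B³ averages per-mention chain-overlap ratios; CEAF aligns chains
one-to-one by maximum-weight bipartite matching (the Kuhn–Munkres optimal
assignment, igraph again) under mention (`|K∩R|`) or entity
(`2|K∩R|/(|K|+|R|)`) similarity; BLANC averages precision/recall/F over
coreferent and non-coreferent mention pairs. Dialect choices the
literature leaves open are pinned as: key singletons count in B³/CEAF/
BLANC universes and are excluded from MUC denominators; twinless response
mentions count for precision only, with the absent side treating the
mention as a singleton; undefined sides (all-singleton keys in MUC, no
coreferent or no non-coreferent key pair in BLANC) report 0 and carry a
flag rather than NA, so corpus aggregation stays total.

Every scorer is checked against an independently coded brute-force oracle
(exhaustive chain-bijection search for CEAF, contingency-table closed form
for BLANC, pair-counting for B³) on **all** key/response partition pairs
over up to six mentions — 44,000+ pairs — to 1e-9.

## The synthetic corpus

`generate_corpus()` builds documents from schematic episode templates that
carry their own gold parse, so offsets, chunks, heads, edges and links are
correct by construction. The generator reproduces the statistical
structure the rules exploit, and nothing else:

* **Type mix** (default): possessive 25.3%, relative 18.6%, demonstrative
  NP 15.2%, demonstrative pronoun 13.6%, the-definite NP 10.9%, personal
  pronoun 9.6%, other definite NP 2.2%, indefinite NP 1.6%, proper name
  1.5%, other pronoun 0.8%, reflexive 0.8% — the anaphor typology measured
  on annotated training data. Documents draw a fixed number of episodes
  (sentences/2.1) so the pooled mix is an unbiased sample; stopping on a
  sentence count would over-represent short episode types.
* **Antecedent distance** (default): sentence offsets 0/1/2/3 with
  probabilities .30/.40/.27/.03 — exactly 97.0% within two sentences,
  matching the reported training statistic. Empirical corpus shares
  fluctuate binomially around this, which is why tests check the
  configured mass exactly and the empirical share within a 3-sigma band.
* **Rule-specific traps.** Each episode type plants the distractor its
  rule needs: possessives get a nearer singular non-protein NP (Rule 2's
  case), the-definite NPs a nearer plural NP (Rule 1's case), personal and
  demonstrative pronouns a nearer wrong candidate with the true antecedent
  farthest in the window (Rule 3's case; filler sentences with no
  markables keep the window clean). Relatives and reflexives are solvable
  by every preset; indefinite/proper/other-type anaphors are planted but
  unreachable by the selection rules, capping recall at the same value for
  every preset — as in real data.
* **Cue and noise rates.** `keyword_cue_rate` (default 0.9) controls how
  often a protein-referring possessive NP carries a keyword; uncued ones
  are filtered and cost recall everywhere equally.
  `nonprotein_possessive_rate` (default 0.15) injects possessives whose
  referent is not a protein, with a protein mention nearby as bait: these
  are what PRO-ANA-SEM exists to remove, and without them an ablation of
  that filter could only gain recall, inverting its real effect.
  `protein_density` (default 0.15) adds farther distractor protein
  mentions between episodes.

What passing tests on this corpus shows: the rules fire for the reasons
claimed, their ablation ordering F(rb-full) ≥ F(rb-min+1,3) ≥ F(rb-min) is
structural, and the I/O and scoring machinery is exact. What it does not
show: performance on real abstracts, where parse errors, coordination,
apposition and unmodelled anaphora types dominate the error budget. The
synthetic numbers (protein-link F ≈ 0.96 for `rb-full` at the defaults)
are therefore upper bounds under idealized parses, not comparable to
corpus results; only the qualitative ordering carries over.

## Numerical and degenerate-input choices

Offsets are 0-based half-open over UTF-8 text, the standoff convention.
All tie-breaks (chunk dedup, candidate ordering, default closeness) are
fixed and documented so runs are reproducible byte for byte. Degenerate
inputs: empty documents and empty candidate sets resolve to nothing;
unparsed sentences are skipped with a warning and contribute no markables;
empty lexicons make PRO-ANA-SEM always UNKNOWN and DEFNP-ANA-SEM always
NON_PROTEIN (with the filters on, this reduces anaphor selection toward
relatives and plain pronouns); scorers flag rather than error on undefined
denominators.

Problem sizes used by the shipped checks were chosen to exercise the
statistics stably: the scorer sweep enumerates all partition pairs up to
six mentions; the acceptance corpus uses 220 documents of ~10 sentences
(~1100 scored anaphors), at which the type-mix and window statistics have
standard errors comfortably below the differences being demonstrated.

## Known limitations

* Resolution quality is bounded by the parse: NP boundaries and
  relative-clause attachment are taken as given, and the fixed relative
  rule fails exactly where the parser does.
* Number agreement is a hard preference; genuinely number-violating
  coreference (it ← "…protein fractions") is unrecoverable by design, and
  one packaged fixture documents this failure mode.
* Appositions, indefinite-NP and proper-name anaphors are not selected.
* PRO-ANA-SEM inspects only the NP the possessive determines, not a wider
  clause window; the keyword list is small and manual.
* Chains are not propagated: each anaphor is resolved independently, and
  predicted links do not feed later semantic classification.
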