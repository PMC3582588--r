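# procoref

Rule-based resolution of anaphoric protein references in biomedical text,
with the standoff annotation I/O, evaluation metrics and synthetic corpus
generation needed to develop and test such a system fully offline.

## The problem

Biomedical abstracts constantly refer back to proteins without naming them:

> "This ability of **CIITA** to facilitate promoter occupation is
> undissociable from [its] transactivation potential."

Event-extraction systems that miss the link between *its* and *CIITA* lose
the information the sentence carries. Protein coreference resolution takes
a text plus its gold protein mentions (BioNLP-ST style `.txt` + `.a1`
files) and produces anaphor → antecedent links; the task's primary metric
scores the derived (anaphor, antecedent-protein) pairs.

`procoref` implements a deterministic five-step pipeline over parser
output:

0. **Preprocessing** — sentence segmentation, tokens, POS, noun-phrase
   chunks with head words, and labelled dependencies, supplied by a
   pluggable backend or by gold-parse fixture files (`.parse.jsonl`), so
   nothing here requires a live parser.
1. **Markable detection** — NP chunks that contain no subordinate clause;
   for chunks sharing a head word only the longest survives; every pronoun
   is a markable.
2. **Anaphor selection** — pronouns and definite NPs, minus first/second
   person and gendered pronouns, pleonastic *it* (four surface patterns),
   possessives whose context NP lacks a protein keyword (PRO-ANA-SEM) and
   definite NPs whose head word is not a protein head word (DEFNP-ANA-SEM).
3. **Candidate selection** — preceding markables within a window of 2
   sentences, minus arguments of non-coreferring dependency relations
   (`poss-arg12`, `prep-arg12`) and pronouns outside the anaphor's pronoun
   family.
4. **Antecedent prediction** — relative pronouns take the NP the parser
   attached them to; every other anaphor runs a nearest-first tournament
   under the decision list

   * Rule 1 (NUM-AGREE): prefer the candidate that does not conflict in
     grammatical number;
   * Rule 2 (SEM-CONS): if the anaphor is a protein reference, prefer a
     protein candidate;
   * Rule 3 (DISC-PREF): for some anaphor types, prefer the farther
     candidate;
   * default: prefer the closer candidate (never ties).

Presets `rb-min` (no rules: nearest candidate), `rb-min+1`, `rb-min+2`,
`rb-min+3`, `rb-min+1,3` and `rb-full` reproduce the standard ablations.

Scorers: the protein-link metric (strict or lenient anaphor-span matching,
maximum bipartite matching so each gold link is credited once) and the
partition metrics MUC, B³, CEAF-M, CEAF-E and BLANC, each verified against
independent brute-force oracles in the test suite.

## Worked example

```r
library(procoref)
fx <- packaged_examples()[["PMID-7964516"]]   # text, gold parse, mentions
links <- resolve_document(fx$document, fx$sentences, preset_config("rb-full"))
links[, c("anaphor_text", "antecedent_text", "anaphor_type", "rule")]
```

```
  anaphor_text
1         this
2          its
3        which
                                                     antecedent_text
1                                               apoptotic cell death
2                                                              c-Myc
3 a dominant negative form of its heterodimeric binding partner, Max
  anaphor_type        rule
1     PRON_DEM   NUM-AGREE
2    PRON_POSS   NUM-AGREE
3        RELAT FIXED-RELAT
```

The possessive *its* resolves to *c-Myc*: the nearer candidates *studies*
(plural) and *apoptosis* (non-protein, while "its heterodimeric **binding**
partner" marks the anaphor as a protein reference) lose under Rules 1
and 2. Under `preset_config("rb-min+1,3")` — no semantic constraint — the
same anaphor resolves to the nearer *apoptosis* instead. The `rule` column
is the decision that settled the final pairwise comparison.

On a generated corpus the ablations separate cleanly
(`score_corpus(generate_corpus(generator_config(seed = 1)), preset_config(p))`),
protein-link F rising monotonically from `rb-min` through `rb-min+1,3` to
`rb-full`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/procoref.R simulate --out gold/ --seed 3 --n-documents 30
Rscript inst/cli/procoref.R resolve  --input gold/ --out pred/ --preset rb-full
Rscript inst/cli/procoref.R evaluate --gold-dir gold/ --pred-dir pred/ --metric all
Rscript inst/cli/procoref.R explain  --input gold/        # decision trace
```

## Limitations

Markable boundaries are exactly the parser's NP boundaries, so parse
errors (coordination, NP attachment) propagate; number agreement is treated
as a hard preference although real data violates it occasionally;
appositional, indefinite-NP and proper-name anaphors are outside the
selection rules. See the methods vignette (`vignettes/procoref-methods.Rmd`)
for the full account of rules, defaults and design choices.
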