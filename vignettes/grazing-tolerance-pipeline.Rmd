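---
title: "Methods: exact DE testing and candidate discovery in unreplicated three-library transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact DE testing and candidate discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazetx)
```

## The design this package serves

A grazing-tolerance transcriptome study typically sequences three
unreplicated bulk libraries: a tolerant population before grazing (TU), the
same population after grazing (TG), and an intolerant population after
grazing (IG). Two contrasts carry the biology: the *grazing response*
(TG vs TU, baseline TU) and *differential tolerance* (IG vs TG, baseline
TG). Each library is a pool over many individuals, so there is exactly one
observation per condition and replicate-aware models (negative binomial with
estimated dispersion) have nothing to estimate. The defensible alternative
is an exact test that conditions on the observed counts under a Poisson
model, which is what this package implements, together with the downstream
enrichment, candidate-pattern and SNP machinery such a study needs.

## The exact conditional Poisson test

Let `x` and `y` be a transcript's mapped read counts in two libraries with
clean-read totals `N1` and `N2` (clean totals, not mapped totals — the
library size is the sequencing depth, so totals are supplied explicitly and
never inferred by summing the count table). Under the null hypothesis of
equal relative expression, conditioning on `x` gives

```
P(Y = y | x) = r^y (x+y)! / ( x! y! (1+r)^(x+y+1) ),   r = N2/N1,
```

a negative-binomial distribution with size `x + 1` and success probability
`1/(1+r)`. All probabilities are computed in natural-log space through
`lgamma`, and only the shorter tail is ever summed directly (the other side
comes from the complement), so the test is stable from `x = y = 0` up to
counts of 10^6.

**Two-sided rule.** The source description of the test calls for the
probability of being "more differential than observed", without an
unambiguous display form. Doubling inclusive tails on both sides —
`2·min(P(Y≤y|x), P(Y≥y|x))` — is the common convention but is *not*
symmetric under swapping the libraries: the discrete point mass at the
observed pair breaks the identity by `O(P(Y=y|x))`. We instead double the
smaller of the two one-sided tails taken each in its own conditioning
direction:

```
p = min(1, 2 · min( P(Y ≤ y | x),  P(X ≤ x | y) ) ),
```

and `P(X ≤ x | y; N2, N1) = P(Y > y | x; N1, N2)` exactly, so the rule is
exactly symmetric (our tests require agreement to 1e-12 under the swap).
Every side is still an inclusive lower tail in one orientation, and the
boundary cases behave as expected: `p = 1` for `x = y = 0` and for any
`x = y` with equal totals (where `P(Y ≤ x | x) = 1/2` exactly). p-values
that underflow double precision are clamped to the smallest positive double
so they remain in (0, 1].

Fold changes are `log2(FPKM_b / FPKM_a)` after substituting 0.01 for zero
FPKM, so transcripts private to one library get a finite, large fold change
(about ±6.64 against an FPKM of 1). Transcripts with zero counts in both
libraries are retained with `p = 1` and `log2FC = 0` rather than filtered:
filtering is a modelling choice we prefer to make explicit, and retention
only makes multiplicity correction more conservative. Multiplicity uses
Benjamini–Hochberg step-up q-values (the description of the correction mixes
family-wise and FDR language; the stated threshold "FDR ≤ 0.001" decides the
FDR reading). DE is called at `q ≤ 0.001` and `|log2FC| ≥ 1`, both
configurable.

## Over-representation and dual-context selection

Enrichment of a term with `M` annotated genes, `m` of them differentially
expressed, against a universe of `N` annotated genes containing `n` DEGs is
the hypergeometric upper tail `P(X ≥ m)`, computed through `phyper`. Two
choices deserve note:

* **The unit is the gene, not the transcript.** DE is decided per
  transcript, but isoform multiplicity would inflate per-term counts, so a
  gene (isoform group) is a DEG when at least one of its transcripts is DE.
* **The universe is the annotated universe of each ontology** — genes with
  at least one GO term for GO, at least one pathway for KEGG — not all
  assembled genes. DEGs outside the universe are dropped (with a logged
  count).

GO significance uses Bonferroni correction at 0.05; KEGG reports both the
Bonferroni-corrected p and the BH q, since pathway tables conventionally
print both. Dual-context selection retains a term only when its corrected p
is ≤ α (default 0.05, inclusive) in *both* contrasts; the comparison column
is configurable (`p_bonf`, raw `p`, or `q`) because published tables do not
always state which value they print. A term present in only one context
gets p = 1 for the missing context plus a warning. Output is ordered by
tolerance-context p, ties broken lexicographically by term id for
determinism.

## Candidate expression patterns

A transcript is a *suppressed-tolerant-advantage* candidate when it is DE
down in TG vs TU and DE with IG below TG; an
*upregulated-tolerant-advantage* candidate when DE up in TG vs TU and DE
with IG below TG. Both requirements use the DE calls (flag and fold-change
sign), not raw FPKM comparisons: "higher/lower" claims should carry the
same statistical guarantee as the contrasts themselves. Every transcript
maps to exactly one of the three patterns (including `other`).

Genes aggregate by a consistency rule: a gene takes a non-`other` pattern
iff at least one isoform shows it and no isoform shows the opposite
pattern. Non-DE (`other`) isoforms do not veto — partial isoform detection
is the norm in de novo assemblies — but one directional conflict does.
Candidates are finally intersected with the dual-context-selected pathways:
a reported candidate must both show a pattern and be annotated to at least
one selected term, and the supporting terms are listed.

## SNP calling, filtering and effect annotation

The SNP stage consumes per-position base compositions (the upstream
aligner/pileup is out of scope). Per library, alleles with frequency
≥ 0.2 and ≥ 2 supporting reads at coverage ≥ 4 are retained; one retained
allele yields that base, two yield the IUPAC ambiguity code, more than two
drop the rarest allele stepwise (a tie rejects the position). **These
thresholds are package defaults, declared and configurable** — the
motivating study names neither a caller nor thresholds.

The reporting rule is taken literally from the source tables' caption: keep
a position iff the two tolerant libraries are monomorphic for the same
single base and the intolerant library differs (another single base or any
ambiguity code). Published tables of this kind contain rows that violate
their own caption (e.g. the same heterozygous code in all three libraries);
we implement the caption rule and such rows are simply not reported.
Positions are 1-based from the 5' end on the sense strand. Inside the CDS
the affected codon is translated with each alternative allele under the
standard genetic code; substitutions are reported per allele as
`Asn->Ile (T); Asn->Ser (G)`-style strings (stop as `X`), positions before
or after the CDS as UTR, transcripts without a CDS as noncoding. A
reference-base mismatch between the composition table and the sequence is a
hard error, not a silent skip.

## Welch tests

Phenotype contrasts (two groups of plants measured for continuous traits)
use the Welch unequal-variance t-test, computable directly from printed
summaries (mean, SD, n per group; SDs are sample SDs with divisor n − 1) or
from raw values. The summary form exists so published tables can be
reproduced exactly: the four trait contrasts in the motivating design
reproduce to their printed precision (8.8e-4, 1.3e-6, 6.5e-9, 2.2e-7).

## The synthetic stated world

`sim_config()` defaults describe the world the package validates against;
they were chosen once, from the study design, and are not tuned against
test outcomes:

* **2,000 genes, 1–3 isoforms, 300–3,000 bp, three libraries of 2×10^6
  clean reads** — a desk-scale version of a ~79k-transcript, ~50M-read
  experiment that keeps the full pipeline under a few seconds.
* **Counts are Poisson** around `FPKM × kb × depth/10^6`, because the DE
  test's null is exactly Poisson and the design has no replicates to reveal
  over-dispersion; an over-dispersion knob exists for robustness
  experiments, default off.
* **Planted effects are |log2| = 2**, twice the calling threshold, applied
  as a per-gene multiplier chain (`TU = g`, `TG = g·2^e_r`,
  `IG = g·2^{e_r+e_t}`) so each contrast carries exactly its own effect.
* **Candidate genes sit at 500 FPKM** — candidate transcripts in this kind
  of figure are abundantly expressed — which makes their weakest isoform
  (300 bp, doubly suppressed) still comfortably detectable at q ≤ 0.001.
* **Planted enriched terms** have 100 member genes of which 40% receive the
  up-in-tolerant-only signature (`e_r = +2`, `e_t = −2`), a 4-fold DEG
  over-representation against the ~10% background; candidate genes are also
  annotated to the planted terms, mirroring how real candidates emerge from
  selected pathways.
* **Heterozygous base compositions use the expected 50/50 allele split
  deterministically**, with only sequencing errors (rate 0.01) drawn
  stochastically. The libraries this emulates are bulks pooled over ten
  individuals, so per-position allele dosage sits near its expectation;
  this choice also makes exact (100%, zero-decoy) SNP-filter recovery a
  property of the filter rather than of binomial sampling luck. Decoys
  cover every violation class: tolerant-discordant, all-heterozygous,
  tolerant-coverage-too-low, and no-variation.

What a green run does *not* establish: robustness to over-dispersed counts,
mapping artefacts, isoform-assignment errors, allele-specific expression,
or assembly chimeras — none of which the generator emulates.

## Numerical choices and limitations

* Tail sums use `lgamma` + log-sum-exp; the open upper tail is accumulated
  in chunks of 512 terms until a geometric-series bound shows the remainder
  is below 1e-15 of the accumulated mass.
* Bonferroni and BH are applied per ontology and per contrast family (the
  number of terms tested).
* Ties in every ordered output are broken by id for byte-identical reruns.
* The CLI (`inst/cli/grazetx`) is a thin dispatcher over the exported
  functions; configs are JSON (`default_config()` documents the schema),
  and seeds are echoed into `config.json` for provenance.
* The package does not parse SAM/BAM or FASTQ, does not traverse the GO
  graph (annotation maps are flat sets as given), and implements no
  replicate-aware or normalisation-beyond-FPKM models by design.
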