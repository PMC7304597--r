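---
title: "Scanning genomes for functional non-tandem-duplicated clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for functional non-tandem-duplicated clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A functional non-tandem-duplicated cluster (FNTDC) is a run of
co-localized, mutually non-homologous genes sharing a GO Biological
Process annotation more densely than chance allows. The scanner
formalizes "more densely than chance" as a hypergeometric draw: if the
genome carries $N$ GO-BP-annotated genes of which $K$ carry term $t$,
and a window holds $n$ genes of which $k$ carry $t$, the enrichment
P-value is the upper tail

$$P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n).$$

Three modelling commitments follow from the biology:

* **Windows are counted in genes, not base pairs.** Intergenic and
  repeat content varies enormously across plant genomes; a fixed-kb
  window would make cluster calls a function of repeat load rather
  than gene organization, and would break cross-species comparison.
  All window arithmetic in the package is therefore on gene *ranks*
  within the per-chromosome order of GO-BP genes; base-pair spans are
  only reported, never tested.
* **Only GO-BP genes form the universe and the windows.** A gene
  without a GO-BP tag cannot contribute evidence for or against
  functional clustering, so it neither counts toward window size nor
  enters $N$. Unannotated genes inside a called span are retained and
  reported as interspersed candidates — co-localization is a
  functional hint for them — but they never enter the test.
* **Tandem duplicates must not masquerade as clusters.** A tandem
  array trivially shares a term; before each test, window genes whose
  proteins are mutually similar beyond a stringency threshold are
  collapsed to their first-by-coordinate member, which stands in as a
  placeholder ("counts as one gene").

# The scanning procedure

Master windows of `master_size` (default 24) consecutive GO-BP genes
tile each chromosome without overlap; a trailing block is kept when it
holds at least 6 genes (the shortest testable sub-window) and dropped
otherwise. Inside each master window a discrete set of sub-windows is
probed; the sub-window whose best term attains the minimum P wins, and
a call is emitted iff that minimum passes the threshold. At most one
call per master window.

The default sub-window scheme is a systematic tiling — lengths
24, 18, 12, 8 and 6 at offsets $\{0\}$, $\{0,6\}$, $\{0,6,12\}$,
$\{0,8,16\}$ and $\{0,6,12,18\}$ — 13 sub-windows in total, the master
window itself among them, spanning lengths 6–24. The exact offsets of
the tiling are a design choice of this package (any scheme with 13
windows covering 6–24 genes satisfies the published description; the
scheme is a `subwindow_scheme()` value, so users can substitute their
own). The shortest default sub-window is 6 genes: plant functional
clusters reported to date hold 3–10 genes, and 6 keeps the scheme
small while letting the minimum-3-genes rule fire inside any
sub-window. Exhaustive mode probes every contiguous sub-window of at
least `min_length` (default 3) genes — 253 for a full master window —
at roughly twenty times the cost; it removes the discreteness that the
default scheme imprints on called cluster sizes.

Two readings of the published procedure were genuinely open and were
fixed as follows:

* *The "13" includes the master window.* The master window is treated
  "de facto as a sub-window" and compared with the rest, so the count
  of 13 includes it. For short trailing masters the scheme is clipped
  to windows that fit, and the master itself is always probed.
* *Master windows step by their own size.* The published phrase
  "genes 25 to 49" enumerates 25 genes for a 24-gene window; we read
  this as an off-by-one and use adjacent, non-overlapping windows
  (step 24).
* *Ties.* If two sub-windows attain the same minimum P, the one with
  fewer genes wins, then the smaller offset — the tightest, leftmost
  cluster consistent with "best approximation of cluster length and
  positioning". Ties are exact floating-point equalities and occur
  essentially only in symmetric synthetic fixtures.
* *The threshold is applied after selection, not during.* The winning
  sub-window is chosen by minimum P among all candidates with some
  term at count ≥ 3; the P threshold then decides whether it becomes a
  call. Consequently call sets at nested thresholds are nested with
  identical winning sub-windows, which `filter_calls()` exploits.

# Tandem-duplicate collapsing

All-vs-all pairwise local alignment (Smith–Waterman via
`Biostrings::pairwiseAlignment`) is computed once per master window
over the representative proteins and reused by its sub-windows.
Substitution matrix BLOSUM62 with affine gaps (open 11, extend 1) —
the classic gapped-BLASTP defaults. Identity is matches over all
alignment columns *including* gap columns, and the two coverage ratios
divide that column count by query and subject length respectively
(BLAST tabular convention; gap-excluded variants are recorded in the
hit dumps but do not drive the filter). A pair is a tandem call when
identity and both ratios meet the stringency setting; groups are
single-linkage connected components ("all against all" implies
component closure rather than star linkage to the first gene), and
each group keeps its first member by (start, end, gene id).

E-values are computed from the Karlin–Altschul formula with standard
gapped BLOSUM62 constants ($\lambda = 0.267$, $K = 0.041$, search
space $= q_\mathrm{len} \times s_\mathrm{len}$). They gate only what
is *recorded* (E ≤ 10) and reported; tandem calls rest entirely on
identity and coverage.

Two performance-relevant choices:

* **Seeded prescreen.** Inside a scan, a pair is aligned only if the
  two proteins share an exact word whose length is chosen per pair so
  that a pair actually meeting the setting's identity/coverage
  thresholds would share such a word with overwhelming probability
  (expected word count ≥ 20 under independent columns; at 40%
  identity the word length degenerates to 1 and every pair is
  aligned). This mirrors BLASTP's word seeding. It is a heuristic in
  the same sense BLAST is: a pathological pair exactly at threshold
  with adversarially spaced mismatches could fail to seed. Bundle
  dumps (`BLAST____EVERYTHING`) re-align all pairs exhaustively.
* **Single best local alignment per pair.** Multiple HSPs are not
  enumerated; the per-pair filter columns imply one row per pair.

# Enrichment details

`hypergeom_upper()` delegates to `stats::phyper()` (log-space stable);
the test suite pins it against brute-force subset enumeration over
every universe of up to 15 genes to 12 significant digits. Reported
rows follow the GOstats `hyperGTest` column layout, with the odds
ratio $k(N-K-n+k)/\big((n-k)(K-k)\big)$ reported as infinite when
$k = n$ or $k = K$. No multiple-testing correction is applied: the
method filters on raw hypergeometric P thresholds (the supported grid
is 1e-5…1e-8, default 1e-6), so P-values are screening scores, not
calibrated error rates. The minimum-count rule (`min_count = 3`,
applied to the *collapsed* count $k$) is the prerequisite for any
call.

The universe ($N$, $K$) is **not** tandem-collapsed; collapsing
applies only to the tested window. Collapsing is defined per window
("prior to hypergeometric testing" within a candidate window), and a
genome-wide collapse would require a global homology partition the
procedure never constructs. The effect is mildly conservative:
universe counts include duplicates that windows shed.

Degenerate inputs behave as follows: a window with no term at
`min_count` yields no call (a normal outcome, not an error); a
chromosome with fewer than 6 GO-BP genes yields no windows; genes
without a protein sequence are kept in the catalog (they can carry GO
tags and appear in spans) but are never tandem-grouped; $K = N$ forces
$k = n$ and $P = 1$.

# The synthetic-data generator

`simulate_genome()` emulates the statistical structure the scanner
assumes: multiple chromosomes of genes with sampled lengths (default
1–5 kb) and intergenic gaps (2–20 kb), a background GO-BP vocabulary
(default 500 terms) assigned i.i.d. per annotated gene (1–4 terms) so
that no background term clusters positionally beyond chance, 38% of
genes lacking GO-BP, 20% lacking any GO tag (the shares reported for
well-annotated plant genomes, where more than a third of genes carry
no functional annotation), planted clusters of 4–6 consecutive,
mutually unrelated random proteins sharing one reserved term, and
tandem arrays of 3–6 copies of one protein. Planted features are
placed at least five gene slots apart, and the same seed reproduces
the genome byte for byte.

Protein sequences are i.i.d. uniform over the 20 residues, so
unrelated proteins essentially never reach 40% identity over 40%
coverage — "non-homologous by construction" is therefore a testable
property, not an assumption. `mutate_protein()` substitutes per site
with probability $1 - \text{target}$, drawing from the 19 alternative
residues, with no indels. Tandem copies each diverge from a common
ancestor by *half* the target divergence (star topology), so the
configured `tandem_identity` is realized as the **pairwise** identity
between copies — at the default 0.95, pairwise identities comfortably
exceed 90% and stay below 98%, which is what makes the stringency
contrast sharp: settings 1–3 collapse such an array, setting_4 keeps
it.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: no indel or codon-level
evolution (real "hidden" tandem duplicates with large indels are
harder than the simulated ones, which is exactly why the 40% preset
exists), no segmental duplications or synteny, no correlated GO
assignment between functionally related neighbours short of the
planted clusters, no GO DAG structure in the background vocabulary
(ancestor propagation is exercised on hand-built ontologies in unit
tests), and no annotation error. Recovery rates on synthetic genomes
are an upper bound on real-genome behaviour.

`shuffle_go_labels()` permutes complete GO-BP sets across the
GO-BP-carrying genes: term frequencies and the universe are conserved,
positional signal is destroyed. On ten such null genomes of 3,000
genes the scan at the reference condition produces at most a couple of
calls in total — consistent with the number of (window, term) tests
times the 1e-6 threshold — which is the package's false-positive
calibration.

# Validation problem sizes

The shipped validation uses: 3,000-gene genomes (5 × 600, GO-BP
universe ≈ 1,860) with 15 planted clusters for recovery (≥ 13/15
required at the default seed); a 500-gene two-chromosome fixture with
one 5-gene planted cluster and one 5-copy tandem array at 95% pairwise
identity for stringency discrimination; 600-gene fixtures for
threshold nesting and determinism; ten 3,000-gene label-shuffled
genomes for the null control. The discrimination fixture plants a
5-gene cluster deliberately: in a universe of only ~300 GO-BP genes, a
4-gene cluster misaligned with the discrete sub-window tiling is
covered only by a 12-gene sub-window whose P (~2e-6) misses the 1e-6
threshold — correct scanner behaviour, but it would make the fixture
probe boundary sensitivity rather than tandem discrimination. A 5-gene
cluster is detectable at every offset relative to the tiling.

# Reporting conventions

Per-cluster bundles reproduce the classic six-file layout
(`SUMMARY_OVER`, `DATA_GENES_WITH_BP`, `DATA_ALLGENES`,
`REMOVED_BLAST` with literal `NONE` when nothing was collapsed, and
the two BLAST-tabular hit dumps), plus a pairwise percent-identity
matrix of member proteins in place of a rendered multiple-alignment
figure. "Genes in cluster" counts every catalog gene whose span
intersects the call span, tandem duplicates included. Per-cluster
means are *truncated* to two decimals (17.567 → 17.56), which is the
convention the published per-cluster means follow; the truncation
rounds at the sixth decimal first so exact decimal quotients are not
pushed under the boundary by binary representation error. Call spans
are also emitted as BED6 (0-based half-open), and genome snapshots are
out of scope.

# Known limitations

* One call per master window: nested or adjacent clusters inside one
  window are not disambiguated, and a cluster straddling a
  master-window boundary can be split or (if both halves fall under
  three genes) lost. The sub-window fine-tuning mitigates but does not
  remove this.
* Raw P thresholds are screening scores; no FDR is attached to a call
  inventory.
* The aligner scores one best local alignment per pair; families with
  domain-level mosaicism may evade the coverage ratios.
* Annotation quality bounds everything: terms absent from the input
  annotation cannot support calls, and inconsistent annotation across
  genomes degrades cross-species GO-set comparisons.
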