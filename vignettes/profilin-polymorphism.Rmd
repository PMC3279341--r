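---
title: "Profiling sequence polymorphism in pollen profilin families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling sequence polymorphism in pollen profilin families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profvar)
```

## The problem

Pollen profilins are small (~14 kDa, 130–134 aa) actin-binding proteins and
major cross-reactive allergens (Ole e 2, Bet v 2, Cor a 2, Phl p 12,
Zea m 12). Within a species — and especially across the wide cultivated
germplasm of olive — their coding sequences accumulate point substitutions
and short in-frame deletions that change physicochemical behaviour,
post-translational modification sites and, plausibly, allergenic epitopes.
`profvar` packages the complete analysis chain used to characterise this
polymorphism: per-column variability statistics on a multiple alignment,
identity/divergence summaries at the cultivar, species and family level,
ProtParam-style physicochemical profiling, PROSITE-motif scanning,
neighbor-joining phylogeny with bootstrap, and formal between-species
comparison of the variability distributions.

All analyses run on two S4 containers: a `SampleTable` (sequences joined to
accession/family/species/cultivar/clone metadata) and a `SeqAlignment`
(gapped character matrix with an *anchored* coordinate system). Positions
are numbered 1-based from the anchor column — for coding alignments the A
of the start codon of the selected profilin ORF — so that every reported
position matches the conventional numbering of profilin residues. Columns
left of the anchor get non-positive indices and are excluded from position
reports.

## Variability statistics

Two per-column statistics are computed by `columnProfiles()`:

* **Shannon entropy** (bits): $H = -\sum_s p_s \log_2 p_s$ over the
  unambiguous, non-gap symbols of the column. Used on nucleotide columns.
* **Wu–Kabat variability index**: $viv = k / f_{\max}$ where $k$ is the
  number of distinct residues and $f_{\max}$ the *relative* frequency of
  the most common one. A conserved column has $viv = 1$ at any depth; a
  column with $k$ equally frequent residues peaks at $k^2$. Used on
  amino-acid columns. A position is called polymorphic when $viv$ is
  *strictly* greater than the threshold (default 3).

Gaps and ambiguity codes (N for nucleotides, X and friends for proteins)
are excluded from $k$, $f_{\max}$ and the entropy: they carry no
information about residue variability, and this is the standard Wu–Kabat
convention. Columns that are more than half gaps are kept but flagged
`low_confidence`; columns with no effective symbols get `NA` statistics.

Protein columns additionally receive the Clustal consensus symbol: `*`
(identical), `:` (all residues within one strong group — STA, NEQK, NHQK,
NDEQ, QHRK, MILV, MILF, HY, FYW), `.` (one weak group — CSA, ATV, SAG,
STNK, STPA, SGND, SNDEQK, NDEQHK, NEQHRK, FVLIM, HFY), `•` otherwise; any
gap forces `•`. Note that some intuitively "dissimilar" pairs (D/K) do
share a weak group and are therefore marked semi-conservative — this
follows the group lists, which are the classical Clustal ones.

`kimReport()` specialises the comparison to the kinase-interaction motif
(KIM) window, anchored positions 78–98 (`IQGEAGAVIRGKKGSGGITIK`), and
catalogues every substitution per row; rows whose window is interrupted by
a deletion are flagged rather than failed.

## Identity and divergence

`pairwiseIdentity()` counts matching columns over comparable columns.
Columns gapped in *both* rows are never comparable. For a gap facing a
residue the package defaults to counting a mismatch (the behaviour of the
classic BioEdit identity matrix); `gaps = "exclude"` drops those columns
instead — both are offered because published identity matrices rarely
state the option used. Ambiguity codes count as mismatches unless the two
symbols are identical. `groupSummary()` reports, per group or group pair,
the min/max identity and the variability percentage $100 -
\min(\text{identity})$, with singleton groups flagged. Percentages are
written with one decimal, the conventional reporting precision.

## Physicochemical calculators

`physchemProfile()` reimplements the ProtParam battery:

* molecular weight: Expasy average residue masses plus one water
  (18.01524 Da);
* isoelectric point: bisection of the Henderson–Hasselbalch net charge on
  [0, 14] to $|Q| < 10^{-4}$, Bjellqvist pKa set (N-terminal pKa depends
  on the first residue, C-terminal on the last; K 10.0, R 12.0, H 5.98,
  D 4.05, E 4.45, C 9.0, Y 10.0). $Q$ is monotone decreasing in pH so the
  root is unique;
* extinction at 280 nm: Gill–von Hippel, $5500\,n_W + 1490\,n_Y$, the
  oxidized value adds 125 per cystine pair ($\lfloor n_C/2 \rfloor$);
* GRAVY: mean Kyte–Doolittle hydropathy;
* aliphatic index: Ikai, $X_{Ala} + 2.9 X_{Val} + 3.9 (X_{Ile} +
  X_{Leu})$ in mole percent;
* instability index: Guruprasad, $(10/L) \sum_i DIWV(r_i, r_{i+1})$, with
  the published 400-entry dipeptide table shipped as
  `extdata/diwv_guruprasad.tsv`; values below 40 flag a stable protein.

Average (not monoisotopic) masses are used throughout, matching the tool
the field reports. When comparing averaged values against published
tables, the package's tests allow half a percent: the exact averaged
sequence subset (with or without previously deposited reference entries)
is ambiguous in such tables, so agreement tighter than that cannot be
demanded.

## Motif scanning

`parsePrositePattern()` implements the PROSITE pattern syntax — residues,
`x`, `[sets]`, `{negated sets}`, repetitions `(n)`/`(n,m)`, `<`/`>`
terminal anchors — and `scanProsite()` matches at *every* start position,
so overlapping hits are reported (ScanProsite behaviour; a
`non_overlapping` switch exists). Variable-length elements expand
shortest-first. The packaged panel (`extdata/motif_panel.tsv`) carries the
classical patterns for N-glycosylation (PS00001), PKC and CK2
phosphorylation (PS00005/6), tyrosine-kinase phosphorylation (PS00007),
N-myristoylation (PS00008), amidation (PS00009) and the microbody
C-terminal targeting signal (PS00342). The pattern strings are taken from
the public PROSITE release; analyses that name only motif classes leave
the exact patterns open, so the panel file is versioned data, not code.
`phosphoInventory()` counts S/T/Y residues predicted by the
phospho-pattern classes, deduplicated per residue, and also reports raw
S/T/Y tallies because published phosphosite counts can follow either
reading.

## Phylogeny

Distances are uncorrected p-distances, $d = 1 - \text{identity}/100$,
consistent with the identity matrices; no evolutionary correction is
applied because the divergence summaries use none either. `njTree()` runs
classical Saitou–Nei neighbor joining (via `ape`); negative branch
lengths, an artefact of non-additive distances, are clamped to zero with
the total deficit recorded. `bootstrapTree()` resamples columns with
replacement and reports, per internal edge, the percentage of replicates
containing the same bipartition; the whole procedure is seeded.
`writeNewick()` serialises deterministically: branch lengths at six
decimals, supports as node labels, children ordered by their smallest
descendant tip label.

One caveat is documented rather than hidden: p-distances on an alignment
are integer mismatch counts over the width, so resampled matrices tie
often, and NJ resolves tied joins by the lowest index pair. Bootstrap
supports are therefore stable — but not bit-identical — under permutation
of the input rows.

## Between-species statistics

The observation unit is a *per-position variability value*: the Wu–Kabat
index for amino-acid alignments and entropy for nucleotide alignments,
one sample per species. This is the natural reading of comparing
"distributions of variability" between species, and it is stated
explicitly here because sample sizes per group (the number of alignment
positions) drive all the tests. `compareGroups()` runs:

* the one-way ANOVA F test (`anovaF()`),
* Levene's variance-homogeneity test (`leveneW()`, ANOVA on absolute
  deviations from the group mean; `center = "median"` gives the
  Brown–Forsythe variant),
* per-group Shapiro–Wilk normality tests (delegated to
  `stats::shapiro.test`),
* Games–Howell post hoc pairwise comparisons: $t = |\bar x_i - \bar
  x_j|/\sqrt{s_i^2/n_i + s_j^2/n_j}$, Welch–Satterthwaite degrees of
  freedom, p-value from the studentized range with $q = t\sqrt 2$ and
  $k$ = number of groups. Variances are never pooled. With equal
  variances and group sizes the procedure converges to Tukey's HSD,
  which the test suite verifies.

Degenerate inputs follow explicit conventions: identical groups give
$F = 0, p = 1$; a pair of zero-variance groups is flagged with its
degrees of freedom floored at 1. No multiple-testing correction is
applied beyond the studentized-range control built into Games–Howell.

## The synthetic generator

`simulateFamily()` produces profilin-like CDS families with a complete
ground truth so every downstream stage is testable without any download.
Its defaults emulate the structure of the pollen profilin study the
package targets:

* five species over three families, one of them an olive stand-in with 24
  cultivars of 1–7 clones each (~95 sequences), the others with 4–10
  clones, ~125 sequences in all;
* a packaged 405 nt reference CDS. Its 134 aa product is **synthetic** —
  designed, not downloaded — but carries the hallmarks the analyses look
  for: the KIM domain at 78–98, cysteines at 13/106/118, two tryptophans
  and six tyrosines (a realistic 280 nm extinction), N-myristoylation
  motifs at 30/33/67, the amidation motif RGKK at 87–90 and PKC/CK2/Tyr
  kinase phosphosite candidates (S41, T96, T126, Y125);
* species-level divergence applied on a star topology (one internal
  branch per species, default 0.11 substitutions/site) before
  cultivar-level (0.003) and clone-level (0.004) noise;
* hotspot codons — default ten positions in the 5′ half — with an
  elevated clone-level rate (0.25/site), reproducing the observation that
  the variable positions concentrate in the N-terminal half;
* at most one in-frame deletion per sequence, lengths 3/9/12 nt with 9 nt
  most likely (probabilities 0.10/0.22/0.08), placed on codon boundaries
  within a 5′-half window, so deletions remove 1/3/4 whole residues;
* substitutions draw the target base uniformly from the three
  alternatives; codons are re-sampled if a substitution would create an
  internal stop, and the start and stop codons never mutate (the clones
  are functional mRNAs);
* everything is driven by one integer seed, which is part of the public
  contract: identical seeds give byte-identical output, and
  `writeSimulation()` records the seed in the emitted configuration.

Because the per-site rates of the real families are not published, the
defaults are calibrated only to reproduce the qualitative structure: a
5′-half variability excess, tens of polymorphic positions in the
many-cultivar species versus single digits elsewhere, inter-species
identities in the 70–85% band, and roughly 40% of sequences carrying one
deletion. What the generator does **not** emulate: codon-usage bias,
selection, recombination, alignment error (the emitted truth alignment
bypasses any aligner), and the very deep intra-species divergence of real
olive germplasm, where some cultivar alleles are as distant from each
other as species are. Passing the parameter-recovery tests therefore
shows the statistics are computed correctly and sensitively, not that
real data will be as clean.

Under the uniform-target model, two species branches of divergence $d$
give an expected inter-species mismatch of $2d - \tfrac43 d^2$ per
mutable site; the recovery tests compare realized mean identity against
this closed form rather than against the naive $2d$.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: the default ~125-sequence
family for end-to-end runs; 20 seeded 30-clone families for hotspot
recovery; five 8-sequence families for divergence recovery; 500 seeded
20-sequence families for the Games–Howell null calibration; bootstrap
depths of 5–100 replicates in tests (1000 remains the analysis default).
These sizes were chosen so the whole battery runs in a few minutes on one
core while keeping every estimate's Monte-Carlo error well inside the
asserted tolerances.

Other numerical conventions: pI bisection stops at $|Q| < 10^{-4}$ (about
$10^{-4}$ pH units for proteins of this size); identity percentages are
reported to one decimal; Newick branch lengths to six decimals; the viv
threshold comparison is strict (`>`); metadata joins are case-sensitive
on the accession; `'-'` is the only accepted gap character and `'.'` is
rejected outright to avoid silently misreading Clustal dialect variants.

## Limitations

* Alignment construction is out of scope: the pipeline consumes a
  provided alignment (or the simulator's truth alignment); codon-aware
  alignment quality is the user's responsibility.
* The accession-level numbers of the originating study can only be
  recomputed after supplying the deposited GenBank sequences (see the
  acceptance test `test-acceptance.R` for the expected file layout);
  the package cannot redistribute them.
* Profile-matrix PROSITE entries and trained phosphosite predictors are
  not implemented; the motif engine is pattern-syntax only.
* Trees are distance-based NJ only — no likelihood or Bayesian
  inference — matching the analysis the package reproduces.

## A minimal session

```{r example, eval = FALSE}
sim  <- simulateFamily(simConfig(seed = 1))
aln  <- truthAlignment(sim)
res  <- runPipeline(pipelineConfig(samples = sim$samples, aln = aln,
                                   bootstrap_reps = 100, seed = 1,
                                   out_dir = "profvar_run"))
str(res$summary)
```
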