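---
title: "Detecting two coexisting phasiRNA phasing frames: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting two coexisting phasiRNA phasing frames: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duophase)
```

## The biological problem

Phased small interfering RNAs (phasiRNAs) are 21-nt products released at
fixed 21-nt intervals from a transcript after a trigger miRNA directs
ARGONAUTE-mediated cleavage. The 3′ cleavage fragment is copied into
double-stranded RNA by RDR6 and diced processively by DCL4 from the cut
end, so the 5′ ends of the products fall into a single 21-nt *register*
("phasing frame") anchored at the first nucleotide of the 3′ fragment.

Most phasiRNA analyses assume one frame per locus. Some loci, however,
carry **two** miRNA target sites only a few nucleotides apart — too close
for even one 21-nt product to fit between the cuts — and each cleavage
site can anchor its own frame on *independent* transcript copies. A
locus with a 22-nt guide site and a 21-nt guide site separated by a
12-nt gap places the two cleavage anchors 33 nt apart, i.e. the two
registers differ by 33 mod 21 = **12 residues**. Conventional one-frame
scans can underestimate phasiRNA output from such loci; `duophase`
detects and quantifies both frames and validates their products'
cis-cleavage activity.

## The phasing score

For a candidate frame with anchor $c$, a sense-strand read with 5′ end
$s$ is in phase when $s \ge c$ and $s \equiv c \pmod{21}$, falling in
duplex cycle $d = (s - c)/21 + 1$. An antisense read joins the same
register when its leftmost coordinate plus 2 is congruent to $c$; the
+2 offset encodes the 2-nt 3′ overhangs that DCL4 leaves on each duplex.
Both strands count toward the statistic by default (a flag restricts it
to the sense strand).

Over every window of 8 consecutive cycles (sliding by one cycle), with
$n$ the number of the 8 cycle positions occupied by at least one read
and $k$ the total in-phase read count in the window, the phasing score
is

$$P = (n - 2)\,\ln(1 + k), \qquad P = 0 \text{ when } n \le 2 .$$

The frame's summary score is the maximum window $P$; a frame is called
when it exceeds the cutoff (default **5**, the conventional threshold
for this statistic, exposed as a parameter). The $n-2$ exponent makes
isolated one- or two-cycle pileups score zero regardless of abundance,
while the logarithm prevents a single abundant duplex from dominating.

The classical printed form of this statistic sums $k_i$ over $i = 1..10$
while simultaneously defining an eight-cycle window; the two are
mutually inconsistent. We resolve it in favour of the window definition:
$k$ is summed over the window's 8 cycle positions. The window size is a
parameter, so a 10-cycle variant is one argument away.

### De novo and anchored detection

`detect_frames()` either scores user-supplied anchors (e.g. slice sites
predicted from known guides) or scans all 21 residue classes de novo.
Two surviving registers on one locus constitute a two-frame call. Ties
are broken by higher $P$, then higher window $k$, then smaller residue.
Candidates are named `PFx_3'Dn(+/-)`: frame label, duplex cycle counted
from the anchor, strand.

## Target scanning and the slicer convention

Guides are aligned antiparallel to every transcript window of their own
length: guide nt $i$ (from the guide 5′ end) pairs transcript position
$\mathrm{start} + L - i$. Pairs are Watson–Crick, G:U wobble (guide T
against target G, or guide G against target T — "T-G" in DNA space), or
mismatch; G:U never counts as a mismatch. The miRNA scan allows 3
mismatches and 1 G:U by default; the phasiRNA scan allows 2 mismatches
with unlimited G:U. We read the "T-G" allowance as a wobble *pair*, not
an unpaired bulged base: it accompanies a mismatch budget in a
complementarity scan, where wobble is the standard tolerated pair;
indel bulges are out of scope.

ARGONAUTE cuts the target between the bases pairing guide nt 10 and 11,
so the predicted slice coordinate — the first nucleotide of the 3′
cleavage fragment, the expected degradome 5′ end, and the phasing
anchor — is $\mathrm{start} + L - 10$.

Each hit carries a transparent penalty score (mismatch 1.0, G:U 0.5,
both doubled in guide positions 2–13, the cleavage-critical region) and
a fixed per-pair pseudo-energy (G:C −3.0, A:T −2.0, G:U −1.0, mismatch
+0.5; a perfect 21-mer scores between −42 and −63). These are
deliberately simple, deterministic desk-scale stand-ins: the penalty
score is *not* a TargetFinder score (published "score ≥ 140" thresholds
are not comparable to any public TargetFinder semantics, which are
small-is-better), and the pseudo-energy is not a nearest-neighbour
thermodynamic model. Both thresholds are caller-chosen.

## Degradome validation and RACE tallies

`filter_upstream()` implements the rule of discarding degradome signal
that cannot derive from slicing at the predicted sites: counts strictly
upstream (smaller sense coordinate) of the 5′-most predicted slice
coordinate are zeroed; the boundary position itself is kept, since the
slice-site peak is the evidence of interest. The opposite reading of
"the 5′ end of the targeting sites" (filtering at each site's 5′
boundary) is available by passing those boundaries as the site list.

Quantification is RPKM = reads × 10⁹ / (region length × library size).
Group comparisons use the two-sided Wilcoxon rank-sum test: exact
enumeration when both groups have ≤ 10 observations and no ties,
otherwise the normal approximation with tie and continuity correction;
the path taken is reported. Box summaries report median, interpolated
quartiles, and whiskers at 1.5 × IQR beyond the box edges.

`degradome_peak_check()` is the per-site diagnostic: the count at the
slice coordinate divided by the mean over ±`flank` positions (site
excluded); an empty flank with positive site signal reports `Inf`.
RLM-RACE clones are tallied by `race_tally()`: each clone 5′ end is
assigned to the nearest predicted site within `tolerance` nt (default
0, i.e. exact; ties to the smaller coordinate), with unassigned clones
counted separately so clones are conserved.

## Gene-set reporting

`venn_overlap()` reports intersection percentages rounded to one
decimal, half away from zero. `fisher_exact()` returns the two-sided
Fisher p-value (hypergeometric: all tables at fixed margins with
probability ≤ the observed are summed, as implemented by R's
`fisher.test`) together with the sample odds ratio $ad/bc$; the 2×2
universe is always supplied explicitly by the caller rather than
guessed. `expression_matrix_summary()` z-scales rows with the sample
standard deviation (so a (1,2,3) row becomes (−1,0,1)), flags
zero-variance rows as all-zero, and orders rows by average-linkage
hierarchical clustering on Euclidean distance, emitting a
cluster-ready matrix rather than a rendered heat map.

## The synthetic-data generator

Every stage is testable against `sim_config()` ground truth. The
defaults are the study conditions of the two-frame system:

| parameter | default | meaning |
|---|---|---|
| `locus_length` | 1500 nt | gene-sized locus |
| `guide_sequences` | one 22-nt + one 21-nt guide | trigger pair (a 22-nt trigger with a 21-nt second site) |
| `inter_site_gap` | 12 nt | gap between the two target-site intervals |
| `site_start` | 100 | 0-based start of the first site |
| `n_duplexes_per_frame` | 10 | phased duplex positions per frame |
| `duplex_mean_count` | 10 | expected reads per duplex strand |
| `duplex_dispersion` | 5 | negative-binomial size; `Inf` = Poisson |
| `noise_fraction` | 0.2 | expected share of uniform noise reads |
| `degradome_peak_count` | 50 | expected degradome reads at each slice site |
| `degradome_background_rate` | 1 | expected background reads per position |
| `n_race_clones` / `race_site_probs` | 35, (2,9,23,1)/35 | four-site cis-cleavage scenario |

With these defaults the implanted anchors sit at 112 and 145 (33 nt
apart, frame offset 12). Abundances are negative binomial per duplex
strand because small-RNA counts are overdispersed; dispersion 5 gives a
variance about three times the mean at the default mean of 10, typical
of sRNA libraries, and `Inf` recovers Poisson. Noise reads are uniform
in position and strand with lengths uniform on 18–29 nt, matching the
observed length range of non-phased products from such loci; reads that
would overhang the locus are redrawn, not truncated, preserving the
length distribution. The expected noise share is `noise_fraction`
(realised counts are Poisson around it).

The generator does **not** emulate transcription or RDR6 kinetics,
sequencing error, adapter artefacts, genomic multi-mapping across
paralogues (e.g. homoeologous subgenome copies), or FASTQ qualities.
Passing the closed-loop tests therefore shows that the detector
recovers the geometry it models — registers, offsets, overhangs, peaks
— not that it is robust to every artefact of real libraries.

The "12-nt" inter-site distance is deliberately exposed as the gap
between site *intervals*; since printed inter-site distances are
ambiguous between interval gaps and cleavage-to-cleavage distances, the
truth record stores both conventions (`gap_between_sites` and
`anchor_separations`).

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; writers add 1-based
  display columns, raw columns carry the `_0b` suffix.
* **Exact mapping** reports every occurrence on both strands with no
  mismatches (`-a -v 0` semantics); N never matches on either side.
  Multi-mapped reads keep their full count at every placement — how
  multi-mappers were weighted in published density plots is usually
  unstated, so the all-alignment convention is adopted and flagged.
  CPM uses a caller-supplied whole-library total when given (tissue
  library normalisation), else the collapsed sum.
* **Phasing counts** default to 20–22-nt reads: phasing is defined on
  the 21-nt interval while the loci also emit 18–29-nt products. The
  range is configurable.
* **Degenerate inputs**: loci shorter than one window (168 nt) are a
  detection error; empty alignment sets give empty profiles and empty
  candidate lists, not errors; an empty degradome site list leaves the
  profile unfiltered with a warning.
* **Determinism**: every generator draws under a seed supplied in the
  config and restores the caller's RNG state afterwards.
* **Problem sizes** used by the shipped tests — 1.5-kb loci, hundreds
  of reads, 100-replicate stochastic checks — were chosen as the
  smallest sizes at which the stochastic properties (≥ 95/100 recovery,
  ≤ 5/100 false calls) are stable; they run in about a minute.

## Known limitations

* One interval (21 nt) per locus; 24-nt registers are not modelled.
* The scan is per-candidate-locus, not genome-wide PHAS discovery.
* Target scanning has no secondary-structure or accessibility terms,
  and no indel bulges.
* RACE tallies are descriptive only: cloning efficiency differs between
  fragments, so clone counts are not quantitative cleavage rates.
* Degradome analysis is per-locus; no transcriptome-wide category
  classification (CleaveLand-style) is attempted.
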