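---
title: "Mapping polyprotein processing from orthogonal protein-chemistry evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polyprotein processing from orthogonal protein-chemistry evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymap)
```

## The problem

Picorna-like insect viruses (iflaviruses among them) translate their entire
positive-sense RNA genome into a single polyprotein, which a virus-encoded
3C-like protease cuts into mature proteins: a leader protein (L), the capsid
proteins named VP1–VP4 by descending molecular weight, and the nonstructural
proteins. None of the cuts is directly observable from the genome. What a
laboratory actually measures is

* **Edman N-terminal reads**: ~10-residue N-terminal sequences of gel spots,
  which pin a mature protein's first residue — and therefore the cleavage
  immediately before it — exactly;
* **peptide mass fingerprints (PMF)**: MALDI-TOF neutral masses of tryptic
  peptides from each spot, matched against the in silico digest of the
  translated polyprotein within a ppm tolerance. Matched peptides merge into
  *coverage blocks* that delimit where a spot's protein lies;
* **cleavage-site motifs**: 3C-like proteases cleave after glutamine or
  glutamic acid, with a preferred context (P1′ methionine, P or A at −4,
  acidic residues at +2/+3 in the viruses modelled here);
* **apparent spot weights and isoelectric points** from 2-D gels.

`polymap` re-implements the inference that turns these four evidence streams
into a single cleavage map with calculated molecular weights and pI values,
plus the supporting genome arithmetic (ORF finding, UTR lengths, base
composition) and the distance-based phylogenetics (p-distance, neighbor
joining, bootstrap) used to place a strain among its relatives.

## The evidence model and the assembly procedure

`assemble_map()` integrates an `evidence_set` in a fixed hierarchy that
mirrors how such maps are argued in the literature:

1. **Anchors are facts.** Every unambiguous Edman anchor at residue
   $s$ fixes a boundary "cleavage after $s-1$" (position conventions below).
2. **Coverage constrains.** A candidate cleavage position is discarded when
   fingerprint coverage *straddles* it — but only when the straddle is
   supported by at least three distinct matched peptide intervals backed by
   three distinct peaks within one spot. This support rule is deliberate:
   at a 75 ppm tolerance against a ~3000-residue digest, single matched
   peptides are frequently chance coincidences; nested missed-cleavage
   variants share an endpoint, and single-residue-shifted peptides (sequence
   permutations) share the very peak that matched them, so neither pair
   constitutes two independent observations. Genuine coverage of an uncleaved
   position, by contrast, produces the zero-missed peptide plus both of its
   missed-cleavage extensions — three intervals, three peaks — whenever
   detection is good.
3. **Weights select.** Within each gap between fixed boundaries, at most one
   additional boundary is chosen. If the segment starting the gap carries an
   observed spot weight, the candidate minimizing
   $|MW_{calc} - MW_{obs}|$ wins, with "no additional cut" included as a
   competing hypothesis (preferred on ties); this is how a ~26 kDa spot
   decides between a nearby and a distant downstream site. Without a weight
   observation, only candidates showing the *fully conserved* canonical
   context (maximum attainable motif score) qualify, the 5′-most
   highest-scoring one winning; divergent M/D-type sites are never chosen on
   motif evidence alone, because in the source system that cleavage type was
   only credible once an N-terminal read demonstrated it.
4. **Nothing is invented.** A gap with no qualifying candidate stays merged
   and the map carries a note. Contradictions — an anchored boundary inside
   supported coverage — raise an error naming the position rather than
   silently resolving.

Internal processing of a pro-protein (two spots sharing one N-terminal read
but differing in apparent weight) is reported by
`infer_internal_processing()` as a *hypothesis* — the cut position whose
N-terminal fragment weight best matches the smaller spot — and never becomes
a map boundary, since the evidence cannot pin it to a residue.

### Position conventions

Cleavage positions are indexed by the P1 residue: "cleavage after residue
$i$" produces segments ending at $i$ and starting at $i+1$. A Q/M site at
position 171 therefore ends one protein at 171 and starts the next at the
methionine 172 — which also explains why an N-terminal read *mapped to*
residue 172 implies cleavage after 171. All coordinates are 1-based and
inclusive, and motif offsets count −4…−1 on the N-terminal side of the
scissile bond and +1…+4 on the C-terminal side.

### Capsid naming

Mature segments are named by the traditional weight-ranking convention:
the N-terminal pre-anchor segment is L, and the remaining capsid segments
take VP names by descending calculated weight. For the canonical five-segment
layout, the ranking maps largest→VP1, second→VP3, third→VP2, smallest→VP4,
which reproduces the standard iflavirus gene order L–VP2–VP4–VP1–VP3.

## Mass, pI and digestion arithmetic

Peptide masses are neutral and monoisotopic (MALDI-TOF PMF convention);
whole-protein weights are average-isotope and reported in kDa, rounded to
one decimal in reports. Residue masses, water (18.010565 / 18.015286 Da),
the proton (1.007276 Da, used to convert MH⁺ m/z lists), and the
modification deltas — carbamidomethyl-C +57.021464 Da fixed, oxidation-M
+15.994915 Da variable, at most 2 per peptide by default — ship as
plain-text tables in `extdata`, so an alternative constants set is a data
change. Digestion follows the classical trypsin rule (cleave after K/R, not
before P; the exception can be disabled), with 1 missed cleavage by default,
and a semitryptic mode generating peptides that end at the protein
C-terminus — the signature of a mature-protein C-terminus that trypsin could
not have produced.

Matching uses relative error, $|m_{obs} - m_{theo}|/m_{theo} \cdot 10^6 \le$
`tolerance_ppm` (default 75 ppm), inside a 500–5000 Da detection window
(a typical MALDI reflectron acquisition range). The window matters for more
than realism: 1–4 residue peptides are mass-degenerate across a long
polyprotein and would otherwise "cover" everything. Identification
confidence uses a decoy estimate: the peak list is re-searched against the
reversed sequence and seeded residue shuffles (20 decoys by default), and
FDR = mean decoy matched-peak count / target matched-peak count, accepted at
≤ 0.05.

The isoelectric point solves net charge = 0 under a Henderson–Hasselbalch
model (N/C termini plus C, D, E, H, K, R, Y side chains) by bisection on
pH ∈ [0, 14] to 1e−4; the charge function is strictly decreasing, so the
root is unique. The default pKa set is a Bjellqvist-style table, with an
EMBOSS-style alternative shipped alongside; the tables live in data because
published pI values are only reproducible with the matching constants.

## Phylogenetics

`p_distance()` computes the proportion of differing sites under pairwise or
complete gap deletion, optionally Jukes–Cantor corrected. Neighbor joining is
implemented from scratch (Saitou–Nei Q-criterion, standard branch-length
formulas); negative branch lengths are clamped to zero with the deficit
recorded, and Q ties break deterministically on the lexicographically
smallest pair of cluster representatives, so identical inputs give identical
trees. Bootstrap resamples alignment columns with replacement under a seeded
generator, rebuilds the tree per replicate, and reports per-bipartition
support as internal node labels; supports depend only on the column
resampling, so they are invariant to taxon input order. Trees are
ape-compatible `phylo` objects, written as Newick; rooting on an outgroup is
a display operation.

## What the synthetic generator emulates — and what it does not

`generate_truth()` plants a ground-truth map: segment lengths drawn from
20–450 residues (five segments by default, followed by a 1934-residue
nonstructural tail), boundary windows written to satisfy the full motif
context, uniform background residues elsewhere (unintended motif cores
within four residues of a planted site are resampled away), and a genome
assembled as a 918-nt 5′-UTR + synonymous-codon back-translation + stop +
204-nt 3′-UTR (+ optional poly(A)). The explicit
`segment_lengths = c(171, 237, 24, 424, 257)` preset with the defaults
reproduces an iflavirus-sized layout: a 3047-residue polyprotein in a
10,266-nt genome.

`simulate_edman()` corrupts N-terminal prefixes per cycle (substitution and
undetermined-X rates, X capped at 40%); by default segments 2 and 4 are
observed, matching a study in which only those two N-termini yielded reads.
`simulate_pmf()` detects each tryptic peptide with probability 0.6, perturbs
masses with 20 ppm Gaussian relative error, and adds 10% uniform contaminant
peaks — chosen so that the 75 ppm matching tolerance is a 3.75-sigma gate
(expected true-peak loss < 0.1%). Segments with no peptide in the detection
window yield no peak list, as small VP4-like peptides do in real virion
preparations.

What the generator does **not** model: peptide detectability physics
(intensity, ionization bias), Edman preview/lag chemistry, isotope
envelopes, gel-mobility anomalies (apparent weights are taken as the true
segment weights in tests), post-translational heterogeneity, and indels in
the alignment simulator. Passing the recovery tests therefore demonstrates
that the *inference logic* is sound under calibrated noise, not that every
real gel will yield a complete map — on real data, unresolved gaps and
flagged notes are the expected honest outcome.

## Numerical and degenerate-input choices

* Sites within 5 residues of a terminus are reported with truncated windows
  and flagged.
* Ambiguous Edman anchors (several equally good hits) are excluded from
  assembly and noted.
* An all-identical distance matrix still yields a deterministic NJ tree via
  the label tie-break; a pair with zero comparable alignment sites is an
  error naming the pair.
* A decoy search with zero target matches reports FDR 1.0 with a warning
  status rather than dividing by zero.
* The `AUTO` region-end policy picks the highest-scoring candidate site past
  all anchors within a window of 30–45% of the polyprotein length (structural
  regions of these viruses occupy roughly the N-terminal third). This is a
  package policy for data lacking a C-terminal semitryptic peptide, and it is
  configurable.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run: 200 noiseless + 200
default-noise synthetic maps for boundary recovery (the package's own
standard is exact recovery in the noiseless regime and ≥ 90% under noise;
both measured at 100% here); 100 random PMF instances against a brute-force
enumeration oracle; 100 random 5–8 taxon additive matrices for NJ (exact
topology and branch lengths); 100 seeded 10 kb Jukes–Cantor simulations on
6-taxon trees; 50 random peptides comparing pI bisection to a 1e−5 grid; and
1000 simulated peptide masses for the 75 ppm/20 ppm gate. These sizes were
chosen to make the Monte-Carlo rates stable at the percent level while
keeping a full run in the low minutes on one core.

## Worked example

```{r example}
truth <- generate_truth(seed = 7)
poly  <- truth$polyprotein

reads   <- simulate_edman(truth, seed = 7)
anchors <- locate_reads(reads, poly)
peaks   <- simulate_pmf(truth, seed = 7)
results <- lapply(peaks, function(p) match_peaks(p, list(poly))[[1]])
sites   <- rbind(scan_cleavage_sites(poly), scan_divergent_md(poly))

segmw <- vapply(truth$segments$index, function(k)
  protein_average_mw(substr(poly$sequence, truth$segments$start[k],
                            truth$segments$end[k])), numeric(1))
obs <- data.frame(spot_id = c("E2", "E4"), apparent_mw_kda = segmw[c(2, 4)])

map <- assemble_map(poly, evidence_set(
  anchors = anchors, pmf_results = results, candidate_sites = sites,
  spot_observations = obs, region_end = truth$region_end))
map
identical(as.integer(map$boundaries), as.integer(head(truth$boundaries, -1)))
```

## Known limitations

* The mapper assumes at most one undetermined boundary per gap between
  anchors; two adjacent segments both lacking any direct evidence collapse
  into one flagged segment rather than being guessed.
* Scoring is matched-peak count with coverage as a tiebreak — a deliberate
  simplification of probabilistic PMF scoring (MOWSE), adequate because the
  mapper needs presence/absence evidence, not database ranking.
* The additive motif weights are a formalization of a qualitative consensus;
  they are editable data (`read_motif_model()`), not learned from alignments.
* MS/MS fragment evidence, spectrum preprocessing and external database
  search are out of scope.
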