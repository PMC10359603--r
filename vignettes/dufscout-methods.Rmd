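---
title: "Methods: reconstructing and characterizing DUF6499-DUF2285 activator systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and characterizing DUF6499-DUF2285 activator systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dufscout)
```

This vignette documents the models, conventions and numerical choices
behind each `dufscout` stage, what the synthetic-data generator does and
does not emulate, and the design decisions that were genuinely open.

## 1. The +1 PRF gene model and its reconstruction

Activator genes of the FseA family are encoded either as a single ORF
or as two ORFs that overlap in the +1 reading frame and are joined
during translation by a +1 programmed ribosomal frameshift at a
slippery sequence (mRNA `UGGGGG`; we work on the coding strand, so the
configurable motif default is `TGGGGG`).

**Detection** (`detect_prf()`) considers every ORF pair on one strand
with `frame_down == (frame_up + 1) mod 3` and an overlap of at least
1 nt (no gap-tolerant pairing: the defining gene pairs overlap). The
upstream ORF must contain the slippery motif within `window_nt`
(default 45 nt, a configurable guess — how far upstream of the stop a
functional site may sit is not established) of its stop codon, with at
most `max_mismatch` mismatches (default 0).

Two conventions needed fixing where the underlying biology leaves
freedom:

* **Codon alignment.** Only motif occurrences whose final base falls on
  a codon boundary of the upstream frame are considered. Otherwise
  "translate through the final nucleotide of the motif" would end in
  mid-codon. The canonical site is codon-aligned (`TGG|GGG`, encoding
  Trp-Gly), and this convention places the conserved W-G(-L) across the
  junction.
* **Edit point.** `fuse_prf()` translates the upstream frame through
  the last motif base, skips exactly one nucleotide, and resumes in the
  downstream frame (which is the +1 frame by construction) through the
  downstream stop. `junction_residue` is the last residue encoded
  before the edit. An internal stop after the edit signals a false call
  and raises a classed error with the offending coordinate rather than
  emitting a truncated protein.
* **Tie-breaks.** Within an ORF pair, the best motif is the one with
  fewest mismatches, then the most 3' position (the ribosome slips near
  the ORF boundary); across pairs, calls are sorted by (mismatches,
  ascending position).

ORFs are found in all six frames (`find_orfs()`), reported from their
first ATG through the stop codon; an `include_startless` option reports
stop-to-stop segments without an ATG, which models loci whose start
codons are misannotated. Coordinates are 0-based half-open internally;
GFF3 output is 1-based inclusive; protein residues are 1-based.

## 2. Homologue curation

DUF6499 is recognized by the `AWEFLRRN` motif in the protein's
N-terminal region (in the reference activator it occupies residues
31–38, on the alpha-2 helix). `find_motif()` performs an ungapped
Hamming search within residues 1–`region_end` (default 60). The
"AWEFLRRN-like" tolerance is not quantified in the literature; we use
Hamming distance ≤ 2 with no indels, exposed as a flag — tight enough
to stay distinctive, loose enough to admit homologue drift.

`curate()` applies four filters. Length > 400 aa and ambiguous-residue
(`X`) removal are mechanical. Lone-DUF6499 duplicates are supplied as
an id list (they are locus-level duplicates of kept activator records).
The "distinct motif after alignment" stage is a stand-in: instead of
requiring an external aligner, each sequence's best-motif window is
anchored and compared to the majority-letter consensus of those
windows, with the same mismatch tolerance; an externally produced MSA
can be supplied to reproduce an alignment-based check exactly. The
consensus is computed once from the stage input, which makes all four
filter predicates independent of application order — permuting the
stage order provably changes only the attribution of removals, never
the kept set, and this is property-tested.

The curation report reconciles exactly: input = kept + sum of
removals; it also reports the fraction of kept activator-like records
with `PRF_FUSED` provenance, mirroring the headline statistic of a
curated homologue database (about 61% of activator loci requiring the
+1 PRF at genomic scale). Database-scale counts themselves depend on a
dated homology search and are out of scope; the synthetic sets instead
plant a known fraction and require the report to echo it.

## 3. Inverted-repeat (operator box) scanning and profiling

The operator is an inverted repeat: two hexamer half-sites separated by
a 15- or 16-bp spacer (total span 2·6 + 16 = 28 bp for the canonical
spacer; hexamer centres 22 bp apart, about two helical turns — the
geometry a dimer binding two half-sites on the same DNA face implies).
`scan_ir()` tests every (position, spacer) pair and counts mismatches
between the downstream half-site and the reverse complement of the
upstream one. A hit is reported once per (position, spacer), not once
per strand: an inverted repeat is its own reverse complement as a pair,
and double counting would follow.

`redundancy_filter()` is greedy in input order with ungapped identity
(windows are fixed-length upstream extracts in a common coordinate
frame, so gapped alignment is not warranted); the default threshold is
0.90.

`split_profile()` avoids the smearing that mixed 15/16-bp spacers cause
in a naive fixed-coordinate stack by stacking two independently
anchored blocks: the upstream flank plus half-site 1, right-aligned on
the end of half-site 1; and half-site 2 plus the downstream flank,
left-aligned on its start. The spacer columns themselves are excluded
(they have no common coordinate system). Default flank widths take
everything available in every window, which keeps the profile of
reverse-complemented windows the exact mirror image of the original —
a property test. Information content is 2 − H bits per column with
plug-in Shannon entropy (log2), no small-sample correction, and no
pseudocounts by default (intended for hundreds of sequences; a
pseudocount flag exists for small n).

## 4. Charge accounting

`net_charge()` is purely compositional: Arg +1, Lys +1, Asp −1, Glu −1,
His 0 by default, optional +1/−1 for free N-/C-termini. Histidine is
neutral because the canonical DUF2285 tally (15 Arg − 6 Asp − 1 Glu −
1 C-terminus = +7) counts none; the rule is configurable. There is no
pKa/pH model — the statement being reproduced is compositional, and a
Poisson-Boltzmann surface calculation is explicitly out of scope.
`window_profile()` applies terminal charges only in windows containing
a true terminus.

## 5. EMSA binding-curve fitting

The response is the bound fraction `bound / (bound + unbound)` per lane
(a flag switches to the raw bound/unbound ratio): the quantity fitted
is ratio-based, and the fraction bounds the response in [0, 1], which
is numerically stabler. Before fitting, `exclude_constant_unbound()`
implements the band-exclusion rule: a separately quantitated
co-purified band whose coefficient of variation across lanes is below
0.10 is deemed constant (it "remains equally unbound at each protein
concentration"), and its mean is subtracted from every lane's unbound
signal; subtraction is clipped at zero with a warning count.

`fit_hill()` minimizes squared error of Y = B·X^h/(K^h + X^h) over
log-parameters (positivity for free), with BFGS from 8 deterministic
multi-starts — K_D initialized at the concentration nearest half-max
response and jittered over [0.25×, 4×], h at 1, B at the maximum
response — followed by a Nelder-Mead polish. Hill fits are multi-modal
enough that single starts stall on plateaus. The convergence flag is
honest: if every start fails, parameters are `NA`. Replicates are
unweighted by default (no variance model is imposed; a weighting flag
is a natural extension). Scale equivariance (X → cX gives K_D → cK_D,
h unchanged) and permutation invariance are property-tested; at zero
noise the generator's parameters are recovered to ≤ 1e-6 relative
error, and across 100 noisy replicates the median recovered K_D stays
within 20% of truth.

## 6. Structure ensembles

`read_ensemble()` is a deliberately minimal fixed-column PDB reader
(ATOM/MODEL/ENDMDL; altloc blank or A; hydrogens skipped; author
residue numbering preserved) — no R PDB parser is available among the
package's allowed dependencies, and deposited NMR ensembles need
nothing more. Malformed coordinates fail with the line number.

`ensemble_rmsd()` reports **both** common conventions, because
published ensemble-precision numbers rarely state one: `to_mean`
iteratively superposes all models onto the evolving mean (convergence
when the mean moves < 1e-6 Å) and averages model-to-mean RMSDs;
`pairwise` averages RMSD over all superposed model pairs. `pairwise ≥
to_mean` always (tested). "Backbone heavy atoms" defaults to
{N, CA, C, O}; some tools exclude O, so the atom set is configurable.
`kabsch()` is the closed-form SVD solution with the determinant
correction enforcing a proper rotation; it is checked against a
brute-force quaternion search, which can only approach its optimum
from above.

## 7. The synthetic world

The generators state one fixed world and the tests live in it:

* `gen_loci()` plants activator-like genes as a 160-codon upstream ORF
  (ATG start, TAA stop, `AWEFLRRN` at residues 31–38) and a 110-codon
  downstream ORF overlapping by 8 nt in the +1 frame, joined at a
  codon-aligned `TGGGGG` two codons before the upstream stop;
  antiactivator-like genes are single motif-free ORFs; decoys are
  random ORFs. Background is i.i.d. nucleotide sequence at GC 0.6
  (rhizobial-like), the simplest null that still exercises the
  scanners. The +1 geometry forces `overlap_nt ≡ 2 (mod 3)` (and ≥ 8)
  when the downstream ATG is codon-aligned; other values raise an
  explicit construction error rather than silently shifting anything.
  An in-frame stop is placed immediately 5' of each planted ATG so the
  planted start is the first ATG of its segment and truth equals what
  the ORF finder reports. An operator-like IR (our chosen consensus
  hexamer `TGACGT`; the reference operator's hexamer sequence is not
  available in the source material) is planted in the 5' flank of each
  activator locus. A `misannotate` flag drops the upstream-ORF
  annotation, emulating public-database records; reconstruction must
  not depend on it. Mutations are i.i.d. substitutions applied after
  construction; truth records keep the clean sequence.
* `gen_upstreams()` samples half-site 1 from a position probability
  matrix whose two central columns are nearly invariant (the conserved
  core of the operator hexamers) and half-site 2 from its reverse
  complement, with spacer 15 or 16 drawn from stated probabilities.
  Windows are rejection-sampled so the background contains no spurious
  perfect IR — one planted box per window, by construction.
* `gen_emsa()` draws bound intensity from the Hill model with
  multiplicative Gaussian lane noise (which keeps the half-saturation
  identity exact at zero noise, matching densitometry behaviour),
  complements it into the unbound band, and adds a constant co-purified
  band reported both inside `unbound` and as its own column. The
  default K_D of 30 nM is the affinity scale of the
  activator-operator interaction being emulated.
* `gen_ensemble()` is a **synthetic** stand-in for a deposited NMR
  ensemble: a smooth 83-residue backbone with per-coordinate Gaussian
  scatter `0.36/sqrt(3)` Å over the ordered core (expected
  model-to-mean RMSD ≈ 0.36 Å, the precision scale of a
  well-determined solution structure) and 8× that at the disordered
  termini (residues 1–5 and 75–83). It verifies the reader and both
  RMSD conventions; it does not verify any deposited coordinates, and
  the acceptance check against PDB 7UQT requires network access.

What the generators do **not** emulate: phylogenetically realistic
sequence evolution, indels, codon-usage bias, overlapping gene
constraints beyond the planted pair, gel-image artefacts beyond
multiplicative lane noise, and real protein stereochemistry. A green
test therefore establishes algorithmic correctness against planted
truth and brute-force oracles — not performance on real genomes.

## 8. Known limitations

* Frameshifting efficiency ("low-frequency") is not modelled; −1 PRF
  is unsupported.
* `reconstruct_proteins()` emits one protein per locus (best PRF call,
  else longest ORF); on loci whose planted gene is short, a spurious
  longer ORF (often reverse-strand) can be the one reported. Planted
  fusions are unaffected.
* The redundancy filter is quadratic in kept windows — appropriate for
  the hundreds-of-sequences regime it targets.
* The PDB reader handles single-character chain ids and integer
  residue numbers only (no insertion codes, no mmCIF).
* Absolute logo coordinates relative to a start codon are supported
  only through the windows supplied; reproducing a specific published
  extract requires the original window definitions.
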