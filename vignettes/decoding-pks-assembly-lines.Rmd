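---
title: "Decoding a modular PKS assembly line: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a modular PKS assembly line: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksdecode)
```

## The problem

Modular type I polyketide synthases (PKSs) are assembly lines: each
*extension module* — minimally a ketosynthase (KS), an acyltransferase (AT)
and an acyl-carrier protein (ACP), optionally with ketoreductase (KR),
dehydratase (DH) and enoylreductase (ER) domains — performs one cycle of
chain extension and sets the oxidation state and stereochemistry of one
two-carbon unit of the product. In the canonical ("colinear") case the
product can be read off the gene cluster: one module, one cycle. The
clusters this package targets break colinearity in an informative way: the
ossamycin cluster encodes fourteen extension modules but the 24-membered
macrolactone requires fifteen extension cycles, so one module must act
twice on consecutive cycles (*programmed iteration*, or stuttering).

`pksdecode` turns that style of reasoning into a tested pipeline: classify
the cluster genes into roles, locate catalytic domains and read their
active-site fingerprints, group domains into modules, reconcile the module
line against a target backbone (inferring multienzyme order and any
iteration), build the predicted product with its tailoring, and do the
elemental bookkeeping down to a monoisotopic mass that can be compared with
an LC-MS observation.

## Fingerprint grammar

The classification rules are deliberately literal transcriptions of the
published motif grammar for cis-AT PKSs:

* **AT extender choice.** Malonyl-specific ATs read `GHSQ` at the
  active-site serine and `HAFH` at the second-histidine position;
  (2S)-methylmalonyl-specific ATs read `GHS(I/L/V)` and `YASH`. When the
  YASH-position motif is instead a small-residue variant (`SPGH`, `VASH`,
  ...), the AT is called `unusual-alkylmalonyl` — the signature of exotic
  branched extender units. When the two motifs each match a rule but
  disagree (e.g. `GHSQ` with `YASH`) the call is `unknown` with a
  `discordant` flag rather than a guess: motif predictions can be wrong
  (the ossamycin AT2 is the packaged example — its motifs say
  methylmalonyl, the product says malonyl), and discordance must surface.
* **KR activity and stereotype.** Activity requires the catalytic Tyr;
  missing Lys/Ser downgrade confidence, not the call. An Asp as third
  residue of an LDD-like motif gives B-type (B1, d-configured
  β-hydroxyl); a Trp gives A-type (l-configured), subdivided into A2 when
  a His replaces the usual Gln, else A1. Product labels follow the
  published A1 (2S,3R) / B1 (2R,3R) / A2 (2R,3R) mapping. Note the
  published labels make A2 coincide with B1 although A-type KRs are
  l-specific; the package keeps the as-published default, exposes the A2
  alpha label as an argument (`classify_kr(..., a2_alpha=)`), and flags
  the coincidence in the call's `note`.
* **DH activity.** Active iff both the His of the conserved
  `Hxxx(G/D)xxxxPG` box and the Asp of `Dxxx(Q/H)` are present; an
  inactive call names the substitution (`His→Arg`, `His→Tyr` — the two
  dead DHs of the ossamycin line).
* **ER stereo outcome.** A Tyr-containing active-site motif predicts the
  (2S) α-substituent configuration; its absence 2R.
* **KSQ loading.** A KS-like domain with Gln in the catalytic-Cys slot is
  a decarboxylating loading domain; a methylmalonyl-specific loading AT
  then means a propionate starter.

## Domain location: anchored profiles

The motif literature gives diagnostic residues but no domain boundaries, so
domains are located by **anchored profile scanning**: each domain type has a
packaged template block containing a conserved literal anchor (wildcarded
at classification slots), and fingerprints are extracted at fixed offsets
from the anchor. The templates are compact desk-scale proxies (30–120
residues; real domains run to several hundred) that carry the genuine
diagnostic residues in conserved context. All offsets live in the profile
object (`pks_profiles()`), not in code, and externally located domain
intervals can be injected by building a call table directly — the packaged
ossamycin call table is exactly such a table. Classification reads only the
fingerprint slots, never flanking sequence; this is property-tested by
mutating non-anchor positions.

A hit whose template span is truncated by a protein end is flagged
`partial` and excluded from classification rather than guessed at.

## Ordering and iteration as a scored search

Modules are grouped by the grammar `KS (AT) (DH) (ER) (KR) ACP`; a module's
*reduction level* is the maximal reduction its ACTIVE domains support
(inactive DH caps at hydroxyl, missing/inactive KR at ketone). The loading
didomain pins its protein to the front of the line, the thioesterase pins
its protein to the end, and the remaining multienzymes are permuted
exhaustively (the search is bounded at 8 unpinned proteins; the packaged
problem has 6, i.e. 720 orders).

Each candidate order is scored against the target backbone by the best
cycle-to-module assignment. With `k` more cycles than modules, every
composition of `k` stutters over the modules is enumerated; an assignment
is admissible only if each stuttering module covers **consecutive,
chemically identical** target cycles (same extender, reduction and stereo
labels — stuttering repeats a chemistry, it cannot vary one). Mismatch
weights are 1 per cycle for a differing extender class, 1 for a differing
reduction level, 0.5 for a stereo-only difference, and 0.5 for an
uninformative (unknown/discordant) AT. Ties are broken toward the earliest
stuttered cycle, both among assignments and among equally scored protein
orders, and all ties are reported rather than hidden. On the packaged
fixture this matters: the monomodular OssA5 and the bimodular OssA7 carry
chemically identical malonyl/fully-reducing modules, so swapping them (with
the stutter moving from cycles 9/10 to 12/13) scores equally; the
earliest-stutter tie-break selects the annotated order and the alternative
is retained in the `ties` attribute. Everything here is checked against
brute-force permutation/placement oracles in the test suite.

The scored search is deliberately simple and reproducible; resolving ties
by KS-sequence similarity to known systems would be a natural extension but
is not implemented.

## Product construction and mass bookkeeping

Carbon numbering follows polyketide convention: C-1 is the carboxyl carbon
delivered by the last cycle, so cycle *c* of *n* contributes backbone
carbons 2(n−c)+1 and 2(n−c)+2, and the β-carbon processed by cycle *c*'s
reductive domains is 2(n−c)+3 (for cycle 1, the starter carbonyl). Backbone
carbons therefore total `starter + 2n` (33 for ossamycin: propionate + 15
cycles), an invariant that is property-tested. Side-chain carbons — the
branched C4 unit of the unusual alkylmalonyl extender — are numbered beyond
the backbone (C-34..C-37 here); tailoring sites keep their customary
display labels (the side-chain hydroxylation is labelled "C-35" after the
feeding-study numbering of the related 22-membered compound, which is
offset by the two iteration-inserted carbons).

Macrolactonization at carbon *s* requires a hydroxyl there and gives a ring
of *s*+1 atoms (C-1..C-s plus the ester oxygen): C-23 → 24-membered.
Rebuilding the same line without the iteration moves the same hydroxyl to
C-21 and gives the 22-membered homologue — the structural relationship
between the 22- and 24-membered members of this compound family.

Tailoring events carry explicit elemental deltas: hydroxylation +O;
glycosylation + (free sugar − H2O), permitted only after a hydroxyl exists
at the site (the C-8 hydroxyl/ossamine dependency); spiroacetal closure of
a ketone onto two hydroxyls is −H2O under the `ketal` convention used by
the packaged fixture (an `annotation` convention with no formula change is
available, but the ketal convention is what makes the final model formula
match the compound — it is validated against the observed des-hydroxy ion);
a hemiacetal is formula-neutral connectivity. The ossamine formula is
derived from the sugar-pathway module, not hard-coded. Enoyl (E/Z) geometry
is left unassigned: the motif grammar provides no DH geometry rule.

Monoisotopic masses use a packaged six-element table (C,H,N,O,S,P) at
1e-6 Da precision; [M+H]+ adds a proton (1.007276 Da), and the test suite
checks the computation against an independently typed mass table to 1e-4.
The SMILES-style export is generated from the model (rings, substituents,
tailoring, the O-linked sugar) and must round-trip: a small built-in SMILES
reader recounts the formula of the emitted string and the tests require
exact agreement. Stereo marks in the export are annotations mapped from the
model's labels by a fixed convention, not a CIP perception.

## The target backbone fixture

The 15-cycle target is reconstructed from textual constraints: the malonyl
insertion at C-27/C-28 despite AT2's methylmalonyl motifs; KR-less modules
4 and 7 leaving ketones at C-25 (the spiroacetal centre) and C-19 (the
side-chain hemiacetal partner); dead DH1/DH7; malonyl + full reduction on
the iterated cycles 9/10; the methylmalonyl + ER (2S) module 11; the
lactone hydroxyl at C-23 and the spiroacetal ring hydroxyls at C-21/C-29.
Cells not pinned by those constraints (methyl placement, the extra
hydroxyls at C-3/C-5, the Δ16,17 enoyl) were chosen once, as the
configuration that completes a chemically sensible backbone whose final
tailored glycoside (C50H89NO13) reproduces the observed des-hydroxy ion
mass, and are marked `confidence: low` in the YAML. They are fixture data,
not inferences the pipeline makes.

## The synthetic-data generator

`emit_line()` builds multienzymes from the same profiles the scanner uses:
planted fingerprint slots, fixed anchors, background-frequency linkers
(Robinson–Robinson-style composition, not uniform, to avoid both anchor
collisions and unrealistic composition), and a configurable mutation rate
(default 0.05 per residue) outside anchors and slots. A collision check
re-draws any protein in which a spurious anchor match appears, so the
ground truth table is exact by construction. One integer seed drives
everything; per-protein sub-seeds are derived by a fixed integer mixing
function, and identical seeds give byte-identical output.

What the generator emulates: domain grammar and order, fingerprint
variation, linker variability, point substitutions away from functional
sites. What it does not emulate: real domain lengths, phylogenetic
covariation, indels, anchor-motif divergence, or trans-AT architectures. A
passing round-trip therefore demonstrates that the decoding logic is
internally consistent and robust to neutral sequence variation — not that
the anchors would locate domains in arbitrary natural sequences, where
profile-HMM scanning would be the appropriate front end (external domain
intervals can be supplied as call tables for exactly that use).

Default study conditions in the tests: the ossamycin-mimic configuration
(14 modules over 8 proteins, loading KSQ, TE, the dead DHs, the unusual
AT7) and 200 randomized configurations of 2–4 proteins with 1–2 modules
each, plus boundary instances at 8 proteins/16 cycles; brute-force oracle
cross-checks run on every fourth case and on all boundary cases. These
sizes keep the whole suite to a couple of minutes on one CPU while
exercising every rule.

## Degenerate inputs and edge behaviour

* Empty or domain-free (decoy) sequences give empty hit tables, not errors.
* Orphan domains (an ACP with no upstream KS) produce a structured warning
  and a `malformed` module, excluded from ordering but reported.
* Fewer cycles than modules ("surplus modules") is an error — module
  skipping is a different phenomenon and out of scope.
* No loading module and no TE leaves the orientation ambiguous: the
  ordering fails with the candidate set in the message.
* Lactonization at a non-hydroxyl carbon is an error naming the carbon's
  actual state; rings smaller than six atoms are flagged implausible.
* The two printed variants of the cluster accession (MH763624 /
  MH7636247) are both recorded in the cluster fixture header without
  choosing.

## Known limitations

Substrate calls are fingerprint lookups, not structure- or ML-based
prediction, and inherit the grammar's blind spots (AT2-style shifted
preference is detected as a discrepancy, not predicted). Trans-AT systems,
module skipping, non-TE release chemistry, and enzyme kinetics are out of
scope. Stereo labels are propagated as printed labels; the package does
not re-derive configurations from first principles.
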