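# pksdecode

Rule-based decoding of modular type I polyketide synthase (PKS)
biosynthetic gene clusters, built around the ossamycin cluster of
*Streptomyces hygroscopicus* var. *ossamyceticus* as a worked, fully
packaged example.

Modular PKSs are assembly lines: each extension module (KS + AT + ACP,
optionally KR/DH/ER) adds one two-carbon unit to the growing polyketide and
sets its oxidation state and stereochemistry. Reading a cluster therefore
means (i) classifying the cluster's genes into biosynthetic roles, (ii)
locating the catalytic domains in the giant multienzymes and reading their
active-site fingerprint residues (AT substrate motifs GHSQ/HAFH vs
GHS(I/L/V)/YASH vs small-residue variants such as SPGH; KR catalytic triad,
LDD/Trp stereotype residues and the A2 His-for-Gln; the DH His/Asp boxes;
the ER Tyr motif; the KSQ loading glutamine), (iii) grouping domains into
modules and reconciling the module line with the target backbone, and (iv)
building the predicted product. The interesting clusters are the
non-colinear ones: ossamycin's PKS houses only **14 extension modules** but
needs **15 extension cycles**, so one module must stutter — `pksdecode`
finds such programmed iteration by scored exhaustive search, checked
against brute-force oracles.

The package is intended for natural-product bioinformaticians who want the
motif-to-product reasoning to be explicit, reproducible and testable,
rather than re-derived by hand in a figure. All rules (anchor profiles,
fingerprint offsets, role keywords, mismatch weights, tailoring deltas) are
data, not code.

## Worked example

The packaged fixtures are the ossamycin cluster annotation (27 ORFs), the
per-domain fingerprint table for the eight multienzymes OssA1–OssA8, the
15-cycle target backbone, and the tailoring events:

```r
library(pksdecode)
rep <- run_pipeline(ossamycin_cluster(), ossamycin_domain_calls(),
                    ossamycin_target(), ossamycin_tailoring())
print(rep)
#> == pksdecode pipeline report ==
#> Cluster: 27 genes; 8 modular PKS; 4 P450; 6 sugar-pathway genes
#> Assembly line: 14 extension modules in order OssA1 -> OssA2 -> OssA3 -> OssA4 -> OssA5 -> OssA6 -> OssA7 -> OssA8
#> Cycles: 15; iterated: OssA5_m1 at cycles 9,10
#> Product: ring size 24 | formula C50H89NO13 | [M+H]+ 912.6407
#> Discrepancies:
#>          cycle module_id    field  module_value target_value weight
#> extender     2  OssA1_m2 extender methylmalonyl      malonyl      1
```

Reading the report: the 27 genes classify into 8 giant PKS multienzymes,
4 cytochrome P450s (the post-PKS hydroxylases), the six
ossamine-biosynthesis genes plus a glycosyltransferase, and accessory
genes. Grouping the domain calls gives a loading didomain (KSQ +
methylmalonyl-AT, i.e. a propionate starter), 14 extension modules and a
thioesterase; scoring all multienzyme orders against the 15-cycle target
pins OssA1 first (loading) and OssA8 last (TE) and maps the monomodular
OssA5 onto **both** cycles 9 and 10 — two malonyl units, fully reduced,
added by one module. Cyclizing the 33-carbon chain at the C-23 hydroxyl
gives the 24-membered macrolactone; with the iteration suppressed
(`drop_cycle()`) the same line gives the 22-membered homologue. The one
discrepancy is real biology, not a bug: AT2's motifs read methylmalonyl
although malonyl is incorporated at C-27/C-28.

The deoxyaminosugar module reconstructs the dTDP-l-ossamine pathway from
the role table (OssS → OssT → OssQ → OssZ1 → OssJ → OssI, plus two enzymes
recruited from outside the cluster) and derives the glycone formula by
elemental bookkeeping:

```r
residue_formula(ossamine_pathway())
#> C8H17NO2 (monoisotopic 159.1259 Da)
```

That formula feeds the glycosylation delta in the tailoring step, and the
final model's des-hydroxy ion can be compared directly with an LC-MS
observation (see the test suite).

A seeded generator emits synthetic multienzymes with planted ground truth
(`ossamycin_mimic_config()`, `emit_line()`), so the whole chain of
inference — scan, classify, group, order, iterate — is validated by exact
round-trips and brute-force oracles. A thin CLI wrapper lives at
`exec/pksdecode` (`run`, `roles`, `sugar`, `simulate`).

## Package layout

* `R/cluster_io.R` — cluster tables (TSV/GenBank/GFF3), role rules.
* `R/profiles.R`, `R/domain_scan.R`, `R/domain_calls.R` — anchored
  profiles, domain location, fingerprint classification.
* `R/assembly.R` — module grammar, multienzyme ordering, iteration
  detection.
* `R/product.R`, `R/structure.R` — chain assembly, macrolactonization,
  tailoring, formula/mass, SMILES export and parse-back.
* `R/sugar.R` — dTDP-deoxyaminosugar rule engine.
* `R/simulate.R` — seeded synthetic-line generator.
* `R/pipeline.R` — `run_pipeline()` and the JSON report.
* `vignettes/decoding-pks-assembly-lines.Rmd` — methods, parameters and
  design decisions.
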