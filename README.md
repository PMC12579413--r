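# polledtrio

Trio-based structural forensics of the bovine *POLLED* locus.

## The problem

Polledness (hornlessness) in cattle is a dominant trait controlled by
structural variants on chromosome 1 between ~2.42 and 2.73 Mb. The two
common alleles are the Celtic variant `P_C` — a 10-bp deletion at
g.2,429,326–2,429,335 replaced by a 212-bp duplicated insertion — and the
Friesian variant `P_F` — an 80,128-bp tandem duplication
(g.2,629,116–2,709,243) whose second copy differs from the first only by a
T→A substitution at its first base and a 2-bp TG deletion (`P_F2D`) at
bases 38–39.

Rarely, a horned `p/p` calf is born to a homozygous- or compound-polled
parent. Two recombination mechanisms explain this:

* **Non-allelic homologous recombination** between the two copies of the
  Friesian duplication deletes exactly one unit; because the copies differ
  at only two positions near the copy start, any crossover at unit offset
  > 39 reconstructs the wild-type sequence byte-exactly.
* **Allelic recombination** in a dam carrying `P_C` and `P_F` in trans: a
  single crossover between the two variant positions (which lie ~200 kbp
  apart; at 1.085 Mb/cM that is ~2 recombinant oocytes per 1,000) yields a
  gamete with neither variant — or, equally likely, the cis fusion
  carrying both.

`polledtrio` implements the complete analysis used to adjudicate such
trios: sequence-level models of the alleles and of both recombination
products, an ONT-like long-read simulator with exact truth provenance and
analytically projected split alignments, a split-read breakpoint scanner
(clusters need two or more consistent reads), a windowed read-depth scanner
with a Poisson start-count significance test, trio Mendelian checks and
crossover localization as haplotype switches against phased parents, a
read-count analog of the diagnostic polled genotyping test (the 2:1 vs 1:1
`P_F2D` peak-height zygosity rule), and a rule engine that classifies the
combined evidence into the structural hypotheses H1 / H2 / H3-or-H4 or the
Fleckvieh-trio outcomes parental / crossover-wild-type / cis-fusion.

## Worked example

```r
library(polledtrio)
v <- run_polled_pipeline("FV_ahr_wildtype", seed = 31)
print(v)
```

```
POLLED locus trio analysis — scenario FV_ahr_wildtype (seed 31)
  offspring reads: 1040 (~20.0x)
  parentage: pass (0/78 markers in conflict)
  split clusters (support >= 2): 0
  CNV calls (>= 1 kbp, significant): 0
  P_C diagnostic: p/p (conf 1.00) [21 ref / 0 var]
  P_F2D diagnostic: p/p (conf 0.99) [12 ref / 0 var]
  dam haplotype switch at ~2687110 (interval 2679215-2695005)
verdict:
<hypothesis_call> FV_AHR_WILDTYPE (predicted phenotype: horned)
  - neither polled variant transmitted
  - exactly one maternal haplotype switch in 2679215-2695005 (point estimate 2687110): allelic crossover skipping both variants
(designed truth: FV_AHR_WILDTYPE)
```

Reading the report: the simulated offspring carries a maternal gamete that
recombined at 2,694,883 bp. The diagnostic sites show only
reference-supporting reads (neither the 212-bp Celtic insertion nor the
2-bp Friesian deletion was transmitted), no structural-variant evidence
survives the two-read / significance filters, and the dam's transmitted
alleles switch from her `P_F`-carrying haplotype to her `P_C`-carrying
haplotype inside an informative-marker interval that contains the designed
breakpoint — the allelic-crossover wild-type gamete.

Other scenario labels accepted by `run_polled_pipeline()` /
`design_trio()`: `HF_expected`, `HF_H1`, `HF_H2`, `HF_H3H4`,
`FV_parental`, `FV_cis_fusion`.

Lower-level entry points: `polled_allele()`, `build_haplotype()`,
`nahr_product()`, `ahr_product()`, `simulate_reads()`,
`project_alignments()`, `scan_splitreads()`, `compute_depth()` /
`call_regions()`, `simulate_snp_panel()`, `mendelian_consistency()`,
`assign_parental_origin()`, `detect_switches()`, `genotype_pc()` /
`genotype_pf()`, `expected_offspring()`, `recombinant_gamete_rate()`,
`classify_hf()` / `classify_fv()`.

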