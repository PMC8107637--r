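---
title: "Reconstructing a founder haplotype from small-cohort genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a founder haplotype from small-cohort genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

## The problem

In recessive disease-gene discovery, a recurrent allele observed in several
unrelated families raises one central question: did the allele arise once,
on a common ancestral chromosome, or repeatedly? The two hypotheses are
distinguished by the chromosomal background: descendants of a single
founder share, identical by descent, a segment of the chromosome
surrounding the allele, eroded at each generation by recombination, whereas
recurrent mutations sit on unrelated backgrounds. `founderhap` implements
the genotype-level workflow for answering that question in small clinical
cohorts, as applied to ferredoxin-reductase (*FDXR*) associated optic
atrophy and retinal dystrophy, where a recurrent missense allele
(c.1115C>A, p.(Pro372His)) was observed in five of eight families:

1. assemble rare **biallelic candidate genotypes** per affected individual
   (homozygous, compound heterozygous in trans, or heterozygous opposite a
   multigene deletion, i.e. hemizygous);
2. select **informative SNVs** in a window around the gene;
3. **phase** each carrier's local haplotype by pedigree segregation, or
   anchor it by hemizygosity over a deletion;
4. intersect carrier haplotypes into a maximal **shared core**, localizing
   per-family **recombination breakpoints**;
5. **interrogate** unphaseable singletons for presence of every
   core-defining allele;
6. tabulate the cohort's genotype and phenotype summary statistics.

Because WGS data of such cohorts are not redistributable, the package pairs
the pipeline with a synthetic-cohort generator whose outputs carry a
machine-readable truth ledger, so every step is validated by parameter
recovery.

## Candidate genotype assembly

The rare-variant filter retains protein-altering variants (default classes:
missense, stop-gain, frameshift, splice donor/acceptor, in-frame indel,
start-lost, stop-lost) with population MAF below `maf_rare` (default
0.001; a laxer `maf_rare_exome = 0.003` is provided for exome-sequenced
probands), excluding genes on a virtual panel of already-known disease
genes. Two deliberate conventions:

* **Unknown frequency passes the filter.** An allele absent from the
  population resource is treated as MAF 0; several cohort alleles have
  frequency exactly 0 in gnomAD.
* The class set for "protein altering" is a package decision: whether
  near-splice synonymous changes count is not specified by the clinical
  workflow this reproduces, and the set is configurable.

`assemble_biallelic()` then combines an individual's heterozygous
candidates with segregation:

* both parents each carrying exactly one allele of a pair confirms
  **trans**;
* a **single available parent** carrying exactly one allele and
  definitively lacking the other also confirms trans — the missing allele
  must have come from the unavailable parent (or arisen de novo, which at
  these frequencies is the less parsimonious reading used in practice);
* a **sibling** carrying exactly one allele of the pair separates the two:
  variants a gene-length apart co-segregate unless they lie on opposite
  chromosomes;
* a parent carrying **both** alleles excludes the pair (`cis_excluded`);
* no informative relatives leaves `compound_het_unresolved`, reported with
  an explicit evidence grade rather than dropped — a genotype can be a
  strong candidate even when segregation is impossible.

A heterozygous or apparently homozygous SNV lying **inside a deletion
carried by the same sample** is reclassified hemizygous regardless of its
diploid GT string, because genotype callers emit diploid calls over
copy-loss regions; a warning is raised when read depths contradict copy
loss (substantial reference-allele depth). Deletions are consumed as calls
(sample, interval, copy number) — discovery from reads is out of scope.

## Informative sites and phasing

The window is `window_bp = 150000` bp (150 kb) each side of the gene
interval — an "approximately 150 kb" convention fixed to an exact value for
reproducibility. Within it, SNVs with known population MAF below
`maf_informative = 0.1` are informative: sharing a sufficiently rare allele
across carrier chromosomes is evidence of common descent rather than
chance. The index variant is always included regardless of frequency.

Segregation phasing is deterministic Mendelian logic, not a statistical
model: at each site the two orderings of the child's alleles are checked
against what each parent can transmit; exactly one consistent ordering
resolves the site, two leave it unresolved, zero flag a `mendel_conflict`
(excluded from the haplotype — with error-free input this cannot happen,
so conflicts surface genotyping errors). Homozygous sites are always
resolved, whatever the pedigree. There is no read-backed or LD-based
phasing, no reference panel: phase evidence is genotype + pedigree +
deletion only, mirroring a workflow whose read inspection was manual.

Two structural rules matter for counting:

* **Hemizygous anchoring**: for a carrier of the index variant in trans
  with a deletion spanning the gene, every call at a site inside the
  deletion interval reflects the single retained chromosome and is assigned
  to the index haplotype directly. Anchoring is refused if the index
  variant is not inside the deletion. Anchoring resolves a superset of what
  homozygosity alone would resolve there.
* **One haplotype per transmitting lineage**: affected siblings who
  inherit the index allele from the same parent share one chromosome and
  are merged into a single haplotype (founder statistics count chromosomes,
  not people). If siblings' index origins differed, both would be kept.

Unresolved sites are carried as wildcards, not dropped: a site no haplotype
resolves cannot contradict sharing, but it is reported as unresolved
support rather than silently strengthening the core.

## The shared core and breakpoints

`shared_core()` finds the maximal contiguous run of informative sites
containing the index position at which all haplotypes agree (resolved
alleles all equal, or wildcard). Numerical conventions, each of which a
reader comparing outputs should know:

* Extension stops at the first site with any resolved discordance;
  the discordance tolerance defaults to 0 (strict), with a parameter for
  genotyping-error robustness that is off by default.
* The core is reported **boundary site to boundary site** — the outermost
  *concordant* sites of the run — not at midpoints between concordant and
  discordant sites, matching how such haplotypes are reported
  (rsID-to-rsID).
* `span_kb()` is the **difference of the two boundary point coordinates**,
  floored to whole kb: boundaries 74819055 and 74947323 give 128268 bp,
  reported as 128 kb. (The inclusive length of an interval, by contrast, is
  `end - start + 1`; both are exposed.)
* Per-family breakpoints beyond the core are attributed against the modal
  resolved allele of each column (the allele still carried by the families
  whose segment extends further): the first discordant site below the core
  is a **centromeric** recombination (lower coordinate), above it
  **telomeric**. Where resolved alleles tie, the recombinant family cannot
  be identified and no attribution is made at that site.

Singletons cannot be phased, so `interrogate_singleton()` checks **allele
presence, not phase**: the verdict is `consistent` only if the consensus
allele is present (het or hom) at every resolved core site, `indeterminate`
when nothing is testable. A consistent verdict is necessary, not
sufficient, for carrying the founder chromosome — with enough rare
core alleles the chance-sharing probability becomes negligible, which is
exactly what the non-carrier simulations quantify.

## What the generator emulates — and what it does not

`sim_config()` defaults describe the validation scenario shaped like the
study cohort: 8 families, 5 carrier families, gene interval
chr17:74862454–74873150 inside a ±150 kb window, index variant at
chr17:74865062 with population frequency 1.315e-5, 120 background SNVs with
frequencies uniform on [0.0005, 0.5] (roughly a quarter fall below the 0.1
informativeness threshold, giving ~25–30 informative sites over the ~310 kb
window, about one per 10 kb), and carrier roles trio / affected-sib-pair /
trio / hemizygous-deletion singleton / singleton. Two carrier families
truncate the founder segment on opposite sides (centromeric breakpoint at
74819000 in carrier family 1, telomeric at 74947400 in carrier family 3),
chosen to give a truth core of roughly the reported 128 kb scale; the
deletion family carries the index variant opposite a deletion spanning
chr17:74818633–74888183.

Deliberate modelling choices:

* **No linkage disequilibrium.** Background chromosomes are sampled
  site-independently from the configured frequencies. The analysis argument
  is rarity-based — chance co-occurrence of rare alleles — not LD-based, so
  the relevant null is independent sampling. Consequently, passing tests
  say nothing about confounding by population LD structure; on real data a
  shared common haplotype is a weaker signal than this null implies.
* **Founder ascertainment.** The founder chromosome carries the alternate
  allele at informative sites with probability `founder_alt_prob = 0.5`
  rather than at its population frequency: sites enter such an analysis
  because they distinguish the founder lineage, so the founder is enriched
  for minor alleles at the sites actually tabulated. At non-informative
  sites the founder is an ordinary population draw.
* **Detectable breakpoints.** With `force_detectable = TRUE` (default) the
  first informative site beyond each planted breakpoint is set up so that
  the recombinant chromosome resolves to the non-founder allele there and
  the sib-pair family resolves the founder allele. Reported recombinations
  are, by construction of the real analysis, identified at observed
  discordant SNVs; planting exactly that signal makes parameter recovery a
  deterministic property of the procedure rather than of the seed. With
  the flag off, breakpoint localization degrades gracefully to the first
  chance mismatch beyond the truncation.
* **Breakpoints are specified positions**, not draws from a genetic map
  (an optional uniform-random mode exists for the stochastic shrinkage
  property); tests need controllable truth.
* **Cohort shape**: one child per trio, a larger sibship only in the
  designated two-affected-sib family, one singleton, one deletion family —
  the generator mirrors the cohort rather than exploring pedigree space.
* Genotype error and missingness are applied as independent per-allele
  flips / per-genotype masks; there is no probabilistic phasing model, so
  errors surface as Mendelian conflicts (by design).
* A single integer seed drives one generator stream; identical seed and
  config give byte-identical files.

The truth ledger (`SimTruth`) records the founder allele vector over
informative sites, each family's transmitted segment, forced discordant
sites, the deletion, and a config echo — everything needed to score
recovery without re-deriving it from the outputs being tested.

## Worked example

```{r example}
cfg <- sim_config(seed = 42)
co <- simulate_cohort(cfg)
haps <- build_carrier_haplotypes(co$vcf, co$ped, co$freq, co$deletions,
                                 index_key = co$truth$index_key,
                                 gene = cfg$gene)
core <- shared_core(haps, cfg$index_pos)
core
interrogate_singleton(co$vcf$calls, "F5_CH", core)
```

```{r plot, fig.width = 7, fig.height = 3}
plot(core)
```

## Validation strategy and problem sizes

The test suite validates each operation against an independent brute-force
oracle rather than against itself: trio phasing against exhaustive
enumeration of Mendelian-consistent orderings (500 random error-free trios
of up to 10 sites), the shared core against an oracle that enumerates every
contiguous run containing the index and keeps the longest concordant one
(500 random haplotype sets, up to 20 sites and 8 haplotypes), summary
counts against plain set-based recounts, and the full pipeline against the
generator's truth ledger (exact founder-segment recovery at error rate 0;
100/100 simulated non-carriers rejected by singleton interrogation). These
sizes keep the whole suite under a minute while covering the combinatorial
space the procedures actually face (cohorts of this kind have tens of
informative sites and a handful of carrier chromosomes).

## Known limitations

* Phase evidence is pedigree + deletion only; a cohort of true singletons
  without deletions reduces to homozygous-site haplotypes and
  presence-based interrogation.
* The strict (tolerance 0) core is brittle to genotyping error at
  informative sites; errors shrink the core rather than biasing it outward,
  and the tolerance parameter trades this for robustness explicitly.
* Breakpoint attribution requires a modal allele; with two haplotypes a
  discordant site bounds the core but cannot name the recombinant family.
* No allele-age or founder-dating estimate is attempted from core length,
  and no genome-wide IBD scan: the scope is the local haplotype around a
  designated index variant.
* Coordinates are treated as an opaque, internally consistent 1-based
  system; no genome build is assumed and no liftover performed.
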