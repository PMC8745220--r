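---
title: "Methods: a combined genomic-transcriptomic variant prioritization funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a combined genomic-transcriptomic variant prioritization funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfunnel)
options(varfunnel.quiet = TRUE)
```

# The problem

Common-variant GWAS hits explain only part of the genetic architecture of
complex neurovascular disease. One complementary strategy combines three
orthogonal lines of evidence to prioritize candidate variants that single
approaches would miss:

1. **Tissue transcriptomics** — genes differentially expressed between
   case and control vascular-wall specimens (here: internal jugular vein
   wall, the main cerebral venous outflow path).
2. **A disease gene set** — genes mapped to GWAS-catalog SNPs for the
   disease at a sub-genome-wide threshold.
3. **Family co-segregation** — whole-exome variants transmitted with
   disease from affected parent to affected child in multiplex families.

Variants surviving all three filters, restricted to low-frequency
nonintronic sites, are then tested for allele-frequency differences
between an affected cohort and reference control populations. `varfunnel`
implements this funnel end to end, with strict readers for every input
format and a synthetic-data module that generates all inputs with planted,
parameterized signal, so every stage is testable without patient data.

# Stage 1: differential expression

Expression values are log2 intensities. For gene $g$ with case/control
means $\bar x_{1g}, \bar x_{0g}$, the reported **fold change** is the
absolute linear ratio $\mathrm{FC}_g = 2^{|\bar x_{1g}-\bar x_{0g}|} \ge 1$,
with direction "up" when cases are higher (ties break as "up" so output is
deterministic).

Per-gene testing uses the **moderated t-test**: the pooled sample variance
$s_g^2$ (residual df $d_g = n_1+n_0-2$) is shrunk toward an
empirical-Bayes prior $\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$, giving the
posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and

$$ t_g = \frac{\bar x_{1g}-\bar x_{0g}}
             {\sqrt{\tilde s_g^2 (1/n_1 + 1/n_0)}},
   \qquad t_g \sim t_{d_0+d_g} \text{ under } H_0 . $$

The hyperparameters $(d_0, s_0^2)$ are estimated by moment matching on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: the prior df solves
$\psi'(d_0/2) = \mathrm{var}(e_g) - \overline{\psi'(d_g/2)}$ by monotone
Newton inversion of the trigamma function, and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$; a non-positive
variance excess yields the degenerate prior $d_0=\infty$. With shrinkage
disabled the ordinary pooled t-test is recovered exactly (this identity is
a test oracle at tolerance 1e-12; the estimator is cross-checked against
limma's independent implementation in the test suite).

P-values are adjusted by **Benjamini–Hochberg** (a validated wrapper over
`stats::p.adjust`), and genes are selected by the rule
$\mathrm{FC} \ge 2$ **and** adjusted $p \le 0.05$, both boundaries
inclusive as printed in the source tables this reproduces. One numerical
convention departs from a strict $(0,1]$ domain for BH inputs: a
zero-variance gene with a mean shift gets the limit convention
$|t|=\infty, p=0$ (flagged `degenerate`), so the adjustment accepts
$p \in [0,1]$.

# Stage 2: the disease gene set

Catalog records are SNP–trait–p–gene tuples. SNPs are selected by exact,
case-insensitive trait match and association $p \le 5\times10^{-6}$
(inclusive); the gene set is the union of their mapped symbols. Symbol
matching everywhere is case-sensitive exact string match after trimming —
no alias resolution, which keeps set arithmetic auditable. Multi-gene
records are split on commas, semicolons, and the spaced `" - "` separator
used for intergenic annotations; a bare hyphen is deliberately *not* a
separator, since it would destroy legitimate symbols such as `HLA-DRB1`.

The candidate set for the funnel is the plain intersection of the catalog
set with the differentially expressed set.

# Stage 3: family co-segregation ("vertical transmission")

Genotypes are diploid alt-allele counts (0/1/2, or missing). The filter is
dominant carrier logic; under the defaults a variant **passes in a
family** when

* every affected member carries at least one alt allele,
* at least one affected parent–affected child pair both carry (the
  "vertical" requirement), and
* (optionally, off by default) no unaffected member carries.

A variant passes overall when at least `min_families_passing` (default 1)
families pass. Defaults reflect a deliberately permissive reading suited
to incomplete penetrance in outbred families: unaffected carriers are
tolerated, and any one family suffices. Missing genotypes are resolved
conservatively: a missing call in an *affected* member fails the variant
in that family (policy `fail_variant_in_family`; the alternative treats it
as non-carrier), while missing calls in unaffected members always count as
non-carrier. Every per-family verdict carries a reason code, and the full
report is emitted for every input variant. Verdict logic is validated
against exhaustive enumeration of all $4^4$ genotype assignments on a
four-member family under several rule settings.

# Stage 4: consequence annotation and the low-frequency filter

Transcript models carry strand, 1-based inclusive exon intervals, genomic
CDS bounds, and the spliced sequence in transcript orientation. A
single-nucleotide substitution is mapped into transcript space
(reverse-complemented on minus-strand genes) and classified:

* inside the CDS, the affected codon is translated before and after the
  edit — same amino acid = `synonymous`, new stop = `stop_gained`,
  otherwise `missense`;
* exonic positions upstream/downstream of the CDS are `utr5`/`utr3`, with
  `c.-N` counting backwards from the first CDS base;
* inside the gene span but in no exon = `intronic`; outside = `intergenic`.

Codon-change strings follow the compact published style (unchanged bases
lowercase, substituted base uppercase: `Ggt/Agt`), and protein notation
uses three-letter codes (`p.Gly482Ser`). Splice-region classes are not
modeled — the funnel's dichotomy is exonic vs intronic. A VCF ref allele
disagreeing with the transcript sequence is a hard error, not a silent
skip. The classifier is validated against a full-CDS translation oracle on
1000 random substitutions and by a strand-mirroring property.

The **low-frequency filter** retains variants whose *maximum* frequency
across the source populations is $\le 0.04$ (inclusive). Which
population's MAF defines "low-frequency" is genuinely open in the source
material; the default thresholds the control populations (an affected
cohort can be enriched for a risk allele precisely because of the
disease), and `maf_source = "affected"` is available. The nonintronic
restriction applies to the disease-GWAS arm together with this filter.

# Stage 5: case-control allele-frequency testing

For allele counts $x_1/n_1$ vs $x_2/n_2$ the pooled two-proportion z-test
uses $\hat p = (x_1+x_2)/(n_1+n_2)$ and

$$ z = \frac{x_1/n_1 - x_2/n_2}
            {\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}},
   \qquad p = 2\Phi(-|z|). $$

$z^2$ equals the Pearson chi-square without continuity correction — an
oracle identity tested to 1e-10. Degenerate tables ($\hat p \in \{0,1\}$)
return $z=0, p=1$ flagged. When a table supplies only frequencies, counts
are reconstructed as `round(freq * allele_number)` with a logged residual,
because the test needs sample sizes; frequency-only files without allele
numbers are rejected.

Multiplicity uses the Bonferroni threshold $\alpha/m$ with $m$ counted as
**distinct variants tested** (not variant × comparison pairs): a
25-variant family at $\alpha = 0.05$ gives the printed 0.002. Tiers mirror
the published three-color scheme: `significant` for $p < t$ (strict),
`borderline` for $p \in [t, 5t)$, `nominal` for $p \in [5t, 0.05)$, else
`ns`. The borderline band is a package definition (the source never
defines "borderline"); the multiplier 5 reproduces the published
borderline labels for p = 0.0093 and p = 0.0067 and is configurable.
Published p-values themselves are not reproduction targets: the control
allele numbers behind them are not public, so the test is validated
against oracles and calibration instead.

# The synthetic-data module

The generator is a first-class module that defines the study conditions:

* **Expression**: 20,000 genes, 10 cases vs 10 controls; gene variances
  from a scaled inverse-chi-square with $d_0 = 4$, $s_0^2 = 0.05$ (typical
  microarray values); baselines uniform on log2 (2, 14); 923 planted DE
  genes with absolute log2 shifts of 1.5–3, inflated for noisy genes to
  $1 + 4.5\,\mathrm{SE}(\Delta)$ so planted signal is detectable at the
  study's sample size. Because Benjamini–Hochberg controls FDR rather than
  FWER, a handful of heavy-tailed null genes will genuinely pass the
  selection rule at 20,000 genes; tests therefore assert perfect recall
  plus a bounded false-discovery count, not exact set equality. Funnel
  counts are unaffected: false DE genes carry no co-segregating variants.
* **Catalog**: 805 qualifying SNPs over 543 genes (plus decoys above the
  threshold or under other traits), overlapping the DE set in 18 genes
  (2 ncRNA).
* **Families**: three nuclear families, 11 members, 7 affected, each with
  an affected transmitting parent. Planted variants co-segregate by
  construction (every affected member of one family heterozygous);
  background variants draw founder genotypes from Hardy–Weinberg with
  allele frequency uniform on (0.05, 0.4), transmit alleles Mendelianly,
  and are rejection-sampled (capped at 1000 attempts, then a hard error)
  until they fail the rule in every family.
* **Variant plan**: 127 co-segregating variants across 15 of the overlap
  genes (100 intronic, 20 common nonintronic, 7 low-frequency
  nonintronic), and 57 in 7 functional-partner genes (39 intronic, 18
  nonintronic). Consequence classes are planted by direct codon search on
  the generated transcripts, not by calling the classifier.
* **Frequencies**: binomial allele counts at allele numbers 2196
  (affected cohort of 1098 exomes), 214 (a Tuscany-sized reference
  sample), and 68,032 (a large non-Finnish European reference). Planted
  low-frequency control frequencies lie in (0.0005, 0.012) — small enough
  that a realized frequency essentially never crosses the 0.04 ceiling
  even in the 214-allele sample — with planted affected-control
  differences of +0.02 (low-frequency) and +0.15 (common), sized for
  near-certain detection against the large control and honest
  non-detection against the small one.
* **Transcripts**: 2–6 exons, 120–400 codons, UTRs of 40–200 nt, both
  strands, valid by construction (start codon, no internal stop, terminal
  stop). Two hand-crafted minus-strand fixtures reproduce the published
  Gly482Ser codon geometry and the c.-54 5'-UTR geometry exactly.

One integer seed drives independent sub-streams per generator, so any
stage regenerates byte-identically on its own. What the generator does
*not* emulate: linkage disequilibrium, probe-level microarray noise,
population demography, sequencing error, and multi-transcript genes —
passing tests demonstrate the pipeline's correctness on its stated model,
not robustness to those real-data features.

# The partner arm

Functional-partner genes (interaction partners of disease-GWAS gene
products) enter as a plain gene list — interaction-database retrieval is
out of scope. The pipeline restricts this arm to partner genes that are
*also differentially expressed*, mirroring how the partner list was
defined in the motivating study, and applies only the nonintronic
restriction (no MAF ceiling): partner variants are common coding SNPs by
design. With 7 low-frequency disease-GWAS variants and 18 partner
nonintronic variants the tested family has $m = 25$ and threshold 0.002.

# Numerical and design choices

* Coordinates are 1-based inclusive throughout (VCF convention).
* Multiallelic sites are split into biallelic records, never dropped;
  half-calls (`./1`) are conservatively treated as missing, with counts
  logged.
* All readers reject malformed rows rather than coercing; every dropped
  record is counted.
* The trigamma inversion uses a Newton iteration that is stable because
  trigamma is monotone and convex in $1/y$; extreme arguments use
  asymptotic starts.
* Tie at $\Delta = 0$ in fold-change direction: "up", so outputs are
  deterministic and diffable.

# Problem sizes in the test suite

The test suite validates at these scales: exhaustive segregation
enumeration on $4^4 \times 5$ rule settings; 1000 random allele tables
for the z-test/chi-square identity; 1000 random substitutions for the
classifier oracle; 10,000 replicates at 2196 vs 250 alleles for the
z-test size (accepted band 0.035–0.065); 5000 genes for hyperparameter
recovery ($d_0$ within 20%, $s_0^2$ within 10%); planted-recovery runs at
50 planted + 950 background variants; and 20 fully null end-to-end
studies at 1200 genes each, which must produce zero significant-tier
calls in at least 18. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

# Known limitations

* Only single-nucleotide substitutions are classified; indels are out of
  scope.
* One transcript per gene; canonical-transcript choice is the input's
  burden.
* The dominant carrier model is the only implemented transmission model;
  recessive/X-linked logic would need new rule types.
* No covariate adjustment or exact tests in the association stage; the
  pooled z-test is the published method and small-count tables lean on a
  normal approximation.
* CADD scores and eQTL targets are consumed as annotations when supplied;
  they are never computed.
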