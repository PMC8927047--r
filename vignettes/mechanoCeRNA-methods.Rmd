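---
title: "Models and methods behind mechanoCeRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechanoCeRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
what each stage assumes, which knobs matter, what the synthetic-data
generator does and does not emulate, and where genuinely open design
choices were settled.

# The analysis problem

A two-group bulk RNA-seq comparison (mechanical stress vs control, three
biological replicates each) quantified at four layers: mRNA, miRNA,
lncRNA and circRNA. The aim is to move from raw counts to a regulatory
reading: which transcripts respond, which responding lncRNAs are novel,
which coding genes the lncRNAs plausibly regulate in cis / trans /
antisense, and which mRNA–lncRNA/circRNA pairs compete for shared miRNAs
(ceRNA). With n = 3 per group every statistical choice below is shaped by
the tiny sample size.

# Differential expression

**Filtering.** A transcript is kept iff its *group-wise mean* raw count
reaches 5 (coding) or 2 (non-coding) in at least one group. The rule is
stated in the literature as "low count in both groups were removed"
without saying whether "count" is a mean or a sum; the mean was chosen so
the rule does not change meaning if the replicate number changes.

**Normalization.** Trimmed mean of M-values against the highest-depth
sample as reference: per-gene log2 ratios (M) and average log abundance
(A) vs the reference, 30% trimming on M and 5% on A from each tail,
inverse-asymptotic-variance weighting, and rescaling of all factors to
geometric mean 1. This follows the published TMM algorithm; the test
suite cross-checks the factors against an independent reference
implementation on fixtures.

**Exact test.** Counts are pseudo-equalized to the geometric-mean
effective library size, summed per group, and tested conditionally: under
a common dispersion $\phi$, a group sum of $n$ i.i.d. NB($\mu, \phi$)
counts is NB($n\mu, \phi/n$), and the two-sided p-value is the total
probability of all splits of the overall sum whose conditional
probability does not exceed that of the observed split (the minimum-
likelihood definition; the "doubling" convention was rejected because its
tie handling is less deterministic). At $\phi = 0$ the conditional law is
exactly the binomial split test, which the tests exploit as a closed-form
oracle.

**Common dispersion.** With three replicates per group, tagwise
dispersions are hopeless; a single common $\phi$ per layer is estimated
by conditional maximum likelihood (the within-group distribution of
counts given their sum is Dirichlet-multinomial and free of the group
means). Genes whose per-gene moment dispersion exceeds 10x the positive
median are set aside before fitting: a handful of strongly co-regulated
transcripts (exactly the structures this pipeline is looking for) are
overdispersed relative to the bulk and would otherwise inflate the shared
estimate severalfold, destroying power for everything else. On clean null
simulations the estimator recovers the true value (0.099 at truth 0.1)
and the test's type-I error at the 0.05 level is 0.047.

**Fold change.** log2 of the ratio of group mean CPMs with a prior count
of 0.5 (in raw-count units at the average effective library size) added
to both groups. No shrinkage is attempted: published analyses of this
kind print extreme fold changes (|log2FC| above 14) that imply a very
small prior, and matching a particular shrinkage scheme is not the point
of the statistic.

**Calling.** mRNA/lncRNA: |log2FC| > 1 (strict) and BH FDR < 0.05;
miRNA/circRNA: |log2FC| > 1 and raw p < 0.05. The literature is
internally inconsistent here (one figure legend implies FDR for all
layers); the methods-section rule is implemented, and both thresholds sit
in `runConfig()` if a user prefers otherwise.

**PCA** is computed on log2(CPM + 1) with gene centering; the input
transform is not stated in published descriptions of this workflow, so the package uses the
field's default and says so.

# Novel lncRNA discovery

The published procedure intersects two external coding-potential tools
and a protein-database screen. The *intersection logic* is the defined
computation and is preserved exactly; the external tools are replaced by
two self-contained scorers:

* **Fickett TESTCODE** — the classical position/composition statistic
  with its published lookup tables (a stand-in for an SVM-based
  coding/non-coding index); default non-coding cutoff 0.95.
* **Longest-ORF fraction** — longest ATG-to-stop span across the three
  forward frames divided by transcript length (transcripts are stranded,
  so reverse frames are not scanned); default non-coding cutoff 0.30.
* **Annotation screen** — membership in the known-id catalogue (a
  sequence-similarity search is out of scope; the catalogue plays the
  database's role).

A transcript is a novel lncRNA iff both scorers call non-coding, the
screen finds nothing, and length ≥ 200 nt. The two cutoffs are package
defaults, flagged as such — published descriptions give none.

# lncRNA target assignment

Structural candidates: *cis* = DE lncRNA and DE coding gene with interval
gap strictly below 100 kb (overlap counts as distance 0; gap arithmetic
is 1-based inclusive and covered by per-bp oracle tests); *antisense* =
at least 1 bp of overlap on opposite strands; *trans* = every remaining
DEL x DEM pair. Restricting trans to the differential sets mirrors how
such studies report them; a full-transcriptome trans search would only
add candidates, not change the gates.

Every candidate must pass |Pearson r| > 0.9 with two-sided t-test
p < 0.05, computed across all six samples pooled. Pooling mixes the group
effect into the correlation — with n = 6 that is the only way the 0.9
gate is reachable at all, and it matches the co-expression intent; the
caveat is documented here deliberately: a pair can pass purely by strong
antagonistic (or parallel) group response. Each (lncRNA, gene) pair is
reported once with mode priority antisense > cis > trans (published
analyses report modes jointly; a priority was needed to make the output
unique).

Antisense pairs carry a **duplex score**: the minimum over all ungapped
antiparallel window alignments (window 40 nt) of summed pair scores
(Watson–Crick −2, G·U wobble −1, mismatch +3). It is a complementarity
surrogate, *not* a nearest-neighbor free energy; it is annotation-only by
default because no energy cutoff is published, and `duplex_max` gates on
it if desired.

# ceRNA network

miRNA targets come from seed matching on the DE sponges' 3'UTRs: the
6mer core is the reverse complement of miRNA nt 2–7, extended to
7mer-m8 / 7mer-A1 / 8mer by the nt-8 match and the A opposite nt 1;
the default minimum class is 7mer-m8 (the strong classes), a documented
stand-in for the external hybridization predictors. Gates, in order:
per-miRNA negative co-expression r < −0.9 (strict) against each sponge;
at least one shared gated miRNA; positive sponge–sponge correlation; and
the hypergeometric upper-tail test on the shared count with the universe
N set to the number of differential miRNAs (published workflows defer the
universe to an external description; N is configurable). Degree is the
number of distinct shared miRNAs per node — the published "number of
co-expressed targeted miRNAs" — with the plain edge count reported
alongside, and hubs at degree ≥ 5. Sponge pair types default to
mRNA–lncRNA and mRNA–circRNA, matching the miRNA-centric networks the
procedure was built for; lncRNA–circRNA pairing is a constructor option.

# Enrichment

ORA is the same hypergeometric kernel over GMT collections with BH
adjustment. GSEA uses the weighted KS running sum (hit increments
proportional to |metric|^p, default p = 1; miss decrement 1/(N−K)), with
a **gene-set permutation** null: with three replicates per group only ten
distinct phenotype relabelings exist, far too few for an empirical null,
so random same-size gene sets are drawn instead. NES is the ES divided by
the mean |null ES| of the same sign, p is the add-one-smoothed same-sign
tail, and FDR is BH across terms on those empirical p-values (simpler
than the original pooled-NES procedure, and documented as such). The
ranking metric is sign(log2FC) · (−log10 max(p, 1e−300)) with ties broken
lexicographically — published workflows do not state their metric.

# The synthetic-data generator

The generator is the package's test bed and defines its study
conditions: one synthetic chromosome, coding genes on a 250 kb grid,
lncRNAs placed as cis candidates (gap 5–90 kb), antisense candidates
(opposite-strand overlap) or distal (> 100 kb from every gene), miRNA
and circRNA loci downstream; 3 vs 3 design, library sizes ~5e5 (±10%),
NB dispersion 0.1 (typical bulk RNA-seq), half the lncRNAs flagged novel
(matching the roughly 50% novel fraction such studies report).

Planted structure: stand-alone DE transcripts at |log2 effect| = 2 on
baselines ≥ 100 (the conditions under which DE sensitivity is measured);
pair/module members at |log2 effect| = 6 — well inside the |log2FC| 10–14
range the strongest published responders show — with effects centred so
each group mean is baseline × 2^(±effect/2). Co-expression is induced by
a shared per-sample latent factor (SD 1.5 on the log2 scale) added with
positive sign to sponges and lncRNA targets and negative sign to module
miRNAs. The sizing is deliberate: at dispersion 0.1 the per-sample
log2 noise floor is ≈ 0.21 variance, and a strict |r| > 0.9 gate at
n = 6 needs shared variance an order of magnitude above that — the
generator must make the gate reachable or pair recovery would be
untestable. Module direction (sponges up / miRNA down or the reverse) is
randomized per module so the small miRNA layer is not compositionally
skewed, which would break TMM there.

Sequences are constructed so structural assertions are provable rather
than probabilistic: every generated miRNA seed (nt 2–7) contains at least
one C, and non-target 3'UTRs are drawn from the {A, C, T} alphabet — a
seed core match requires a G, so non-targets provably contain no site for
any generated miRNA, while each planted (miRNA, target) pair gets one
exact 8mer spliced in. Novel lncRNA sequences are rejection-sampled to be
ORF-poor (ORF fraction < 0.3, Fickett < 0.9); antisense partners get a
long-ORF coding sequence whose 40-mer reverse complement is embedded in
the lncRNA, making the duplex score exactly −80.

What the generator does **not** emulate: batch effects, splicing,
GC/length bias, realistic UTR composition (the G-free screen is a
construction device, stated openly), tagwise dispersion spread, and any
read-level artifacts. Passing recovery tests therefore demonstrates the
pipeline's internal correctness under its own model, not robustness to
real-data pathologies.

# Numerical choices and degenerate inputs

* Exact-test ties: probabilities within a relative 1e−10 of the observed
  split's probability count as "as extreme" to make tie handling
  deterministic across platforms.
* All-zero transcripts: log2FC 0, p 1. Zero-variance expression vectors:
  correlations are flagged undefined and the pair skipped, never NaN.
* Dispersion optimization runs on log φ over [1e−6, 10] with an explicit
  boundary check that returns 0 when the likelihood is monotone toward
  zero.
* Fickett bin edges get a 1e−9 epsilon so exact boundary compositions
  (e.g. 1/3) land in their nominal bin on all floating-point platforms.
* GSEA with every gene in the set has no miss decrement; the ES is the
  maximum of a monotone walk, in (0, 1].
* The GTF reader requires an explicit strand for every transcript
  (antisense logic is meaningless without it) and reports the offending
  file line.

# Problem sizes used by tests and the acceptance script

Unit and property tests run on fixtures of tens to a few hundred
transcripts. Recovery checks use the default conditions (2,000 coding,
300 lncRNA, 50 miRNA, 100 circRNA; 20 seeds in the test suite, 5 in the
acceptance script) and a 120/40/25/20 configuration for the fast
end-to-end checks; the null-calibration check uses ten 2,000-gene null
simulations. These sizes were chosen so the full suite exercises every
stage at meaningful scale while remaining a routine desktop run.

# Known limitations

* The exact test assumes a single common dispersion per layer; strong
  per-gene dispersion heterogeneity will mis-calibrate tails.
* Pooled-sample correlation gates conflate group response with
  co-regulation (see above); interpret trans pairs accordingly.
* The duplex score and seed matcher are sequence-complementarity
  surrogates without thermodynamics or conservation.
* The hypergeometric shared-miRNA test treats miRNA target sets as
  exchangeable draws; correlated targeting violates that assumption.
* With a small miRNA universe (N ≤ 20), a single shared miRNA can never
  reach p < 0.05 — a structural property of the test worth knowing when
  configuring simulations or interpreting sparse networks.
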