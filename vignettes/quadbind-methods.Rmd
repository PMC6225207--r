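---
title: "Methods: composition profiling and RG-rich motif analysis of quadruplex binding proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition profiling and RG-rich motif analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

G-quadruplex (G4) structures — four-stranded arrangements of guanine-rich
DNA or RNA — are recognised by a distinctive set of proteins, many of which
carry intrinsically disordered arginine/glycine-rich (RGG/RG) regions.
`quadbind` characterises such protein sets through their amino-acid
composition and through the RG-rich motifs themselves: composition
profiling with a bootstrap enrichment test, residue-content correlation,
composition-based clustering with bootstrap support, position-weight-matrix
(PWM) scanning under an exact background null, de novo ungapped motif
discovery, and motif-based ranking of new candidate binders.

Throughout, a protein's composition is the fraction of each of the 20
canonical residues among its canonical residues. Ambiguity codes
(X, B, Z, U, O) are tolerated on input but excluded from both numerator and
denominator, so composition rows always sum to 1 and percentages remain
comparable across proteins regardless of how many ambiguous positions they
contain. The alternative — spreading ambiguous counts across residues —
would shift every fraction by an amount that depends on the annotation
quality of the source database rather than on the protein.

# Composition profiling

`composition_matrix()` stacks per-protein compositions into a proteins × 20
matrix. `boxplot_stats()` summarises each residue column with type-7
quartiles and the 1.5 × IQR whisker rule, reporting outlying proteins by
name; `relative_change()` compares set means against a reference frequency
table as $(\bar c - c_{\mathrm{ref}})/c_{\mathrm{ref}}$, classifying
residues with $|{\cdot}| > 0.10$ as enriched or depleted (the threshold is
an argument). Reference frequencies are deliberately an input, not a
constant: proteome-wide residue frequencies differ between releases and
species, so `read_reference_frequencies()` reads a two-column table and
`reference_frequencies_from_set()` derives one from any supplied proteome
FASTA. The table shipped in `inst/extdata/` is synthetic and only for
examples, as its name says.

`kmer_composition()` counts overlapping k-mers normalised by the number of
valid windows, so per-protein k-mer rows are probability vectors and the
k = 1 case coincides with the composition matrix. `shared_kmer_search()`
answers the complementary question — is any k-mer literally universal in
the set — by exact substring intersection.

# Bootstrap enrichment test

`bootstrap_enrichment()` compares the query set's residue frequencies with
a background set's, in the style of composition-profiler tools. The default
statistical unit is the pooled residue: each set's canonical residues are
resampled with replacement (equivalently, a multinomial draw over observed
frequencies), which reflects the view that the set is one large sample of
residues. Protein-level resampling — resampling whole proteins and
averaging their composition rows, appropriate when between-protein
variation is the dominant noise — is available via
`test_config(sampling_unit = "protein")`.

For each residue the test forms the bootstrap distribution of frequency
differences and reports a two-tailed empirical p-value with add-one
correction,

$$p = \min\!\left(1,\; \frac{2(k+1)}{B+1}\right),$$

where $k$ counts bootstrap differences falling on the opposite side of
zero from the observed difference and $B$ is the number of iterations
(default 10,000). The doubling matters: the directed tail alone is a
one-sided p-value, and calibration runs against a null with identical
generating frequencies showed it inflating the family-wise error to
roughly twice the nominal level, while the doubled version sits at the
nominal 5% with the Bonferroni correction (α/20 = 0.0025 for the 20
per-residue tests; stars at 0.0025 / 0.0010 / 0.0001). The reported effect
size is always $(\bar q - \bar b)/\bar b$ on the original means, never on
resampled ones. With $B$ iterations the smallest attainable p-value is
$2/(B+1)$; at the default $B = 10{,}000$ this is below the strictest star
level.

`correlation_analysis()` correlates residue-content columns across proteins
(Pearson by default, Spearman via argument) with two-sided p-values from
the t transform with $n-2$ degrees of freedom — identical to `cor.test` —
and a mask of pairs with $p > 0.05$. Constant columns have undefined
correlation and are reported as `NA` and masked rather than silently
dropped.

# Clustering with multiscale-bootstrap support

Proteins are clustered by average linkage (UPGMA-style agglomeration via
`stats::hclust`) on either correlation distance $1-r$ between composition
rows (default) or Euclidean distance. Equal linkage distances are broken by
`hclust`'s internal rule; for continuous composition data exact ties have
probability zero, so this choice is immaterial in practice and keeps the
implementation on the reference C code path.

Support values come from multiscale bootstrap over the 20 residue-fraction
**feature columns**: at each relative scale $r \in \{0.5, \dots, 1.4\}$
(10 scales, total replicate budget split evenly, default 10,000), columns
are resampled with replacement to size $\mathrm{round}(20r)$, the tree is
re-fitted, and $BP_r$ — the fraction of replicates containing each original
cluster as a leaf set — is recorded. The probit transforms
$\psi(r) = \Phi^{-1}(1-BP_r)$ are fitted by weighted least squares to
$d\sqrt{r} + c/\sqrt{r}$, giving the approximately unbiased support
$AU = 100\,(1-\Phi(d-c))$ and the fitted plain-bootstrap value
$BP = 100\,(1-\Phi(d+c))$; proportions of 0 or 1 are clipped to
$1/2B$ and $1-1/2B$ before the transform, and clusters never or always
observed at every scale are flagged degenerate with AU set to 0 or 100.
With only 20 features, AU estimates are inherently noisy; supported
conclusions should rest on clearly separated groups, which is exactly what
the synthetic recovery test uses.

`cut_by_support()` returns the maximal (non-nested) clusters with
AU ≥ 95 by default. The root bipartition is trivially contained in every
replicate, so it is excluded unless `include_root = TRUE`; including it
would make any threshold return the whole tree.

Two numerical choices in the recovery experiment deserve explanation. The
synthetic two-group data shift glycine by +0.05 in one group of 10 versus
the other; the generator draws sequences of length 1000 so that
multinomial noise in each composition entry
($\mathrm{sd} \approx \sqrt{p(1-p)/L}$) is well below the planted shift.
And the recovery test clusters on Euclidean distance: under correlation
distance only the *shifted* group is internally correlated — the unshifted
group's rows are mutually independent noise around the base composition,
so its bipartition has no cohesion to recover, whatever the support
machinery does. Replicates at scale $i$ are drawn from a stream seeded
with `seed + i`, so per-scale proportions can be reproduced (and are, in
the test suite, by an independent direct-count oracle at $r = 1$).

# PWM scanning with exact p-values

`peptide_to_pwm()` turns a peptide (e.g. the 26-residue FMR1 RGG-box or
the 20-residue RG-rich consensus shipped as `FMR1_MOTIF` / `NIQI_MOTIF`)
into a PWM: position $i$ gives probability $1-\varepsilon$ to the peptide
residue plus $\varepsilon\,b_a$ to every residue $a$, with total
pseudo-probability $\varepsilon = 0.01$ by default and a uniform
background. Scores are log-odds sums in bits.

Exact p-values use the standard dynamic-programming construction: log-odds
entries are discretized to bins of 0.001 bit (`granularity`), and the
distribution of total window scores under the background model is built by
convolution across positions, yielding $p(s) = P(\text{score} \ge s)$ for
every achievable score. Because scanning uses the same discretized matrix,
reported p-values are exact for the discretized scores and reproducible
bit-for-bit. Zero motif probabilities (only possible at
$\varepsilon = 0$) have $-\infty$ log-odds, clamped at −20 bits to keep
the support finite; a −20-bit penalty already puts any window containing
such a position beyond every practical threshold. Ambiguity-code positions
contribute 0 bits (background-neutral) rather than disqualifying their
windows.

`scan_set()` reports hits at $p < 0.01$ by default and computes
Benjamini–Hochberg q-values over **all** tested windows of the scan — the
universe a genome-scale scanner uses — not merely the windows that passed
the threshold. `classify_by_q()` partitions proteins by best q-value at
0.05 and 0.1; `multi_hit_proteins()` lists repeat carriers with their hit
positions; `predict_candidates()` ranks a target set by best hit
(ascending p, ties by descending score, then id), drops supplied known
binders, and keeps the top 100 by default — the motif-based route to
proposing new quadruplex binders.

# Gibbs motif discovery

`gibbs_discover()` is a site-sampling Gibbs sampler for a shared ungapped
motif of fixed width (default 20): per sweep, each sequence's site is
re-sampled from the posterior over windows under the PWM estimated from
all other sequences' sites, with Dirichlet pseudocounts proportional to
the background (weight 0.1, i.e. 2 pseudocounts total). The default
occurrence model is ZOOPS — zero or one occurrence per sequence, with
prior site probability 0.9 — so sequences without the motif can opt out.
After each sweep a phase-shift move proposes translating every site by
±1 or ±2 and accepts on score improvement; without it the sampler
reliably converges to misregistered local optima one column off the
planted register. The tracked quantity is the best total log2
likelihood-ratio score of the alignment seen so far, which is
non-decreasing by construction; restarts (default 10) run up to 500 sweeps
each and stop early after 50 sweeps without improvement. Gapped alignment
in the style of full glam-type samplers is out of scope: the motif of
interest here is a contiguous 20-mer, and planted-motif recovery is the
verifiable contract.

`best_ungapped_identity()` compares two motif strings by sliding the
shorter over the longer at all full-overlap offsets and reporting the
maximal percent identity; gapped alignment would change the definition of
the reported identity and is deliberately not offered. The package's two
reference peptides align at 75% identity over 20 positions (offset 1),
which the test suite verifies against exhaustive offset enumeration.

# Synthetic data: what it does and does not emulate

All tests run on data from the `synthetic_data` generators:
`gen_background()` draws i.i.d. residues from a stated frequency vector;
`gen_grouped()` adds per-group frequency offsets (renormalized) and keeps
the labels as ground truth; `plant_motif()` overwrites non-overlapping
motif copies at uniformly chosen positions (sampled by the
stars-and-bars construction, so placements are uniform over all
non-overlapping configurations), mutating each planted residue with a
given substitution probability. Overwriting rather than inserting keeps
sequence lengths fixed, which keeps position bookkeeping and composition
expectations simple. Every generator is a pure function of its spec and
seed.

These generators emulate residue frequencies, composition shifts, and
motif occurrences — the quantities the pipeline measures. They do not
emulate domain architecture, repeat polymorphism, disorder profiles, or
the phylogenetic correlation between real proteins; passing recovery
tests therefore demonstrates that the statistics behave as designed under
their stated models, not that real proteome analyses will show the same
effect sizes. Analyses of real sets require user-supplied FASTA (the
package performs no network retrieval).

# Default problem sizes

The shipped tests and the acceptance script use: 100 null simulations of
200+200 proteins (bootstrap B = 2000) for type-I calibration; 500+500
proteins for power against a glycine shift 0.07 → 0.12; 10+10 proteins of
length 1000 with 1000 replicates per scale for cluster recovery; 50
sequences of length 300 with 10% substitution for discovery recovery
(3 restarts × 150 sweeps, which converges well before the package
defaults); and a 77-protein synthetic set with two planted motif copies
per protein for the scan stage. These sizes were chosen to estimate each
property with comfortable margins while keeping a full run in minutes.

# Known limitations

* AU support from 20 feature columns is noisy; only well-separated
  clusters yield stable AU ≥ 95 calls.
* The enrichment test assumes exchangeable residues (default unit) or
  exchangeable proteins; neither models within-protein residue
  autocorrelation.
* q-values depend on the scan universe: scanning a different target set
  changes every q even if a protein's hits are unchanged.
* The discovery sampler finds one motif per run; iterative masking for
  secondary motifs is left to the user.
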