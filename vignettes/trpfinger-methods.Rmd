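---
title: "Methods: conservation fingerprints and structural core analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation fingerprints and structural core analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpfinger)
```

# Scope and model

`trpfinger` analyses conservation in the transmembrane region of TRP
channels and related 6TM proteins along three complementary axes:
column statistics of a family-wide multiple sequence alignment (MSA),
geometric statistics over a collection of experimental structures, and a
pairwise (Potts) sequence model fitted by pseudo-likelihood.  The package
consumes pre-aligned MSAs and deposited coordinates; building alignments,
retrieving orthologs and inferring phylogenies are out of scope.

# Conservation scanning

For column $c$ of an $N \times L$ alignment, with $n_a(c)$ the count of
residue $a$:

* identity $= \max_a n_a(c) / N$,
* class identity $\Phi(c) = (n_F(c) + n_Y(c)) / N$,

and a column is *highly conserved* when identity (or, with class grouping
enabled, $\Phi(c)$) **strictly** exceeds the threshold, default $0.90$.
Two conventions needed fixing where the source analyses leave them open:

* **Denominator.**  Gapped sequences are counted in the denominator, so
  gaps erode conservation.  This is the conservative reading — it keeps a
  90% threshold meaningful in variably gapped regions — and the
  alternative (non-gap denominator) is exposed via
  `gap_denominator = FALSE` for sensitivity analysis.
* **Class membership.**  The aromatic class is exactly $\{F, Y\}$
  (six-carbon aromatics); tryptophan is excluded.  Unknown residues
  (`X`) count in the denominator but can never be the consensus, and
  consensus ties break alphabetically (deterministic output).

Logo data report, per column, non-gap residue frequencies and the
information content $\log_2 20 - H$ where $H$ is the Shannon entropy of
the frequency vector; an all-gap column yields a flagged zero-information
row rather than an error.

# The twelve-slot fingerprint

The default fingerprint is the ordered signature
W F Φ G Φ Φ Φ N L I A W at alignment columns
81, 320, 331, 633, 662, 755, 852, 862, 864, 865, 866, 883 (equivalently,
rat TRPV1 positions 426, 434, 441, 563, 591, 638, 666, 676, 678, 679,
680, 697).  The scoring rule is:

* single-residue slots match on strict identity;
* Φ slots match any of $\{F, Y\}$;
* a literal `Φ` in an *input* row (as printed in subfamily consensus
  rows) matches Φ slots only;
* gaps never match.

This is the maximal-agreement reading of the published per-subfamily
counts: it reproduces every published row that is internally consistent
(TRPV/TRPM/TRPC 12, TRPN1 11, TRPA1 10, CsTRP2 9, TRPY 8, CrTRP1/TRPVL 7,
hPKD2/mTRPML1 6, KvAP/NavAb 5, Kv1.2 3, Shaker 2).  A small number of
printed rows are not consistent under any fixed rule (a slot-2 aromatic
sometimes counted, sometimes not); we treat slot 2 as strict F by default
and expose `fingerprint_default(slot2_phi = TRUE)` for the alternative.
Definitions are also loadable from JSON so non-default signatures can be
scored.  The census (`fingerprint_census`) reports, for $k = 0..12$, the
fraction of sequences with exactly $k$ and at least $k$ matches; when a
labelled alignment mixes families, the intended denominator is the TRP
rows (the deposited family alignment contains only TRP and TRP-like
sequences, so the default is all rows).

# Emission entropy

Match columns are those with gap fraction strictly below 0.5.  Emissions
are estimated with a single total pseudocount $\kappa$ over a background
$b$ (default uniform):
$p_c(a) = (w_a(c) + \kappa b_a) / (W(c) + \kappa)$,
where $w_a(c)$ is the (optionally sequence-weighted) non-gap count.  The
profile-HMM machinery that originally produced these rankings (Dirichlet
mixture priors, internal weighting) is deliberately **not** replicated:
the entropy *ranking* of columns is robust to the prior, and the simple
estimator is exactly testable ($\kappa = 0$ recovers empirical
frequencies; $\kappa \to \infty$ recovers the background).  Entropy is
reported in bits; the base only rescales and never reorders.

# Ensemble distograms

Residue–residue distances use the Cβ atom (Cα for glycine; Cα fallback
with a warning for truncated side chains).  Positions are the alignment
columns present in more than 96% of sequences (strict), optionally
intersected with annotated regions (pre-TM1, TM1–TM6, linker, pore,
TRP-domain helix).  Per-structure matrices are masked, not dropped: a
cell aggregates every structure where both positions resolve, and the
per-cell count is reported.  Ensemble statistics are

$$\mu_{ij} = \overline{d_{ij}},\qquad
  \sigma^2_{ij} = \overline{(d_{ij}-\mu_{ij})^2},\qquad
  \tilde\sigma^2_{ij} = \sigma^2_{ij} / \mu_{ij}^2 .$$

The **population** variance (divide by $n$) is the default because the
ensemble is the object of study, not a sample from a larger population;
`sample_variance = TRUE` switches to $n-1$.  The normalized variance is
dimensionless and scale-invariant, which removes the bias toward large
variances at large separations and highlights variable *short-range*
pairs.  Numerical choices: variance uses the two-pass formula and is
clamped to exactly zero for constant cells, so replicate ensembles report
identically zero variance; cells observed in fewer than two structures
have masked variance; the whole computation is superposition-free (only
pairwise distances), hence rigid-motion invariant by construction.

# Aromatic core

For each residue $r$ of a helix, with $o$ the opposing-helix residue
minimising $d(C\alpha_r, C\alpha_o)$, residue $r$ *faces the core* iff

$$d(C\alpha_r, C\alpha_o) > d(C\alpha_o, C\gamma_r)$$

(strict), i.e. the gamma atom points inward.  Both orderings of each
opposing pair (TM1–TM3, TM2–TM4) are evaluated and unioned, since the
original procedure's directionality is not documented.  "Cγ" means the
residue's gamma-position heavy atom: CG generally, CG1 for Ile/Val,
OG/OG1/SG for Ser/Thr/Cys; Gly and Ala have none and are never facing.
Facing aromatics (default {Phe, Tyr, Trp}; His available via
`include_his`) are then connected by edges where the minimal heavy-atom
pair distance is strictly below 5 Å and single-linkage clusters are the
connected components — so raising the threshold can only merge clusters,
never split them.  Contact detection applies a 4 Å minimal-heavy-atom
threshold generally and 5 Å for aromatic–aromatic (π–π) pairs, with a
`cross_chain` pass for inter-subunit contacts.  Hydrogens are excluded
throughout (absent from most deposited models); backbone atoms are
included in minimal distances by default (`side_chain_only` to restrict).

# Direct coupling analysis

`plmdca()` fits fields $h_i(a)$ and couplings $J_{ij}(a,b)$ of a Potts
model by asymmetric pseudo-likelihood: each column's conditional
multiclass model is fitted independently with objective

$$f_r = -\frac{1}{M_\mathrm{eff}}\sum_s w_s \log
        P(x_{sr}\,|\,x_{s,-r}) + \lambda_h\lVert h_r\rVert^2
        + \lambda_J\lVert J_{r\cdot}\rVert^2,$$

then $J_{ij} \leftarrow (J_{ij} + J_{ji}^\top)/2$.  Sequence weights are
$w_s = 1/|\{t: d_H(s,t)/L < \theta\}|$ with $\theta = 0.1$;
$\lambda_h = \lambda_J = 0.01$ as printed, interpreted in the cited
algorithm's $M_\mathrm{eff}$-normalised convention.  Optimisation is
L-BFGS with analytic gradients (tolerance $10^{-5}$ on the projected
gradient, 500 iterations; non-convergence is an error carrying
per-column diagnostics, demotable to a warning).  Scores are the
Frobenius norms of gap-excluded coupling blocks in the zero-sum gauge,
followed by the average-product correction
$F_{ij} - \bar F_{i\cdot}\bar F_{\cdot j}/\bar F_{\cdot\cdot}$ (full-row
means, under which a rank-one matrix maps exactly to zero).  Gauge
freedom is handled by gauge-fixing *before* scoring, so any gauge shift
of the fitted parameters leaves scores unchanged.  Two pragmatic knobs:
a desk-scale guard refuses $L > 400$ or $N > 20000$ without an explicit
override, and `alphabet` can be reduced to the observed states for
reduced-alphabet (synthetic) data — the default is the full 21-state
alphabet with gap as a state and unknowns mapped to gap.

# Synthetic worlds and what a green test establishes

The generators emulate the *statistical* structure the analyses rely on,
not protein physics:

* `simulate_msa`: i.i.d. background columns (uniform over 20 residues by
  default), planted columns carrying their residue with probability $p$
  (class columns draw F/Y at 1:3, mimicking a Tyr-dominated aromatic
  position), and subfamily indel blocks emitted as solid gaps.  Defaults
  for test fixtures use hundreds of sequences and conservation levels
  0.95–0.99, the regime of the real family alignment's conserved columns.
* `simulate_potts_msa`: single-chain Gibbs sampling with burn-in 500
  sweeps and thinning 5 (samples from one chain are mildly correlated;
  the acceptance-scale recovery test at $N = 2000$, $L = 30$, $q = 8$,
  5 planted same-state-favouring pairs of strength 2 is insensitive to
  this).
* `simulate_bundle_ensemble`: ideal α-helices (1.5 Å rise, 100°/residue,
  2.3 Å Cα radius) on a bundle circle of radius 8.5 Å; minimal side
  chains (Cβ, Cγ pseudo-atom, six-carbon ring template for aromatics)
  with gamma atoms displaced 2.5 Å from Cα toward or away from the
  bundle axis; optional rigid per-conformer displacement of one helix,
  isotropic coordinate noise, and an exactly 4-fold symmetric tetramer
  whose protomer spacing is tuned to a requested inter-subunit gap.
  A clash guard rejects geometries with inter-helix Cα distances ≤ 3 Å.

Green tests on these worlds establish that the *rules* are implemented
exactly (planted sets are recovered with precision = recall = 1, oracles
agree, invariances hold to stated tolerances).  They do not establish
performance on real structural data, which carries missing residues,
alternate conformations, non-ideal helix geometry and annotation errors;
the reader should treat the shipped helix annotations for PDB 7LP9 and
3J9P as approximate.

# Degenerate inputs and tie-breaking

* Ragged alignments, empty FASTA, labels for unknown ids: hard errors.
* Out-of-alphabet residues are mapped to `X` with a warning; `.` is read
  as a gap.
* All-gap columns: flagged in logo output; an error only when emissions
  are requested with zero pseudocount.
* Altloc atoms resolve to highest occupancy, ties toward altloc `A`;
  HETATM records are ignored; only PDB-format input is supported (no
  mmCIF reader is available in the dependency set, and deposited PDB
  files cover the intended inputs).
* Residues lacking Cα and Cβ are masked out of distance matrices;
  missing helix annotations are a hard error.

# Known limitations

* The profile-emission module ranks conservation; it is not a generative
  profile HMM (no transitions, no decoding).
* The DCA optimiser is pure R; at the guard scale ($L = 400$, $q = 21$)
  a fit takes hours, and the intended scale is exploratory
  ($L \lesssim 50$) or reduced alphabets.
* Ensemble-level published distogram values are not reproducible because
  the exact structure collection is not recoverable; the distogram code
  is therefore validated by its invariants and oracles.
* The pipeline runner executes stages sequentially in one process;
  deterministic reruns are guaranteed only for identical inputs, seeds
  and package version.
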