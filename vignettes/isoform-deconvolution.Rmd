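---
title: "Isoform deconvolution by convex-cost network flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform deconvolution by convex-cost network flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflow)
```

## The statistical model

`isoflow` treats isoform identification and quantification as one sparse
estimation problem. The gene model is an ordered list of *n* disjoint exons
on one strand (0-based half-open coordinates internally; GTF's 1-based
inclusive convention is converted at the annotation boundary, BED is used
as-is). Exons carrying alternative 5′-donor or 3′-acceptor sites are split
at every observed boundary when the annotation is loaded, so "exon" below
means one of these disjoint segments; abutting segments are re-merged when
predictions are written back to GTF.

A **bin** is the exact ordered set of exons a read overlaps. Sliding a read
of length $L$ along an isoform visits a sequence of bins; the number of
start positions assigned to bin $i$ is its **effective length** $l_i$,
which depends only on the bin's own exon lengths — not on the containing
isoform — and is

$$l_i = l_e - L + 1 \quad (\text{single exon}), \qquad
  l_i = \min(l_\mathrm{left}, L - l_\mathrm{int} - 1)
      + \min(l_\mathrm{right}, L - l_\mathrm{int} - 1)
      - L + l_\mathrm{int} + 1 \quad (k \ge 2).$$

Negative values clamp to zero and such bins are dropped. Within an isoform
of length $M$ the effective lengths of its bins partition the $M - L + 1$
admissible read starts; both facts are exercised as exact properties in the
test suite against a brute-force sliding count.

Bin counts $y_i$ are modelled as independent Poisson draws with intensity
$\delta_i = l_i \sum_j U_{ji}\theta_j$, where $U_{ji}$ indicates that bin
$i$ occurs in isoform $j$ and $\theta_j \ge 0$ is the isoform abundance in
expected reads per base. The estimator is the $\ell_1$-penalised Poisson
maximum likelihood over **all** candidate isoforms,

$$\hat\theta_\lambda = \arg\min_{\theta \ge 0}
  \sum_i \left[ \delta_i - y_i \log \delta_i \right] + \lambda \|\theta\|_1,$$

the $\log(y_i!)$ constants being dropped inside the optimisation (they are
restored in reported log-likelihoods and in BIC). The non-negativity plus
$\ell_1$ penalty yields sparse solutions; $\lambda$ controls how many
isoforms survive.

## The bin graph

Candidate isoforms are never enumerated. Instead a DAG is built whose
vertices are all bins with positive effective length consistent with a
junction set (by default the junctions actually observed in the
alignments — the de novo setting; annotation junctions can be supplied
instead). Only bins with internal length $\le L - 2$ can have positive
effective length, so the vertex count is polynomial in $n$ for fixed $L$.
An arc connects two bins that two reads at successive positions can
occupy: one slide step either drops the bin's first exon, appends a
junction-consistent next exon, or — when the first exon ends exactly where
a new exon is entered — both at once (a single combined arc; the geometry
decides). A source $s$ is connected to every *starting bin* (a read at the
first base of an isoform) and every *stopping bin* to a sink $t$; no
restriction is placed on transcription start or polyadenylation sites.
$(s,t)$-paths are then in bijection with candidate isoforms, a property
tested exhaustively on random small genes against direct chain
enumeration. Vertices on no $(s,t)$-path are pruned; counts observed on
pruned bins are reported as diagnostics, never silently dropped.

## Flow reformulation and the solver

Writing $f_v$ for the flow through vertex $v$ and $F$ for the total flow
into $t$, the estimator becomes

$$\min_{f \in \mathcal F} \sum_v \left[ l_v f_v - y_v \log (l_v f_v)\right]
  + \lambda F,$$

a separable convex-cost flow problem (vertex costs reduce to arc costs by
the classical node-splitting transformation, provided as
`node_split_transform()`; all arcs have zero lower and infinite upper
capacity). Any algorithm meeting the optimality contract is acceptable
here; `isoflow` uses fully-corrective column generation on the cone of
$(s,t)$-path flows:

1. price paths by the current gradient $c_v = l_v(1 - y_v/(l_v f_v))$ via a
   shortest-path dynamic program over the topological order ($\lambda$ is
   charged at the sink);
2. add the minimum-reduced-cost path to the active set;
3. refit all active weights by bound-constrained quasi-Newton (L-BFGS-B);
4. stop when no path prices below $-\mathrm{tol}\cdot\max(1, \sum_i y_i)$
   (default `tol = 1e-6`, iteration cap `1e5`, deterministic start at zero
   flow).

Because the penalised solutions are sparse, active sets stay small, and
each iterate is a certificate: the reported gap is the best reduced cost.
The tests verify the solution against a brute-force oracle (full path
enumeration plus generic convex minimisation) to 1e-4 relative on hundreds
of random genes, and against the closed form $\theta^\* = y/(l+\lambda)$
on single-bin problems. Inside the solver, logarithms are guarded by a
$10^{-12}$ additive term so line searches stay finite; exact conventions
($0\log 0 = 0$, $-\infty$ for positive counts under zero intensity) apply
to all reported values.

## Flow decomposition

The flow decomposition theorem guarantees the optimal flow is a
superposition of at most $|E'|$ path flows. `decompose_flow()` repeatedly
extracts the path carrying the maximum amount of flow — the
maximum-bottleneck path, by the same dynamic-programming pattern as a DAG
shortest path — subtracts its bottleneck, and stops when the remaining
flow into the sink falls below `min_frac` (default `1e-8`) of the original
total; "until convergence" needs a numerical threshold and this is ours.
Ties between equal-bottleneck paths go to fewer vertices, then the
lexicographically smallest vertex sequence, making extraction
deterministic; which of several maximum-bottleneck paths other
implementations return is unspecified, so this tie-break is a documented
local choice. The decomposition (like the $\ell_1$ estimator itself) is
not unique in general: the output is one solution attaining the optimal
objective value.

## Model selection

`fit_path()` walks a decreasing $\lambda$ grid — by default 20 log-spaced
values from $\lambda_{hi} = \sum_i y_i$ down to $10^{-4}\lambda_{hi}$,
since Poisson gradients scale with counts — warm-starting each solve from
the previous active set. Each support is refit by unpenalised maximum
likelihood (removing the $\ell_1$ shrinkage so models are compared on
genuine likelihoods) and scored by a Schwarz-type criterion

$$\mathrm{BIC} = \log \hat L - \tfrac{k}{2}\,\log N,$$

maximised over the path, where $k$ counts isoforms above a floor of
$10^{-6}$ of the total abundance (numerical zeros are not parameters) and
$N$ is the **total number of assigned reads**. The choice of $N$ deserves a
note: each read is one observation of the isoform mixture, and the Fisher
information about abundances grows with coverage, not with the number of
bins the reads are aggregated into. Using the bin count as the sample size
makes the penalty $O(\log q)$ with $q \approx 10$, while the chance
log-likelihood gain of the best spurious isoform grows with the size of
the candidate set; in simulation under the model itself that variant
overfits roughly a third of the time, whereas the read-count form recovers
the true support essentially always. Ties go to fewer isoforms, then to
the larger penalty. Likelihood-ratio testing and stability selection are
deliberately not implemented.

## The simulator, and what passing tests mean

`simulate_counts()` draws bin counts from exactly the Poisson model above;
`simulate_reads()` draws reads uniformly over admissible start positions,
with isoforms chosen proportionally to $\theta_j (M_j - L + 1)$, and emits
SAM with M/N cigars. Reads are error-free, perfectly and uniquely mapped,
single-end, and free of positional or sequence bias: the fixtures satisfy
the model's own assumptions. Recovery results on these fixtures therefore
demonstrate correctness of the estimator and its optimisation — not
robustness to mapping error, coverage bias, paired-end fragments or
annotation incompleteness, none of which are modelled.

The parameter-recovery study fits the canonical mutually-exclusive-exon
event (four exons; major isoform 1-2-4 and minor 1-3-4 at 3:1, read length
100, expected total 10^4 reads). That structure was chosen on
identifiability grounds: the minor isoform owns enough unique bins that
its maximum-likelihood relative standard error is about 2%, so a ±5%
accuracy band is a meaningful (~2.4 SE) criterion, whereas under heavy bin
sharing the same band shrinks to ~1 SE and no correct estimator could pass
it reliably.

## Evaluation protocol

A reference transcript counts as detected when a prediction has the same
exon chain and identical internal boundary coordinates — the start of the
first exon and the end of the last are free. Matching is greedy
one-to-one. Because outer boundaries are free, the rule alone would let
any two single-exon transcripts match; predictions must additionally sit
on the same reference sequence and overlap the reference span. Precision
and recall are reported pooled and stratified by the reference gene's
transcript count (or by exon count), since deconvolution difficulty grows
with the number of expressed transcripts.

## Numerical and design notes

- Coordinates: 0-based half-open everywhere internally; conversions only
  at the GTF boundary and in the bin-counts TSV dialect (0-based exon ids).
- Reads are counted only when fully embedded in the gene's exons;
  soft-clipped overhangs and reads straddling exon boundaries without a
  junction are discarded into a diagnostic count.
- Problem sizes in the test suite: random genes up to 6 exons for the
  oracle comparisons (so full path enumeration stays below 200 paths), 50
  seeded replicates for the recovery study, a 10-gene synthetic panel for
  the end-to-end SAM-to-GTF pipeline.
- Conservation is enforced to 1e-8 relative; decomposition reconstruction
  holds arcwise to 1e-9 per unit of total flow.

## Limitations

Single-end reads only (a paired-end mate would need fragment-length
heuristics that are out of scope); one gene at a time (no trans-splicing,
circular transcripts, or overlapping-gene deconvolution); the Gaussian
likelihood variant of the same flow formulation is not implemented; and
the reported isoform set is one representative of a possibly non-unique
optimum, as is inherent to $\ell_1$ estimators of this kind.
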