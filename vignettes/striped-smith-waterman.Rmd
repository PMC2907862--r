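---
title: "Striped and partitioned Smith-Waterman: models, design choices and validation"
author: "swstripe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striped and partitioned Smith-Waterman}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swstripe)
```

# The problem and the model

Protein database search asks, for one query sequence, which subjects of a
database contain a region similar to some region of the query.  The exact
answer is the optimal local alignment score computed by the Smith-Waterman
dynamic program with affine gap penalties.  For query $S_1$ (length $l_1$)
and subject $S_2$ (length $l_2$), with substitution matrix $sbt$, gap-open
penalty $\rho$ and gap-extension penalty $\sigma$ (a gap of length $k$
costs $\rho + k\sigma$), the recurrences for $1 \le i \le l_1$,
$1 \le j \le l_2$ are

$$
\begin{aligned}
H_{i,j} &= \max\{0,\; H_{i-1,j-1} + sbt(S_1[i], S_2[j]),\; E_{i,j},\; F_{i,j}\}\\
E_{i,j} &= \max\{H_{i,j-1} - \rho - \sigma,\; E_{i,j-1} - \sigma\}\\
F_{i,j} &= \max\{H_{i-1,j} - \rho - \sigma,\; F_{i-1,j} - \sigma\}
\end{aligned}
$$

initialized with $H_{i,0} = H_{0,j} = E_{i,0} = F_{0,j} = 0$.  $E$ tracks
gaps in the subject (horizontal moves), $F$ gaps in the query (vertical
moves), and the optimal score is $\max_{i,j} H_{i,j}$.  Only $H$ is clamped
at zero; $E$ and $F$ are carried as signed integers, exactly as the
recurrence dictates.  The package reports scores only — no traceback — so a
search result is a ranked score table.

Three engines compute the same number:

* **scalar** (`swScore`, `swFull`): a literal row-major evaluation of the
  recurrence, compiled, used as the correctness oracle.  Evaluation order
  is immaterial because a cell depends only on its left, upper and
  upper-left neighbours; the test suite re-evaluates the table in
  minor-diagonal order and checks for identity.
* **striped** (`stripedSwScore`): the basic vectorized algorithm on an
  emulated SIMD lane machine, with a striped query profile and a lazy-F
  correction loop.
* **partitioned** (`partitionedSwScore`): the query is cut into fixed-length
  partitions, each aligned with the striped engine, with per-column
  boundary values carried between partitions.

The defining contract of the two vectorized engines is bit-exact score
equality with the scalar engine on every input, which the test suite and
`scripts/acceptance.R` verify on hundreds of randomized instances.

# Scoring schemes

`loadMatrix` provides BLOSUM62 and BLOSUM50 with the classic NCBI matrix
file values (including the B/Z/X ambiguity rows and the `*` row), or reads
any user matrix in the NCBI text layout.  Matrices must be symmetric —
score symmetry of the engines depends on it — and an asymmetric user table
is rejected naming the offending pair.  Each alphabet reserves one *dummy*
code that scores 0 against everything; sequences are padded with it
wherever a layout needs a multiple of the vector length, so padding can
never change a score.  Unknown characters map to `X` by default (the usual
search-tool convention), or raise an error under `strict = TRUE`.

Gap penalties use the search-tool shorthand `"10-2k"` ($\rho = 10$,
$\sigma = 2$; a length-$k$ gap costs $10 + 2k$).  The extension penalty
must be at least 1: the vectorized engines rely on strictly decaying
vertical-gap scores for the termination of their correction loop, so
$\sigma = 0$ is rejected package-wide.

# Query profiles

A query profile replaces inner-loop matrix lookups: for each residue $r$,
$P_r(i) = sbt(r, Q[i])$.  The *sequential* layout stores each $P_r$ in
query order.  The *striped* layout, for a lane count $VL$, pads the query
to $T \cdot VL$ positions ($T = \lceil l / VL \rceil$) and assigns query
position $v \cdot T + s$ (0-based) to lane $v$, segment $s$.  Lanes
therefore hold *consecutive runs* of $T$ query positions, and within one
column of the alignment matrix the only cross-lane data dependency is the
vertical-gap $F$ — the property that makes the lazy-F scheme work.
`deStripe` inverts the mapping; an exhaustive sweep over
$l \le 200, VL \le 64$ checks that de-striping reproduces the sequential
profile exactly.

# The emulated lane machine

The paper's target hardware virtualizes a group of GPU threads as one SIMD
vector.  Here that machine is emulated by `VirtualVector`: a fixed array of
$VL$ integer lanes with lane 0 the logical rightmost element, a left shift
that moves values toward higher lanes (`shiftLeft`), lane-predicate votes
(`allLanes`/`anyLanes`, the warp-vote analogue), and saturating add/sub
built from max/min (`satAdd`/`satSub`).  Two deliberate generalizations:

* $VL$ may be any integer $\ge 1$, not only the hardware's 4/8/16/32; the
  engines must be correct for all of them, which widens the test space
  (including non-powers of two) at no cost to the emulation.
* The emulation is sequential, so thread synchronization has no analogue
  and is not modelled; neither are divergence or memory behaviour.  The
  emulation reproduces *values*, not timing.

With the default 32-bit score range the saturation clamp is unreachable at
realistic alignment scores, and the engines use plain integer arithmetic
plus an explicit overflow guard on input size.

# The striped engine and the lazy-F loop

Per subject column, the inner loop walks the $T$ segments once.  For each
segment it forms the diagonal candidate from the previous column's H
(shifted one lane for segment 0, with the matrix-boundary H of 0 filled
in), takes the max with $E$, the running $F$ and 0, stores H, and updates
$E$ and the within-lane $F$ stream.  Because lanes hold consecutive query
runs, this propagates $F$ correctly *within* each lane; what it cannot see
is $F$ flowing across lane boundaries.  The lazy-F loop repairs exactly
that: the final $F$ vector is shifted one lane left and re-applied segment
by segment, wrapping around, until the lane vote

$$\text{continue} \iff \exists\, \text{lane}: F > H_{\text{stored}} - \rho$$

fails.  The rationale: a lane with $F > H$ must still raise H, and a lane
with $H - \rho < F \le H$ can still carry a dominating downstream value,
since $F - \sigma > H - \rho - \sigma$ means the decayed $F$ beats a gap
newly opened from the stored (already correct) H.  Once
$F \le H - \rho$ in every lane, each remaining contribution is dominated
by a gap opened from a correct H, so the stored H *and* E columns are
final.  Three further choices matter:

* **Seeding.**  Lane 0 of the $F$ stream is seeded with the exact
  first-row boundary value $\max(H_{0,j} - \rho - \sigma, F_{0,j} -
  \sigma) = -\sigma$ (or the partition carry, below); all other lanes and
  all lazy-shift fills use a "no path" sentinel far below any reachable
  score.  A zero fill would be safe for H (a non-positive $F$ can never
  raise a non-negative H) but would both inject phantom zero-score gap
  paths into the observable $F$ values and keep re-triggering the vote
  wherever $H < \rho$, preventing termination.  With the sentinel, the
  vote is triggered only by genuine gap paths, which decay by $\sigma \ge
  1$ per step, so the loop terminates — and the observed last-cell $F$ is
  exactly what the boundary carry needs.
* **E exactness.**  The E state is seeded at $-\sigma$ before the first
  column (the exact signed $E_{i,1}$), and the lazy loop re-establishes
  $E \ge H - \rho - \sigma$ whenever it raises an H.  De-striped H *and* E
  columns are then cell-for-cell identical to `swFull`'s signed tables —
  an invariant the acceptance tests check on over a thousand random
  columns.  No analogous guarantee holds for $F$, and none is asserted.
* **Forced full correction.**  For validation, the loop can be forced to
  run $T \cdot VL$ steps (after $VL$ wrap shifts every genuine lane value
  has drained), which provably subsumes the early exit; tests confirm the
  finalized columns are identical either way.

`processColumn` exposes a single column step on a `ColumnState` for
instrumentation; `stripedAlignmentColumns` returns de-striped columns for
oracle comparison.

# The partitioned engine and the boundary carry

`partitionQuery` cuts the query into partitions of exactly $PL$ residues
($PL$ a multiple of $VL$; the last partition dummy-padded) and builds one
striped profile of $T = PL/VL$ segments per partition.  Partitions are
processed outermost, subject columns innermost; between partitions two
subject-length arrays are carried:

* $H_{\text{last}}[j]$ — the (always correct) H of the partition's last
  row, consumed as the diagonal input of the next partition's first row at
  column $j + 1$;
* $F_{\text{first}}[j]$ — the F entering the next partition's first row at
  column $j$, computed by `carryBoundary` as
  $\max(H_{\text{last}} - \rho - \sigma,\; F_{\text{obs}} - \sigma)$,
  where $F_{\text{obs}}$ is whatever F the engine observed at the last
  cell.

Storing the *next* partition's first-cell F, rather than the raw last-cell
F, is what makes the carry exact even though the lazy-F loop guarantees
nothing about F.  When the loop ran to full correction, $F_{\text{obs}}$
is the true last-cell F and the formula is trivially exact.  When it
exited early, every dropped F satisfied $F \le H - \rho$ at the drop
point, so its decayed value is dominated by a gap opened from an H that is
known correct — recursively down to the last cell, whose own H-path term
$H_{\text{last}} - \rho - \sigma$ appears explicitly in the formula.  The
acceptance suite instruments both cases separately (requiring both to
occur) and checks the carried F against the true F from `swFull` at every
boundary column: agreement is 100%.  E needs no carry at all — it depends
only on cells in the same row — which the tests also verify by comparing
first-row E values across different $PL$ against the oracle.

Defaults are $PL = 256$, $VL = 16$, the tuned configuration of the
original GPU implementation; any valid combination gives the same score,
and partition-count invariance is tested explicitly.

# Database search and throughput

`searchDatabase` scores one query against every database record with the
selected engine, ranks by score with ties kept in database input order
(reproducibility), and reports the cell count
($l_1 \times \sum l_2$), the elapsed scoring time (file I/O excluded) and
GCUPS — billions of cell updates per second, the field's standard
throughput metric.  GCUPS is informational: it depends on the host and, in
this package, on an emulation whose purpose is value-faithfulness, not
speed.  It is never asserted in tests.  The original tool's two-stage
subject dispatch balanced GPU thread workloads and has no sequential
analogue; every subject is scored by the same engine here.

The `exec/swsearch` and `exec/swsearch-fixtures` scripts expose the search
and the generator on the command line as thin wrappers over the package
functions.

# The synthetic data generator

`randomProtein`, `mutateHomolog` and `generateDatabase` produce all test
inputs; nothing is downloaded.  Residues are drawn i.i.d. from a
composition table — uniform over the 20 standard amino acids by default
(no composition model is prescribed for the algorithmic properties under
test, all of which hold for every input), with a typical database
composition available for realism.  `mutateHomolog` applies independent
forced-different substitutions and geometric-length indels, leaving the
diagonal signal that makes search rankings non-trivial.  One explicit seed
threads through every generator, the caller's RNG state is saved and
restored, and identical specifications regenerate byte-identical FASTA
output.

What the generator does *not* emulate: domain architecture, repeats,
low-complexity regions, realistic length distributions or evolutionary
substitution processes.  Passing tests therefore demonstrate the engines'
*exactness* on arbitrary sequences — which is the claim under test, and
which holds for real data a fortiori — but say nothing about biological
sensitivity or about throughput on real hardware.

# Problem sizes and numerical choices

The validation suite uses: 500 randomized pairs of lengths 1–300 over both
matrices, penalties 10-2k/20-2k/40-3k, $VL \in \{1,2,3,4,7,8,16,32\}$ and
$PL \in \{VL, 4VL, 256\}$ for cross-engine equality; over 1000 random
columns for lazy-F column exactness and again for boundary-carry
exactness; an exhaustive $l \le 200 \times VL \le 64$ profile round-trip;
and one search of a 5478-residue query (the longest query length of the
original study) against a 50-record synthetic database of lengths 100–400
at the tuned defaults.  These sizes exercise every degenerate corner
(single-residue sequences, $VL = 1$, $VL > l$, single-segment partitions,
non-power-of-two lane counts) while keeping a full run to a few minutes on
one core.

Scores are 32-bit signed integers throughout; an overflow guard rejects
inputs whose best possible score could approach the representable range.
Empty sequences are rejected; empty FASTA records are dropped with a
warning.  Tie-breaks in rankings are stable.  The lazy-F "no path"
sentinel is $-2^{29}$, far enough below zero that per-column decay cannot
underflow.

# Limitations

* Scores only: no traceback, no alignment strings, no linear-space or
  banded variants.
* No statistical significance (E-values or Z-values); scores are biased by
  sequence length and composition, so cross-query comparisons need care.
* The lane machine reproduces values, not performance; GCUPS figures are
  orders of magnitude below hardware implementations and only meaningful
  relative to each other.
* Protein alphabets only; DNA match/mismatch scoring and position-specific
  matrices are out of scope.
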