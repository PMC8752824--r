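---
title: "Entropy-informed segmentation design and hotspot mapping for repeat proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-informed segmentation design and hotspot mapping for repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrmap)
```

## The problem

Leucine-rich repeat (LRR) receptors recognise their targets along an
extended, modularly composed surface, but most of them resist heterologous
expression, so the repeats that actually contact the ligand — the paratope —
are usually unknown. Ribosome display sidesteps the expression problem:
each sub-segment of the receptor is expressed cell-free, kept tethered to
its ribosome and mRNA, and panned against the immobilised target with and
without excess soluble target as competitor. The retained mRNA, quantified
by qPCR, measures binding; the *competable* part of that signal is the
specific part. Because the repeats are modular, the receptor can be cut at
repeat boundaries into testable windows, and binding localised to repeat
resolution.

`lrrmap` implements the desk side of this workflow: deciding *which*
windows to test, simulating the assay readout against a planted ground
truth so the whole loop can be exercised without wet-lab data, analysing
competed/uncompeted Cq tables, and turning per-construct statistics into
hotspot interval calls.

## The entropy model for window length

Consider a region of `L` units tiled by every contiguous window of length
`n` — there are `L - n + 1` of them. Unit `i` is contained in a fraction

$$P_i = \frac{\min(i,\; n,\; L - i + 1,\; L - n + 1)}{L - n + 1}$$

of the windows, and the information content of the whole experiment is
scored as

$$H(n) = -\sum_{i=1}^{L} P_i \log_2 P_i .$$

The $P_i$ are per-unit coverage fractions, not a normalised distribution
(they sum to $n$); the score is applied to them directly. $H$ is zero at
`n = L` (one window, no discrimination) and low at `n = 1` (each unit seen
once, but every window is an independent low-information experiment);
intermediate lengths maximise it.

```{r}
prof <- entropy_profile(11)
max_entropy_length(prof)
admissible_lengths(prof, tolerance = 0.9)
```

For an 11-unit region the maximum is at `n = 3`, and lengths 2–5 retain at
least 90% of the maximal entropy; for a 12-unit region the maximum is at
`n = 4` with lengths 3–5 admissible. The package defaults to the *largest*
admissible length rather than the argmax: longer windows keep each repeat
in a more native-like structural context and present more interfacial
area, at a small information cost that the tolerance bounds explicitly.
Ties in the argmax are broken towards the larger `n` for the same reason.
Threshold comparisons use a relative epsilon of 1e-9 so a length sitting
exactly on the tolerance boundary is never dropped by float rounding.

## Planning rounds

The first round is a coarse partition: `k` equal segments covering all
repeats, with the forced total overlap `k*s - R` spread as evenly as
possible over the junctions (larger overlaps at earlier junctions on
ties). A 31-repeat receptor with `k = 3`, `s = 13` gives segments 1–13,
10–22 and 19–31 with two 4-repeat overlaps. Overlap is deliberate: the
outermost repeats of a segment abut non-native cap interfaces and may
misfold, so evidence about them is weak.

That same distrust drives the pruning rule between rounds. A negative
window argues *against* its units — except its outermost `edge_margin`
units (default 2), where non-binding could equally be misfolding. Each
positive window is reduced by the trusted cores of all negative windows,
and the surviving units become candidate regions:

```{r}
prune_candidates(positives = data.frame(start = c(1, 19), end = c(13, 31)),
                 negatives = data.frame(start = 10, end = 22),
                 edge_margin = 2)
```

The default `edge_margin = 2` is the value that reconciles 4-repeat
segment overlaps with keeping repeats 10–11 (inside the negative middle
segment but within two units of its edge) while discarding repeats 12–13;
it is a reconstruction of the worked campaign's decisions, exposed as a
parameter rather than a constant. Inconclusive calls carry no evidence in
either direction — a weak signal cannot distinguish a non-binder from a
misfolded binder.

Refinement plans then tile each candidate region at stride 1 with the
selected `n`. A non-repeat loopout insertion is treated as one pseudo-unit
occupying one slot in the ordering, so a region of repeats 21–31 spanning
a loopout is a 12-unit design problem, and its `n = 5` round has 8
constructs ending with the loopout–31 window.

## The simulated readout

The simulator exists so the design→analyse→infer loop is testable end to
end; it makes no claim to mechanistic fidelity. A construct's specific
signal is `s = signal_scale * max_p overlap(w, p)/|p|` over planted
paratopes `p`, zeroed when the contiguous overlap is below `min_contig`
units (default 3 — a sliver of a paratope presents too little contact
area to bind detectably). The qPCR readout assumes perfect doubling:

```
bound_uncompeted = s + background
bound_competed   = leak * s + background
Cq = cq_baseline - log2(bound) + batch_offset + Normal(0, noise_sd)
```

so with no noise the paired difference is exactly
`dCq = log2((s + b) / (leak*s + b))`, zero iff `s = 0` and increasing in
`s`. Competition is a multiplicative survival fraction (`leak`, default
0.05) rather than mass-action titration: the assay's contract is presence
versus absence of competable signal, and this keeps the generator's
parameters identifiable at desk scale. Defaults — `noise_sd = 0.25`
cycles, `background = 0.05`, three replicates — are chosen to give a
realistic but not heroic signal-to-noise regime: a full-coverage binder
sits ~3.4 cycles above a non-binder, about ten replicate standard errors.
What the generator does *not* emulate: amplification-efficiency
variation, translation-efficiency differences between constructs,
ribosome-dependent misfolding of particular windows, or plate-position
effects. Passing recovery tests therefore show the inference logic is
sound under the stated noise model, not that any particular wet-lab
campaign would succeed.

## Analysing Cq tables

The analysis follows the assay's standard statistics, in order:

1. **Batch normalisation** — each batch (day) is shifted to the global
   average Cq. Within-batch differences are preserved exactly, so paired
   delta-Cq values are untouched while cross-batch means become
   comparable.
2. **Delta-Cq** — competed minus uncompeted, paired by
   `(replicate, batch)`; positive values mean specific, competable
   binding. The summary sd is propagated from the two conditions,
   `sqrt(sd_c^2 + sd_u^2)`.
3. **Tukey-fence outlier exclusion** — constructs whose propagated sd
   exceeds `Q3 + 1.5*IQR` of the round's sds are excluded. Only the high
   side is fenced (low variance is not a defect), and the conventional
   multiplier 1.5 is assumed. With fewer than four constructs quartiles
   are not meaningful and nothing is flagged.
4. **ANOVA + Tukey HSD** — single-factor ANOVA on the replicate-level
   delta-Cq values grouped by construct (replicate-level rather than
   summary-level: the only choice that makes the ANOVA well-posed),
   then all pairwise comparisons via the studentized range with the
   Tukey–Kramer adjustment for unequal group sizes, significant at
   `alpha = 0.1` by default. The all-identical degenerate case (zero
   variance everywhere) is reported as `NA` statistics with no
   significant pairs.

```{r}
p <- repeat_protein("demo", 31, loopout = list(after_repeat = 27))
truth <- ground_truth(data.frame(start = c(6, 22), end = c(10, 26)))
plan <- plan_refinement(p, list(start = 1, end = 11))
cq <- simulate_cq(plan, p, truth, sim_config(noise_sd = 0.25, seed = 7))
res <- delta_cq(normalize_batches(cq))
cmp <- compare_constructs(res, alpha = 0.1)
glance(cmp)
```

## Calling hotspots

A construct is *significant* when its mean delta-Cq is positive **and**
Tukey's HSD flags it as greater than at least one other construct in the
round. This mirrors reading the strongest windows against the round's own
background constructs, and stays well defined when the identity of the
non-binders is unknown; it degenerates gracefully (a configurable
delta-Cq floor) when a round tested a single construct. Support is then
counted per unit — how many significant constructs contain it — and
hotspots are maximal contiguous runs with support at least `min_support`
(default 1). Intervals can never extend past tested units. Each interval
is annotated with its best construct: largest mean delta-Cq, then
smallest span, then lowest start unit.

Resolution is the repeat unit, not the residue, and a stride-1 tiling at
support 1 widens each call by up to `n - min_contig` units on each side of
the true paratope; raising `min_support` trades sensitivity for sharper
intervals.

```{r}
sup <- unit_support(plan, res, cmp)
call_hotspots(sup)
```

## The packaged demonstration campaign

`run_demo()` replays the full loop on a 31-repeat receptor with a loopout
pseudo-unit between repeats 27 and 28 and planted paratopes at repeats
6–10 and 22–26: coarse 3×13 partition → simulate → verdict (mean delta-Cq
floor of 1 cycle) → prune to the 11-unit and 12-unit regions → `n = 5`
rounds of 7 and 8 constructs → statistics → two hotspot intervals. The
loopout's position is an assumption inferred from construct naming
conventions in the motivating campaign, recorded in the demo config, not
hard-coded.

```{r}
res <- run_demo(seed = 17)
res$hotspots
```

## Numerical and design choices

* Unit indexing is 1-based with inclusive windows, matching the field's
  "LRRs 6–10" naming.
* Sequences are optional everywhere except assembly/FASTA export, which
  fails with an error naming the first unit whose sequence is missing.
* Inclusion fractions are computed in closed form; the test suite checks
  them against a brute-force window-enumeration oracle for all `L <= 30`
  at 1e-12.
* All simulation is reproducible from a single integer seed; the
  pipeline derives per-round seeds as `seed + round index` and embeds the
  seed and a config hash in every artifact.
* Statistical engines are base R (`aov`, `TukeyHSD`, `quantile` type 7);
  the package owns only the assay-specific layers around them.
* Simulation sizes used by the test suite — 200 replicate campaigns for
  recovery and for the null false-positive rate — give Monte-Carlo
  standard errors near 2 percentage points on the reported rates, small
  against the 90% recovery and alpha-level margins being checked.

## Limitations

* The pruning rule and edge margin are a faithful reconstruction of a
  worked campaign, not a formalised algorithm from first principles;
  both are parameters.
* With one positive construct and no significant pairs (all constructs
  binding equally), the within-round contrast cannot fire; the delta-Cq
  floor is the fallback, and dense all-binder rounds will under-call.
* The entropy score treats constructs as independent experiments; it
  does not model correlated failure modes (e.g. a reagent batch).
* No amplification-efficiency correction, standard curves, or multi-gene
  normalisation — the assay this models uses none.
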