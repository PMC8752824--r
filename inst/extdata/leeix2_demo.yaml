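# Demonstration campaign: a 31-repeat LRR receptor modelled on the LeEIX2
# ectodomain architecture (31 LRRs, N/C caps, one loopout insertion).
# The loopout position between repeats 27 and 28 is an assumption inferred
# from construct naming in the motivating study, not a stated coordinate;
# it is a config field, not a package constant.
# The planted paratopes are synthetic ground truth for the simulator.
protein:
  name: LeEIX2-demo
  n_repeats: 31
  loopout:
    after_repeat: 27

design:
  tolerance: 0.9        # entropy tolerance (fraction of maximal entropy)
  overlap: 4            # repeats shared between neighbouring coarse segments
  segments: 3
  segment_length: 13
  edge_margin: 2        # distrusted repeats at each end of a negative window
  selection_rule: largest
  call_floor: 1.0       # cycles of mean delta-Cq for a positive round-1 call

truth:
  paratopes:
    - { start: 6, end: 10 }
    - { start: 22, end: 26 }
  min_contig: 3
  signal_scale: 1.0
  leak: 0.05
  background: 0.05

simulator:
  noise_sd: 0.25        # cycles
  cq_baseline: 20
  batch_offsets: [0.0]
  n_replicates: 3
  seed: 17

stats:
  alpha: 0.1
  outlier_k: 1.5
  min_support: 1
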