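# Example run configuration: the emulated study design at desk scale.
# Defaults not listed here follow run_config(): 203 participants with a
# 118:85 right:left lesion split, 2227 normative assessments from 799
# controls, impairment cut 1.96, FDR 5%, inclusion bound 25, 4000
# permutations, TFCE E = 0.5 / H = 2.
seed: 1
n_tracts: 6
n_controls: 10
n_stroke: 60          # reduce for a quick demonstration run
n_norm_controls: 120
n_norm_assessments: 160
n_perm: 500
inclusion_min_n: 5    # scaled with the smaller cohort
truth:
  causal_tracts:
    tract1: 0.5
  side_effect: 0.3
  gm_effect: 0.2
  noise_sd: 1
  intercept: 0.8
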