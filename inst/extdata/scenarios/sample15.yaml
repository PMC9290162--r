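# Clonal structure with a nested double mutant: K247R occurs only on the
# T315I background (VAFs: L273M 58.1%, T315I 41.7%, K247R 2.8%).
isoform_id: e14a2
n_reads: 10000
clones:
  - mutations: [L273M]
    fraction: 0.581
  - mutations: [T315I]
    fraction: 0.389
  - mutations: [T315I, K247R]
    fraction: 0.028
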