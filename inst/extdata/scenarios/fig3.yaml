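# Canonical phasing scenario: L273M and T315I in distinct molecules,
# K247R only ever together with T315I.
isoform_id: e14a2
n_reads: 10000
clones:
  - mutations: [L273M]
    fraction: 0.56
  - mutations: [T315I]
    fraction: 0.41
  - mutations: [T315I, K247R]
    fraction: 0.03
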