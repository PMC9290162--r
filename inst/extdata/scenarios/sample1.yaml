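# Multi-clone scenario shaped like validation sample 1: a dominant T315I
# clone with two minor subclones each adding a second mutation on the
# T315I background (VAFs: T315I 96.8%, F359C 2.1%, H396R 1.2%).
isoform_id: e14a2
n_reads: 10000
clones:
  - mutations: [T315I]
    fraction: 0.935
  - mutations: [T315I, F359C]
    fraction: 0.021
  - mutations: [T315I, H396R]
    fraction: 0.012
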