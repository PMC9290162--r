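# Five mutually exclusive clones (VAFs: T315I 45.7%, F359I 23.9%,
# E255K 12.5%, H396R 12.4%, F359V 4.8%).
isoform_id: e14a2
n_reads: 10000
clones:
  - mutations: [T315I]
    fraction: 0.457
  - mutations: [F359I]
    fraction: 0.239
  - mutations: [E255K]
    fraction: 0.125
  - mutations: [H396R]
    fraction: 0.124
  - mutations: [F359V]
    fraction: 0.048
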