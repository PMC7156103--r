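# Synthetic example: one trio over the four samples of the bundled
# simulated dataset (inst/extdata/synthetic_trio.vcf), which was generated
# by simulateDataset() with gamma = 0.8, direction P2 -> P3.
trios:
  - name: fwd
    p1: P1
    p2: P2
    p3: P3
    outgroup: O
    hypothesis: geographic
    expected_sign: 1
    mating_systems: [SI, SC, SC]
accessions:
  - id: P1
    lat: -12.0
    lon: -76.5
    species: sp1
    mating_system: SI
  - id: P2
    lat: -13.2
    lon: -72.4
    species: sp1
    mating_system: SC
  - id: P3
    lat: -13.5
    lon: -72.0
    species: sp2
    mating_system: SC
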