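# Curated transmembrane segment annotation for the four receptor structures
# used in the chimera-compatibility benchmark. These residue ranges are
# CURATION, not computation: GPCRdb-style segment boundaries transcribed from
# the literature for bovine Rhodopsin (1U19 inactive, 3PQR active) and
# Smoothened (4JKV human inactive, 6D32 Xenopus active). Chain and
# fusion-construct exclusions for the crystallized constructs are recorded
# per structure. Ranges are approximate at the 1-2 residue level; the
# downstream superposition uses trim-mode pairing, which absorbs small
# boundary differences.
1u19:
  chain: A
  exclusions: []
  segments:
    TM1: [34, 64]
    TM2: [71, 100]
    TM3: [106, 139]
    TM4: [150, 173]
    TM5: [200, 230]
    TM6: [246, 277]
    TM7: [285, 309]
    H8: [311, 321]
3pqr:
  chain: A
  exclusions: []
  segments:
    TM1: [34, 64]
    TM2: [71, 100]
    TM3: [106, 139]
    TM4: [150, 173]
    TM5: [200, 230]
    TM6: [246, 277]
    TM7: [285, 309]
    H8: [311, 321]
4jkv:
  chain: A
  # BRIL fusion replaces ICL3 in the crystallization construct
  exclusions: [[1001, 1106]]
  segments:
    TM1: [222, 249]
    TM2: [256, 284]
    TM3: [290, 323]
    TM4: [332, 356]
    TM5: [379, 407]
    TM6: [416, 446]
    TM7: [451, 477]
    H8: [480, 491]
6d32:
  chain: A
  exclusions: []
  segments:
    TM1: [221, 248]
    TM2: [255, 283]
    TM3: [289, 322]
    TM4: [331, 355]
    TM5: [378, 406]
    TM6: [415, 445]
    TM7: [450, 476]
    H8: [479, 490]
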