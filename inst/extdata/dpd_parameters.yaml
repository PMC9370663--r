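schema: dpdcnt-parameters/1
interaction:
  rC: 1.0
  kBT: 1.0
  gamma: 4.5
  sigma: 3.0
  bead_order:
  - h1
  - h2
  - h3
  - t
  - w
  - cnt
  a:
    h1:
      h1: 110.0
      h2: 100.0
      h3: 102.0
      t: 130.0
      w: 98.0
      cnt: 130.0
    h2:
      h1: 100.0
      h2: 110.0
      h3: 102.0
      t: 130.0
      w: 98.0
      cnt: 130.0
    h3:
      h1: 102.0
      h2: 102.0
      h3: 100.0
      t: 110.0
      w: 102.0
      cnt: 110.0
    t:
      h1: 130.0
      h2: 130.0
      h3: 110.0
      t: 100.0
      w: 130.0
      cnt: 100.0
    w:
      h1: 98.0
      h2: 98.0
      h3: 102.0
      t: 130.0
      w: 100.0
      cnt: 130.0
    cnt:
      h1: 130.0
      h2: 130.0
      h3: 110.0
      t: 100.0
      w: 130.0
      cnt: 100.0
bonds:
- type_i: h1
  type_j: h2
  k_bond: 512.0
  r0: 0.47
- type_i: h2
  type_j: h3
  k_bond: 512.0
  r0: 0.47
- type_i: h3
  type_j: h3
  k_bond: 512.0
  r0: 0.31
- type_i: h3
  type_j: t
  k_bond: 512.0
  r0: 0.59
- type_i: t
  type_j: t
  k_bond: 512.0
  r0: 0.59
angles:
- type_i: h2
  type_j: h3
  type_k: h3
  k_angle: 6.0
  theta0: 120.0
- type_i: h2
  type_j: h3
  type_k: t
  k_angle: 6.0
  theta0: 180.0
- type_i: h3
  type_j: t
  type_k: t
  k_angle: 6.0
  theta0: 180.0
- type_i: t
  type_j: t
  type_k: t
  k_angle: 6.0
  theta0: 180.0
units:
  rC_nm: 0.7113787
  beads_per_rC3: 3.0
  water_bead_volume_nm3: 0.12
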