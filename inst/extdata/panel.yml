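transitions:
- analyte: D9-THC
  role: quantifier
  channel: 315.22>123.04
  precursor_mz: 315.22
  product_mz: 123.04
  rt: 3.6
  cone_v: 42.0
  collision_ev: 32.0
- analyte: D9-THC
  role: qualifier
  channel: 315.22>193.12
  precursor_mz: 315.22
  product_mz: 193.12
  rt: 3.6
  cone_v: 42.0
  collision_ev: 22.0
- analyte: 9R-HHC
  role: quantifier
  channel: 317.25>123.04
  precursor_mz: 317.25
  product_mz: 123.04
  rt: 4.08
  cone_v: 20.0
  collision_ev: 40.0
- analyte: 9R-HHC
  role: qualifier
  channel: 317.25>193.12
  precursor_mz: 317.25
  product_mz: 193.12
  rt: 4.08
  cone_v: 20.0
  collision_ev: 20.0
- analyte: 9S-HHC
  role: quantifier
  channel: 317.25>123.04
  precursor_mz: 317.25
  product_mz: 123.04
  rt: 4.0
  cone_v: 20.0
  collision_ev: 40.0
- analyte: 9S-HHC
  role: qualifier
  channel: 317.25>193.12
  precursor_mz: 317.25
  product_mz: 193.12
  rt: 4.0
  cone_v: 20.0
  collision_ev: 20.0
- analyte: 9R-11-OH-HHC
  role: quantifier
  channel: 333.24>123.04
  precursor_mz: 333.24
  product_mz: 123.04
  rt: 1.86
  cone_v: 20.0
  collision_ev: 35.0
- analyte: 9R-11-OH-HHC
  role: qualifier
  channel: 333.24>193.12
  precursor_mz: 333.24
  product_mz: 193.12
  rt: 1.86
  cone_v: 20.0
  collision_ev: 25.0
- analyte: 9S-11-OH-HHC
  role: quantifier
  channel: 333.24>123.04
  precursor_mz: 333.24
  product_mz: 123.04
  rt: 1.91
  cone_v: 20.0
  collision_ev: 35.0
- analyte: 9S-11-OH-HHC
  role: qualifier
  channel: 333.24>193.12
  precursor_mz: 333.24
  product_mz: 193.12
  rt: 1.91
  cone_v: 20.0
  collision_ev: 25.0
- analyte: 9R-HHC-COOH
  role: quantifier
  channel: 347.22>123.04
  precursor_mz: 347.22
  product_mz: 123.04
  rt: 1.8
  cone_v: 20.0
  collision_ev: 35.0
- analyte: 9R-HHC-COOH
  role: qualifier
  channel: 347.22>193.12
  precursor_mz: 347.22
  product_mz: 193.12
  rt: 1.8
  cone_v: 20.0
  collision_ev: 25.0
- analyte: 9S-HHC-COOH
  role: quantifier
  channel: 347.22>123.04
  precursor_mz: 347.22
  product_mz: 123.04
  rt: 1.97
  cone_v: 20.0
  collision_ev: 35.0
- analyte: 9S-HHC-COOH
  role: qualifier
  channel: 347.22>193.12
  precursor_mz: 347.22
  product_mz: 193.12
  rt: 1.97
  cone_v: 20.0
  collision_ev: 25.0
- analyte: 11-OH-THC
  role: quantifier
  channel: 331.22>201.20
  precursor_mz: 331.22
  product_mz: 201.2
  rt: 1.71
  cone_v: 20.0
  collision_ev: 25.0
- analyte: 11-OH-THC
  role: qualifier
  channel: 331.22>193.12
  precursor_mz: 331.22
  product_mz: 193.12
  rt: 1.71
  cone_v: 20.0
  collision_ev: 29.0
- analyte: THC-COOH
  role: quantifier
  channel: 345.20>299.20
  precursor_mz: 345.2
  product_mz: 299.2
  rt: 1.9
  cone_v: 42.0
  collision_ev: 20.0
- analyte: THC-COOH
  role: qualifier
  channel: 345.20>193.12
  precursor_mz: 345.2
  product_mz: 193.12
  rt: 1.9
  cone_v: 42.0
  collision_ev: 26.0
- analyte: D8-THC
  role: quantifier
  channel: 315.22>123.04
  precursor_mz: 315.22
  product_mz: 123.04
  rt: 3.4
  cone_v: 42.0
  collision_ev: 32.0
- analyte: D8-THC
  role: qualifier
  channel: 315.22>193.12
  precursor_mz: 315.22
  product_mz: 193.12
  rt: 3.4
  cone_v: 42.0
  collision_ev: 22.0
- analyte: D9-THC-d3
  role: IS
  channel: 318.22>196.12
  precursor_mz: 318.22
  product_mz: 196.12
  rt: 3.58
  cone_v: 42.0
  collision_ev: 22.0
- analyte: 11-OH-THC-d3
  role: IS
  channel: 334.27>196.23
  precursor_mz: 334.27
  product_mz: 196.23
  rt: 1.89
  cone_v: 20.0
  collision_ev: 29.0
- analyte: THC-COOH-d3
  role: IS
  channel: 348.20>196.12
  precursor_mz: 348.2
  product_mz: 196.12
  rt: 1.7
  cone_v: 34.0
  collision_ev: 20.0
analytes:
- analyte: D9-THC
  area_cutoff: 1000.0
  is_id: D9-THC-d3
  lloq: 0.53
- analyte: 9R-HHC
  area_cutoff: 2000.0
  is_id: D9-THC-d3
  lloq: 0.53
  surrogate: D9-THC
- analyte: 9S-HHC
  area_cutoff: 2000.0
  is_id: D9-THC-d3
  lloq: 0.53
  surrogate: D9-THC
- analyte: 9R-11-OH-HHC
  area_cutoff: 2000.0
  is_id: 11-OH-THC-d3
  lloq: 0.53
  surrogate: 11-OH-THC
- analyte: 9S-11-OH-HHC
  area_cutoff: 2000.0
  is_id: 11-OH-THC-d3
  lloq: 0.53
  surrogate: 11-OH-THC
- analyte: 9R-HHC-COOH
  area_cutoff: 1000.0
  is_id: THC-COOH-d3
  lloq: 1.06
  surrogate: THC-COOH
- analyte: 9S-HHC-COOH
  area_cutoff: 1000.0
  is_id: THC-COOH-d3
  lloq: 1.06
  surrogate: THC-COOH
- analyte: 11-OH-THC
  area_cutoff: 1000.0
  is_id: 11-OH-THC-d3
  lloq: 0.53
- analyte: THC-COOH
  area_cutoff: 1000.0
  is_id: THC-COOH-d3
  lloq: 1.06
- analyte: D8-THC
  area_cutoff: 1000.0
  is_id: D9-THC-d3
rt_tol: 0.02
ratio_tol: 0.2
cal_levels:
- 0.53
- 1.325
- 5.3
- 13.25
- 26.5
- 53.0
run_length: 6.8
points_per_min: 100.0
search_factor: 3.0
fragment_carbons:
  '193.12': 14.0
  '123.04': 8.0
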