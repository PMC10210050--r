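# Reference configuration: every tunable parameter with its default.
# Unknown keys are rejected by load_config().

regions:
  # Universal-region boundaries in reference coordinates (1-based,
  # inclusive). Editable: block boundaries depend on the alignment; these
  # bracket the classical primer sites in U2 (533-552) and U6 (1505-1524).
  map:
    - {region: U1, start: 80,   end: 140}
    - {region: U2, start: 480,  end: 560}
    - {region: U3, start: 668,  end: 775}
    - {region: U4, start: 942,  end: 980}
    - {region: U5, start: 1040, end: 1270}
    - {region: U6, start: 1505, end: 1560}
    - {region: U7, start: 1700, end: 1760}
    - {region: U8, start: 1880, end: 1940}
  # "nongap": per-group totals count columns with >= 1 non-gap base
  total_mode: nongap

thermo:
  method: nearest_neighbor
  nn_set: breslauer1986     # or santalucia1998
  na_mM: 50                 # monovalent cation concentration
  primer_nM: 250            # total primer concentration

design:
  primer_len_min: 18
  primer_len_max: 22
  tm_min: 48
  tm_max: 62
  max_degeneracy: 16
  max_gc3_run: 3
  min_discrimination: 1
  w3p: 5                    # 3'-terminal positions with extra weight
  omega: 4                  # weight multiplier for those positions
  min_gapfree_frac: 1.0
  locus_tag: mt-SSU
  amplicon_min: 200
  amplicon_max: 2500
  max_delta_tm: 5

pcr:
  max_mismatch: 3
  protected_3prime: 2
  min_len: 200
  max_len: 2500
  ambig_template: intersect # or strict

fixtures:
  seed: 1
  n_target: 10
  n_offtarget: 6
  within_divergence: 0.02
  offtarget_divergence: 0.05
  planted_divergence: 0.45
  indel_prob: 0.5
  max_indel_frac: 0.3
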