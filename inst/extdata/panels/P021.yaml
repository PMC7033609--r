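name: P021
version: '1.0'
region_order:
- RAD17
- SERF1B
- SMN12_e1
- SMN12_e4
- SMN12_e6
- SMN1_e7
- SMN1_e8
- SMN2_e7
- SMN2_e8
- NAIP_e5
- NAIPc_e13
- GTF2H2_e5
probes:
- probe_id: QFRAG_1_p1
  region: QFRAG_1
  category: dq_control
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: QFRAG_1_p2
  region: QFRAG_1
  category: dq_control
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: QFRAG_2_p1
  region: QFRAG_2
  category: dq_control
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: QFRAG_3_p1
  region: QFRAG_3
  category: dq_control
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: QFRAG_4_p1
  region: QFRAG_4
  category: dq_control
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: DFRAG_1_p1
  region: DFRAG_1
  category: dq_control
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: DFRAG_2_p1
  region: DFRAG_2
  category: dq_control
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: SEX_X_p1
  region: SEX_X
  category: sex
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: SEX_Y_p1
  region: SEX_Y
  category: sex
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_01_p1
  region: REF_01
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_02_p1
  region: REF_02
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_03_p1
  region: REF_03
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_04_p1
  region: REF_04
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_05_p1
  region: REF_05
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_06_p1
  region: REF_06
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_07_p1
  region: REF_07
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_08_p1
  region: REF_08
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_09_p1
  region: REF_09
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_10_p1
  region: REF_10
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_11_p1
  region: REF_11
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_12_p1
  region: REF_12
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_13_p1
  region: REF_13
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_14_p1
  region: REF_14
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_15_p1
  region: REF_15
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_16_p1
  region: REF_16
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_17_p1
  region: REF_17
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_18_p1
  region: REF_18
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_19_p1
  region: REF_19
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_20_p1
  region: REF_20
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_21_p1
  region: REF_21
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: REF_22_p1
  region: REF_22
  category: reference
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: SMN1_e7_p1
  region: SMN1_e7
  category: smn_target
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: SMN1_e8_p1
  region: SMN1_e8
  category: smn_target
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: SMN2_e7_p1
  region: SMN2_e7
  category: smn_target
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: SMN2_e8_p1
  region: SMN2_e8
  category: smn_target
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: SMN12_e1_p1
  region: SMN12_e1
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: SMN12_e1_p2
  region: SMN12_e1
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: SMN12_e4_p1
  region: SMN12_e4
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: SMN12_e6_p1
  region: SMN12_e6
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: NAIP_e5_p1
  region: NAIP_e5
  category: smn_target
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: NAIPc_e13_p1
  region: NAIPc_e13
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: NAIPc_e13_p2
  region: NAIPc_e13
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: GTF2H2_e5_p1
  region: GTF2H2_e5
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: GTF2H2_e5_p2
  region: GTF2H2_e5
  category: smn_target
  specificity: combined
  expected_diploid_copies: 4
- probe_id: SERF1B_p1
  region: SERF1B
  category: smn_target
  specificity: gene_specific
  expected_diploid_copies: 2
- probe_id: RAD17_p1
  region: RAD17
  category: smn_target
  specificity: gene_specific
  expected_diploid_copies: 2
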