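# Region composition of the 1x1 mm^2 multi-region rodent brain model
# (cortex M1/S1, thalamus VL/VM, basal ganglia, two cerebellar modules).
#
# Region totals, layer counts and neuron-type counts reproduce the published
# summary exactly. The per-population breakdown below region level is NOT
# published; it is a synthetic elaboration packaged with this library,
# constrained to (a) sum to the regional totals, (b) keep a 4:1
# excitatory:inhibitory ratio in every cortical layer except L1, and
# (c) use plausible relative abundances. "count" is per sheet; "sheets"
# multiplies it. Cortical type labels are layer-qualified; thalamic zones
# share their three type labels.
meta:
  extent_mm: 1.0
  notes: synthetic per-population elaboration; regional sums are exact
regions:
  M1:
    kind: cortex
    populations:
      - {layer: L1,   type: L1_SBC,    count: 402,   ei: I}
      - {layer: L1,   type: L1_ENGC,   count: 603,   ei: I}
      - {layer: L2/3, type: L23_IT,    count: 14080, ei: E}
      - {layer: L2/3, type: L23_PV,    count: 2112,  ei: I}
      - {layer: L2/3, type: L23_SST,   count: 1056,  ei: I}
      - {layer: L2/3, type: L23_VIP,   count: 352,   ei: I}
      - {layer: L5A,  type: L5A_IT,    count: 6720,  ei: E}
      - {layer: L5A,  type: L5A_PT,    count: 2240,  ei: E}
      - {layer: L5A,  type: L5A_PV,    count: 1568,  ei: I}
      - {layer: L5A,  type: L5A_SST,   count: 672,   ei: I}
      - {layer: L5B,  type: L5B_IT,    count: 6400,  ei: E}
      - {layer: L5B,  type: L5B_PT,    count: 6400,  ei: E}
      - {layer: L5B,  type: L5B_PV,    count: 2240,  ei: I}
      - {layer: L5B,  type: L5B_SST,   count: 960,   ei: I}
      - {layer: L6,   type: L6_IT,     count: 7800,  ei: E}
      - {layer: L6,   type: L6_CT,     count: 2600,  ei: E}
      - {layer: L6,   type: L6_PV,     count: 1300,  ei: I}
      - {layer: L6,   type: L6_SST,    count: 910,   ei: I}
      - {layer: L6,   type: L6_VIP,    count: 390,   ei: I}
  S1:
    kind: cortex
    populations:
      - {layer: L1,  type: L1_SBC,   count: 558,   ei: I}
      - {layer: L1,  type: L1_ENGC,  count: 838,   ei: I}
      - {layer: L2,  type: L2_IT,    count: 12800, ei: E}
      - {layer: L2,  type: L2_PV,    count: 1920,  ei: I}
      - {layer: L2,  type: L2_SST,   count: 1280,  ei: I}
      - {layer: L3,  type: L3_IT,    count: 12800, ei: E}
      - {layer: L3,  type: L3_PV,    count: 1920,  ei: I}
      - {layer: L3,  type: L3_SST,   count: 1280,  ei: I}
      - {layer: L4,  type: L4_SSC,   count: 18400, ei: E}
      - {layer: L4,  type: L4_PV,    count: 2760,  ei: I}
      - {layer: L4,  type: L4_SST,   count: 1840,  ei: I}
      - {layer: L5A, type: L5A_IT,   count: 8000,  ei: E}
      - {layer: L5A, type: L5A_PV,   count: 1200,  ei: I}
      - {layer: L5A, type: L5A_SST,  count: 800,   ei: I}
      - {layer: L5B, type: L5B_IT,   count: 6000,  ei: E}
      - {layer: L5B, type: L5B_PT,   count: 6000,  ei: E}
      - {layer: L5B, type: L5B_PV,   count: 1800,  ei: I}
      - {layer: L5B, type: L5B_SST,  count: 1200,  ei: I}
      - {layer: L6,  type: L6_IT,    count: 7800,  ei: E}
      - {layer: L6,  type: L6_CT,    count: 2600,  ei: E}
      - {layer: L6,  type: L6_PV,    count: 1560,  ei: I}
      - {layer: L6,  type: L6_SST,   count: 1040,  ei: I}
  VL:
    kind: thalamus
    populations:
      - {layer: zone_exc, type: TC,  count: 1024, ei: E}
      - {layer: zone_exc, type: IN,  count: 1024, ei: I}
      - {layer: zone_exc, type: RTN, count: 1024, ei: I}
      - {layer: zone_inh, type: TC,  count: 1024, ei: E}
      - {layer: zone_inh, type: IN,  count: 1024, ei: I}
      - {layer: zone_inh, type: RTN, count: 1024, ei: I}
  VM:
    kind: thalamus
    populations:
      - {layer: zone_exc, type: TC,  count: 1024, ei: E}
      - {layer: zone_exc, type: IN,  count: 1024, ei: I}
      - {layer: zone_exc, type: RTN, count: 1024, ei: I}
      - {layer: zone_inh, type: TC,  count: 1024, ei: E}
      - {layer: zone_inh, type: IN,  count: 1024, ei: I}
      - {layer: zone_inh, type: RTN, count: 1024, ei: I}
  BG:
    kind: basal_ganglia
    populations:
      - {layer: StrD1,    type: MSN_D1,  count: 4851, ei: I}
      - {layer: StrD2,    type: MSN_D2,  count: 4851, ei: I}
      - {layer: GPe,      type: GPe,     count: 460,  ei: I}
      - {layer: GPi_SNr,  type: GPi_SNr, count: 414,  ei: I}
      - {layer: STN,      type: STN,     count: 400,  ei: E}
  CB_M1:
    kind: cerebellum
    populations:
      - {layer: molecular_upper, type: MLI, count: 4608,  ei: I, sheets: 4}
      - {layer: molecular_lower, type: MLI, count: 4608,  ei: I}
      - {layer: purkinje,        type: PC,  count: 1152,  ei: I}
      - {layer: granular,        type: GrC, count: 45000, ei: E, sheets: 8}
      - {layer: granular,        type: GoC, count: 1024,  ei: I}
      - {layer: dcn,             type: DCN, count: 768,   ei: E}
      - {layer: pons,            type: MF,  count: 28736, ei: E, model: parrot}
  CB_S1:
    kind: cerebellum
    populations:
      - {layer: molecular_upper, type: MLI, count: 4608,  ei: I, sheets: 4}
      - {layer: molecular_lower, type: MLI, count: 4608,  ei: I}
      - {layer: purkinje,        type: PC,  count: 1152,  ei: I}
      - {layer: granular,        type: GrC, count: 45000, ei: E, sheets: 8}
      - {layer: granular,        type: GoC, count: 1024,  ei: I}
      - {layer: dcn,             type: DCN, count: 768,   ei: E}
      - {layer: pons,            type: MF,  count: 28736, ei: E, model: parrot}
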