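# Pathway parameters of the multi-region model: 2D Gaussian in-plane
# kernels (p0, sigma in mm), synaptic weights (nS at conductance peak),
# delays (ms) and receptor classes, plus per-population bias-current
# moments (pA). None of these values are published for the reference
# model; this file is the packaged synthetic default set, tuned only for
# stable desk-scale resting activity. Slow excitation maps onto the NMDA
# channel and slow inhibition onto GABA_B.
#
# Selectors: a pathway end is {region, layer, type, ei}; omitted fields
# match anything; "|" separates alternatives. Inter-regional pathways are
# topographic (positions carry over); `relay: true` inserts a parrot
# interface sheet mirroring the source population.
intra:
  # --- cortex (applied to M1 and S1 alike) -------------------------------
  - {region: M1|S1, pre: {ei: E}, post: {ei: E}, same_layer: true,
     p0: 0.10, sigma: 0.15, weight: 0.6, receptor: AMPA, delay: 1.0}
  - {region: M1|S1, pre: {ei: E}, post: {ei: I}, same_layer: true,
     p0: 0.20, sigma: 0.15, weight: 0.9, receptor: AMPA, delay: 1.0}
  - {region: M1|S1, pre: {ei: I}, post: {ei: E}, same_layer: true,
     p0: 0.25, sigma: 0.10, weight: 1.5, receptor: GABA_A, delay: 1.0}
  - {region: M1|S1, pre: {ei: I}, post: {ei: I}, same_layer: true,
     p0: 0.20, sigma: 0.10, weight: 1.2, receptor: GABA_A, delay: 1.0}
  # --- basal ganglia -----------------------------------------------------
  - {region: BG, pre: {layer: StrD1}, post: {layer: GPi_SNr},
     p0: 0.30, sigma: 0.20, weight: 1.5, receptor: GABA_A, delay: 1.5}
  - {region: BG, pre: {layer: StrD2}, post: {layer: GPe},
     p0: 0.30, sigma: 0.20, weight: 1.5, receptor: GABA_A, delay: 1.5}
  - {region: BG, pre: {layer: GPe}, post: {layer: STN},
     p0: 0.30, sigma: 0.20, weight: 1.2, receptor: GABA_A, delay: 1.0}
  - {region: BG, pre: {layer: GPe}, post: {layer: GPi_SNr},
     p0: 0.25, sigma: 0.20, weight: 1.0, receptor: GABA_A, delay: 1.0}
  - {region: BG, pre: {layer: STN}, post: {layer: GPi_SNr},
     p0: 0.30, sigma: 0.25, weight: 0.8, receptor: AMPA, delay: 1.0}
  - {region: BG, pre: {layer: STN}, post: {layer: GPe},
     p0: 0.30, sigma: 0.25, weight: 0.8, receptor: AMPA, delay: 1.0}
  # --- thalamus (no TC->TC recurrence) -----------------------------------
  - {region: VL|VM, pre: {type: TC}, post: {type: RTN}, same_layer: true,
     p0: 0.20, sigma: 0.15, weight: 0.8, receptor: AMPA, delay: 1.0}
  - {region: VL|VM, pre: {type: RTN}, post: {type: TC}, same_layer: true,
     p0: 0.25, sigma: 0.15, weight: 1.2, receptor: GABA_A, delay: 1.0}
  - {region: VL|VM, pre: {type: IN}, post: {type: TC}, same_layer: true,
     p0: 0.20, sigma: 0.10, weight: 1.0, receptor: GABA_A, delay: 1.0}
  # --- cerebellum --------------------------------------------------------
  - {region: CB_M1|CB_S1, pre: {type: MF}, post: {type: GrC},
     p0: 0.40, sigma: 0.10, weight: 2.0, receptor: AMPA, delay: 1.0}
  - {region: CB_M1|CB_S1, pre: {type: MF}, post: {type: DCN},
     p0: 0.30, sigma: 0.20, weight: 1.0, receptor: AMPA, delay: 1.0}
  - {region: CB_M1|CB_S1, pre: {type: GrC}, post: {type: GoC},
     p0: 0.05, sigma: 0.15, weight: 0.3, receptor: AMPA, delay: 1.0}
  - {region: CB_M1|CB_S1, pre: {type: GoC}, post: {type: GrC},
     p0: 0.30, sigma: 0.10, weight: 1.0, receptor: GABA_A, delay: 1.0}
  - {region: CB_M1|CB_S1, pre: {type: GrC}, post: {type: PC},
     p0: 0.30, sigma: 0.20, weight: 0.10, receptor: AMPA, delay: 1.0}
  - {region: CB_M1|CB_S1, pre: {type: GrC}, post: {type: MLI},
     p0: 0.10, sigma: 0.15, weight: 0.25, receptor: AMPA, delay: 1.0}
  - {region: CB_M1|CB_S1, pre: {type: MLI}, post: {type: PC},
     p0: 0.40, sigma: 0.10, weight: 1.2, receptor: GABA_A, delay: 1.0}
  - {region: CB_M1|CB_S1, pre: {type: PC}, post: {type: DCN},
     p0: 0.50, sigma: 0.20, weight: 2.0, receptor: GABA_A, delay: 1.0}
inter:
  - {pathway: M1_L5A_to_BG_striatum, pre: {region: M1, layer: L5A, ei: E},
     post: {region: BG, layer: StrD1|StrD2}, relay: true,
     p0: 0.20, sigma: 0.15, weight: 0.8, receptor: AMPA, delay: 1.5}
  - {pathway: S1_L5A_to_BG_striatum, pre: {region: S1, layer: L5A, ei: E},
     post: {region: BG, layer: StrD1|StrD2}, relay: true,
     p0: 0.20, sigma: 0.15, weight: 0.8, receptor: AMPA, delay: 1.5}
  - {pathway: BG_GPiSNr_to_TH, pre: {region: BG, layer: GPi_SNr},
     post: {region: VL|VM, type: TC}, relay: true,
     p0: 0.30, sigma: 0.15, weight: 1.2, receptor: GABA_A, delay: 1.5}
  - {pathway: M1_L5B_to_CB_pons, pre: {region: M1, layer: L5B, ei: E},
     post: {region: CB_M1, type: MF}, relay: false,
     p0: 0.20, sigma: 0.15, weight: 1.0, receptor: AMPA, delay: 1.5}
  - {pathway: S1_L5B_to_CB_pons, pre: {region: S1, layer: L5B, ei: E},
     post: {region: CB_S1, type: MF}, relay: false,
     p0: 0.20, sigma: 0.15, weight: 1.0, receptor: AMPA, delay: 1.5}
  - {pathway: CB_DCN_to_TH, pre: {region: CB_M1, type: DCN},
     post: {region: VL, type: TC}, relay: true,
     p0: 0.30, sigma: 0.15, weight: 0.8, receptor: AMPA, delay: 1.5}
  - {pathway: CB_DCN_to_TH, pre: {region: CB_S1, type: DCN},
     post: {region: VM, type: TC}, relay: true,
     p0: 0.30, sigma: 0.15, weight: 0.8, receptor: AMPA, delay: 1.5}
  - {pathway: M1_L6_to_TH, pre: {region: M1, layer: L6, ei: E},
     post: {region: VL, type: TC}, relay: true,
     p0: 0.15, sigma: 0.15, weight: 0.5, receptor: NMDA, delay: 1.5}
  - {pathway: S1_L6_to_TH, pre: {region: S1, layer: L6, ei: E},
     post: {region: VM, type: TC}, relay: true,
     p0: 0.15, sigma: 0.15, weight: 0.5, receptor: NMDA, delay: 1.5}
  - {pathway: TH_to_M1_L23, pre: {region: VL, type: TC},
     post: {region: M1, layer: L2/3}, relay: true,
     p0: 0.20, sigma: 0.15, weight: 0.8, receptor: AMPA, delay: 1.5}
  - {pathway: TH_to_S1_L4, pre: {region: VM, type: TC},
     post: {region: S1, layer: L4}, relay: true,
     p0: 0.20, sigma: 0.15, weight: 0.8, receptor: AMPA, delay: 1.5}
bias_currents:
  # per-population Gaussian bias-current moments (pA), drawn per neuron
  - {selector: {region: M1|S1, ei: E},          mean: 350, sd: 50}
  - {selector: {region: M1|S1, ei: I},          mean: 320, sd: 50}
  - {selector: {region: VL|VM, type: TC},       mean: 340, sd: 40}
  - {selector: {region: VL|VM, type: IN|RTN},   mean: 320, sd: 40}
  - {selector: {region: BG, type: MSN_D1|MSN_D2}, mean: 250, sd: 60}
  - {selector: {region: BG, type: GPe|GPi_SNr}, mean: 450, sd: 50}
  - {selector: {region: BG, type: STN},         mean: 420, sd: 40}
  - {selector: {region: CB_M1|CB_S1, type: GrC}, mean: 250, sd: 80}
  - {selector: {region: CB_M1|CB_S1, type: GoC}, mean: 360, sd: 40}
  - {selector: {region: CB_M1|CB_S1, type: PC},  mean: 520, sd: 60}
  - {selector: {region: CB_M1|CB_S1, type: MLI}, mean: 340, sd: 40}
  - {selector: {region: CB_M1|CB_S1, type: DCN}, mean: 420, sd: 40}
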