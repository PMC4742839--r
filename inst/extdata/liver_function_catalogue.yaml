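# Default liver metabolic function catalogue (22 functions).
#
# Each function pairs a target reaction (usually the one producing the
# end-product of the function) with a constraint set restricting the
# nutrient environment, written as {reaction, lower, upper} bound
# overrides. Identifiers follow Recon 1 conventions (BiGG-style ids with
# exchange reactions named EX_<met>(e)); edit this file to match your
# model's identifiers or to refine the constraint sets.
functions:
  - id: gng_from_lactate
    description: >-
      Gluconeogenesis from lactate: glucose export with lactate as the only
      permitted carbon source.
    target_reaction: EX_glc(e)
    constraints:
      - {reaction: EX_lac_L(e), lower: -10}
      - {reaction: EX_glc(e), lower: 0}
      - {reaction: EX_glyc(e), lower: 0}
      - {reaction: EX_ala_L(e), lower: 0}
      - {reaction: EX_fru(e), lower: 0}
  - id: gng_from_glycerol
    description: Gluconeogenesis from glycerol as the only carbon source.
    target_reaction: EX_glc(e)
    constraints:
      - {reaction: EX_glyc(e), lower: -10}
      - {reaction: EX_glc(e), lower: 0}
      - {reaction: EX_lac_L(e), lower: 0}
      - {reaction: EX_ala_L(e), lower: 0}
      - {reaction: EX_fru(e), lower: 0}
  - id: gng_from_alanine
    description: Gluconeogenesis from alanine as the only carbon source.
    target_reaction: EX_glc(e)
    constraints:
      - {reaction: EX_ala_L(e), lower: -10}
      - {reaction: EX_glc(e), lower: 0}
      - {reaction: EX_lac_L(e), lower: 0}
      - {reaction: EX_glyc(e), lower: 0}
      - {reaction: EX_fru(e), lower: 0}
  - id: glyceroneogenesis
    description: >-
      Glyceroneogenesis: synthesis of glycerol-3-phosphate from pyruvate via
      an abbreviated gluconeogenic route, with glucose and glycerol uptake
      closed.
    target_reaction: G3PD1
    constraints:
      - {reaction: EX_glc(e), lower: 0}
      - {reaction: EX_glyc(e), lower: 0}
      - {reaction: EX_pyr(e), lower: -10}
  - id: ureagenesis
    description: Urea export from ammonia detoxification.
    target_reaction: EX_urea(e)
    constraints:
      - {reaction: EX_nh4(e), lower: -10}
  - id: ureagenesis_from_alanine
    description: Urea export with alanine as the nitrogen source.
    target_reaction: EX_urea(e)
    constraints:
      - {reaction: EX_ala_L(e), lower: -10}
      - {reaction: EX_nh4(e), lower: 0}
  - id: ketogenesis_bhb
    description: Ketogenesis, beta-hydroxybutyrate export from fatty acids.
    target_reaction: EX_bhb(e)
    constraints:
      - {reaction: EX_hdca(e), lower: -10}
      - {reaction: EX_glc(e), lower: 0}
  - id: ketogenesis_acac
    description: Ketogenesis, acetoacetate export from fatty acids.
    target_reaction: EX_acac(e)
    constraints:
      - {reaction: EX_hdca(e), lower: -10}
      - {reaction: EX_glc(e), lower: 0}
  - id: bile_acid_synthesis
    description: Bile-acid (glycocholate) synthesis from cholesterol.
    target_reaction: EX_gchola(e)
    constraints:
      - {reaction: EX_chsterol(e), lower: -10}
  - id: glycogen_synthesis
    description: Net glycogen synthesis from glucose (glycogen demand).
    target_reaction: DM_glycogen_c
    constraints:
      - {reaction: EX_glc(e), lower: -10}
  - id: glycogen_degradation
    description: Glucose export from internal glycogen stores.
    target_reaction: EX_glc(e)
    constraints:
      - {reaction: EX_glc(e), lower: 0}
      - {reaction: EX_lac_L(e), lower: 0}
      - {reaction: EX_glyc(e), lower: 0}
  - id: tca_cycle_throughput
    description: TCA-cycle throughput via mitochondrial citrate synthase.
    target_reaction: CSm
    constraints: []
  - id: oxidative_phosphorylation
    description: Mitochondrial ATP synthesis capacity.
    target_reaction: ATPS4m
    constraints: []
  - id: de_novo_lipogenesis
    description: De novo palmitate synthesis from glucose.
    target_reaction: EX_hdca(e)
    constraints:
      - {reaction: EX_glc(e), lower: -10}
      - {reaction: EX_hdca(e), lower: 0}
      - {reaction: EX_ocdcea(e), lower: 0}
  - id: triglyceride_synthesis
    description: Triacylglycerol synthesis from fatty acids and glycerol.
    target_reaction: DM_tag_hs_c
    constraints:
      - {reaction: EX_hdca(e), lower: -10}
      - {reaction: EX_glyc(e), lower: -10}
  - id: cholesterol_synthesis
    description: De novo cholesterol synthesis from acetyl-CoA.
    target_reaction: DM_chsterol_c
    constraints:
      - {reaction: EX_chsterol(e), lower: 0}
  - id: fatty_acid_oxidation
    description: Palmitate beta-oxidation to CO2.
    target_reaction: EX_co2(e)
    constraints:
      - {reaction: EX_hdca(e), lower: -10}
      - {reaction: EX_glc(e), lower: 0}
  - id: glutamine_synthesis
    description: Glutamine export from glutamate and ammonia.
    target_reaction: EX_gln_L(e)
    constraints:
      - {reaction: EX_glu_L(e), lower: -10}
      - {reaction: EX_nh4(e), lower: -10}
      - {reaction: EX_gln_L(e), lower: 0}
  - id: glutathione_synthesis
    description: Reduced glutathione synthesis (demand).
    target_reaction: DM_gthrd_c
    constraints: []
  - id: serine_synthesis
    description: Serine synthesis from glucose.
    target_reaction: EX_ser_L(e)
    constraints:
      - {reaction: EX_glc(e), lower: -10}
      - {reaction: EX_ser_L(e), lower: 0}
  - id: heme_synthesis
    description: Heme synthesis from succinyl-CoA and glycine (demand).
    target_reaction: DM_pheme_c
    constraints: []
  - id: glucose_oxidation
    description: Complete oxidation of glucose to CO2.
    target_reaction: EX_co2(e)
    constraints:
      - {reaction: EX_glc(e), lower: -10}
      - {reaction: EX_hdca(e), lower: 0}
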