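# Braak-stage composite membership for the bundled SYNTHETIC 10-region
# atlas.  Region names mimic the anatomical composition of the Braak
# staging scheme; edit or replace this file to target a real atlas
# (one name per list entry, resolved against the region table).
stage_I_II:
  - hippocampus
  - parahippocampus
stage_III_IV:
  - amygdala
  - fusiform
  - inferior_temporal
stage_V_VI:
  - orbitofrontal
  - precentral
  - superior_parietal
  - precuneus
  - lateral_occipital
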