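# Compartment-aware identifier patterns assigning NADPH-producing
# reactions to named sources, for restrict_nadph_source() /
# nadph_yield_comparison(). Edit or replace to match a reconstruction's
# naming scheme; each entry is a list of case-insensitive regexes matched
# against reaction ids.
PPP:
  - "^G6PDH"           # glucose-6-phosphate dehydrogenase (oxidative entry)
  - "^GND"             # 6-phosphogluconate dehydrogenase
  - "^PPP$"            # lumped oxidative cycle (synthetic core model)
IDH_cyt:
  - "^ICDHy"
  - "^IDHy"            # cytosolic NADP-dependent isocitrate dehydrogenase
MAE_cyt:
  - "^MAE"             # cytosolic NADP-dependent malic enzyme
MANNITOL_CYCLE:
  - "^MNLDH"           # mannitol 2-dehydrogenase (NADP)
  - "^M1PD"            # mannitol-1-phosphate 5-dehydrogenase
  - "^M1PP"            # mannitol-1-phosphatase
THF:
  - "^MTHFD"           # methylenetetrahydrofolate dehydrogenase (NADP)
  - "^FTHFL"
SSADH:
  - "^SSALy"           # succinate-semialdehyde dehydrogenase (NADP)
TRANSHYDROGENASE:
  - "^THD"             # energy-independent NADH -> NADPH transhydrogenase
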