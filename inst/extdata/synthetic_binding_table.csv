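aptamer_id,ligand_id,kd_app_uM
MMC1,mephedrone,15
MMC2,mephedrone,6.6
MMC3,mephedrone,30
MMC4,mephedrone,40
MMC5,mephedrone,NB
MMC6,mephedrone,NB
MMC7,mephedrone,NB
MMC8,mephedrone,NB
MMC9,mephedrone,NB
MMC10,mephedrone,NB
MMC11,mephedrone,NB
MMC12,mephedrone,NB
MMC13,mephedrone,NB
MMC14,mephedrone,NB
MMC15,mephedrone,NB
MMC16,mephedrone,NB
MMC17,mephedrone,NB
MMC18,mephedrone,NB
MMC19,mephedrone,NB
MMC20,mephedrone,NB
MMC21,mephedrone,NB
MMC22,mephedrone,NB
MMC23,mephedrone,NB
MMC24,mephedrone,NB
MMC25,mephedrone,NB
MMC26,mephedrone,NB
MMC27,mephedrone,NB
MMC28,mephedrone,NB
MMC29,mephedrone,NB
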