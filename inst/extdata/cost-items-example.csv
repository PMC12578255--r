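item,unit_price,quantity_per_batch
dna_extraction_kit_reaction,0.65,90
taq_master_mix_ml,21.00,1.25
primer_set_dilution,8.50,0.4
agarose_g,0.32,2
gel_stain_ul,0.11,10
pcr_plate,2.80,1
filter_tips_box,7.90,2.5
gloves_pair,0.18,6
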