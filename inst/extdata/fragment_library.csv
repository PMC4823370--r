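metabolite,fragment_id,formula,n_backbone
pyruvate,pyruvate_MOX-TBDMS_M-57,C6H12NO3Si,3
lactate,lactate_2TBDMS_M-57,C11H25O3Si2,3
alanine,alanine_2TBDMS_M-57,C11H26NO2Si2,3
PEP,PEP_2TBDMS_M-57,C11H24O6Si2,3
3PG,3PG_3TBDMS_M-57,C17H40O7Si3,3
citrate,citrate_4TBDMS_M-57,C26H55O7Si4,6
isocitrate,isocitrate_4TBDMS_M-57,C26H55O7Si4,6
succinate,succinate_2TBDMS_M-57,C12H25O4Si2,4
fumarate,fumarate_2TBDMS_M-57,C12H23O4Si2,4
malate,malate_3TBDMS_M-57,C18H39O5Si3,4
glutamate,glutamate_3TBDMS_M-57,C19H42NO4Si3,5
glutamine,glutamine_3TBDMS_M-57,C19H43N2O3Si3,5
aspartate,aspartate_3TBDMS_M-57,C18H40NO4Si3,4
serine,serine_3TBDMS_M-57,C17H40NO3Si3,3
glycine,glycine_2TBDMS_M-57,C10H24NO2Si2,2
cystathionine,cystathionine_4TBDMS_M-57,C27H61N2O4SSi4,7
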