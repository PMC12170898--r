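"cell_id","fate"
"A_D11","LV_AVC"
"A_D12","LV_AVC"
"A_D2","MESO_GFP_NEG"
"B_D1","ENDOCARDIUM"
"B_D2","EXEM"
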