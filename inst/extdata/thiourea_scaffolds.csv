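scaffold_id,template
oxazolone,Nc1nc({R1})cnc1NC(=S)Nc1ccc2c(c1)N({R2})C(=O)O2
aryl,Nc1nc({R2})cnc1NC(=S)N{R1}
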