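"system","model","parameter","value"
"BCNU@HCLI","zero_order","K0",0.246
"BCNU@HCLI","first_order","K1",0.003
"BCNU@HCLI","higuchi","KH",2.3
"BCNU@HCLI","korsmeyer_peppas","KP",1.192
"BCNU@HCLI","korsmeyer_peppas","n",0.65
"BCNU@NaCLI","zero_order","K0",0.166
"BCNU@NaCLI","first_order","K1",0.002
"BCNU@NaCLI","higuchi","KH",1.5
"BCNU@NaCLI","korsmeyer_peppas","KP",0.208
"BCNU@NaCLI","korsmeyer_peppas","n",0.85
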