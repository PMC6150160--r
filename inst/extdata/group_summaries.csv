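"marker","group","mean","sd","n"
"bcl2","C_BCNU@HCLI",75.63,23.59,7
"bcl2","Cream BCNU",106.33,15.12,7
"bcl2","Base Cream",185.66,59.33,7
"bcl2","Control Saline",157,45.15,7
"cox2","C_BCNU@HCLI",67.41,18.7,7
"cox2","Cream BCNU",106.86,20.63,7
"cox2","Base Cream",159.46,54.26,7
"cox2","Control Saline",223,80.23,7
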