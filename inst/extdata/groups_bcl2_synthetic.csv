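"group","value"
"C_BCNU@HCLI",78.985005
"C_BCNU@HCLI",78.535668
"C_BCNU@HCLI",109.663272
"C_BCNU@HCLI",34.357765
"C_BCNU@HCLI",92.45409
"C_BCNU@HCLI",62.758667
"C_BCNU@HCLI",72.655534
"Cream BCNU",90.066991
"Cream BCNU",115.024321
"Cream BCNU",94.74881
"Cream BCNU",96.678759
"Cream BCNU",133.375808
"Cream BCNU",113.17938
"Cream BCNU",101.235931
"Base Cream",134.01204
"Base Cream",233.980143
"Base Cream",143.383981
"Base Cream",296.778511
"Base Cream",144.765214
"Base Cream",175.338423
"Base Cream",171.361689
"Control Saline",127.8255
"Control Saline",92.803039
"Control Saline",174.693332
"Control Saline",209.772053
"Control Saline",180.319952
"Control Saline",199.318844
"Control Saline",114.267279
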