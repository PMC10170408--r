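"CDR3.beta.aa","Species","Pathology"
"CSLYIMCFVNYVNVWCRF","Human","Colorectal cancer"
"CQYTDGRYQYMEVF","Human","Cytomegalovirus (CMV)"
"CREYISRMEDLHNQSF","Human","Epstein-Barr virus (EBV)"
"CADKYNTPGHQYPCPF","Human","Influenza"
"CKGQFLGLLDMMVGPF","Human","Influenza"
"CDYEFAHWCLLQNKF","Human","Influenza"
"CDCGHLPLLDYTVTLLIPF","Human","Influenza"
"CCNMPCGTISSCTAF","Human","Cytomegalovirus (CMV)"
"CVGYWANLWMIAPMF","Human","Colorectal cancer"
"CYFTTPLTAPPIQYQRF","Human","Epstein-Barr virus (EBV)"
"CLTWVQYWHLFLGSF","Human","Influenza"
"CLWPNIGHHFAWMF","Human","Cytomegalovirus (CMV)"
"CTASDSNCVYIF","Human","Influenza"
"CDDLCKYDMAYF","Human","Colorectal cancer"
"CFIWSNRHARIGMCAF","Human","Epstein-Barr virus (EBV)"
"CMQIGFEVIWVF","Human","Colorectal cancer"
"CFMTWVDLMQHEFWWSF","Human","Epstein-Barr virus (EBV)"
"CFGKCTGTHSLF","Human","Colorectal cancer"
"CGQFYHMLSYVKNQF","Mouse","Epstein-Barr virus (EBV)"
"CEADQRLKIVRAWWF","Human","Cytomegalovirus (CMV)"
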