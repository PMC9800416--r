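comparison	up_dhgp	up_rhgp
liver_metastases	1460	427
primary_lesions	1091	452
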