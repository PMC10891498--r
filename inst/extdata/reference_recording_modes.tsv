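identification_mode	n
generic_search	211
previously_selected	175
branded_search	169
barcode_scan	114
recipe	16
associated_item	147
supplement_entry	62
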