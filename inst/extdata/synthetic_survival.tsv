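cancer	de_gene_count	five_year_survival_rate
prostate	118	98.0
kidney	231	64.5
colon	247	63.0
breast	294	87.5
stomach	311	23.0
lung	683	15.0
pancreatic	885	4.5
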