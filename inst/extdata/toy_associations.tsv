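# toy disease-microbe association table (synthetic example)
disease	microbe
asthma	Propionibacterium
asthma	Pseudomonas
asthma	Streptococcus
crohns_disease	Bacteroides
crohns_disease	Clostridium
crohns_disease	Prevotella
crohns_disease	Streptococcus
type_2_diabetes	Fusobacterium
type_2_diabetes	Pseudomonas
type_2_diabetes	Lactobacillus
obesity	Bacteroides
obesity	Lactobacillus
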