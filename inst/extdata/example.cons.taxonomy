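OTU	Size	Taxonomy
Otu001	445	Bacteria(100);Bacteroidetes(100);Cytophagia(98);Cytophagales(98);Cytophagaceae(95);
Otu002	755	Bacteria(100);Candidatus_Saccharibacteria(99);unclassified;
Otu003	535	Bacteria(100);Actinobacteria(100);Actinobacteria(100);Micrococcales(97);Propionibacteriaceae(92);Propionicicella(90);
Otu004	12	Bacteria(100);Proteobacteria(88);
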