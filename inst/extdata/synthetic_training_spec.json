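{"n_per_class":104,"lengths":[7,12],"length_weights":[0.5,0.5],"motifs":["WXXW","FHXXW","WXXWXXXW"],"motif_fraction":0.7,"aromatic_enrichment":3,"background":"uniform","similarity_threshold":0.9,"seed":42}
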