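pathway_id,pathway_name,enrichment_p,target_symbols
hsa04659,Th17 cell differentiation,1e-06,IL6;JAK3;RORC;PRKCQ;ZAP70
hsa04657,IL-17 signaling pathway,5e-06,IL6;MMP1;MMP3
hsa04061,Viral protein interaction with cytokine and cytokine receptor,2e-05,CCR1;CCR5
hsa04064,NF-kappa B signaling pathway,8e-05,ZAP70;PRKCQ
hsa05202,Transcriptional misregulation in cancer,3e-04,IL6;MMP1;MMP3;MMP9
hsa04062,Chemokine signaling pathway,1e-03,CCR1;CCR5;JAK3
hsa00910,Nitrogen metabolism,5e-03,CA2
hsa04668,TNF signaling pathway,1e-02,MMP3;MMP9
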