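gene_id,category,promoter_enrichment_baseline,promoter_enrichment_perturbed,genebody_output_baseline,genebody_output_perturbed
FAM129C,co_suppressed,2.81,0.19,2.41,3.05
SLITRK6,YAP_signature,3.20,-0.16,0.52,0.96
APOBR,co_suppressed,2.82,0.99,0.48,0.70
C8orf74,co_suppressed,2.92,-0.07,0.82,1.01
FOLR3,NELFA_suppressed_YAP_activated,0.57,0.03,0.93,1.07
KCNC3,co_suppressed,2.31,0.09,0.91,0.93
HEG1,YAP_signature,2.66,-0.004,0.76,0.77
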