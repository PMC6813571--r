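rsid,allele_ref,allele_eff,outcome_label,subgroup,original_effect_direction,original_estimate
rs2042329,T,G,recurrence,UBC,+,1.54
rs804256,T,C,recurrence,NMIBC,+,4.58
rs4639,A,G,recurrence,NMIBC,+,2.60
rs804276,G,A,recurrence,NMIBC,+,2.71
rs2344673,G,A,overall_survival,MIBC,+,1.55
rs3756712,A,C,overall_survival,NMIBC,+,5.11
rs2293347,C,T,overall_survival,UBC,+,1.50
rs2297518,G,A,progression,UBC,-,0.21
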