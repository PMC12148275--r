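biomarker,comparison,class,referent,high,low
proximity,adaptive_enriched,AE,FALSE,283,29
proximity,adaptive_enriched,IE/Quiet,TRUE,401,201
consistency,adaptive_enriched,AE,FALSE,199,113
consistency,adaptive_enriched,IE/Quiet,TRUE,255,347
count,adaptive_enriched,AE,FALSE,238,74
count,adaptive_enriched,IE/Quiet,TRUE,209,393
proximity,genomic_instability,AGI,FALSE,330,98
proximity,genomic_instability,NGI,TRUE,299,119
consistency,genomic_instability,AGI,FALSE,229,199
consistency,genomic_instability,NGI,TRUE,192,226
count,genomic_instability,AGI,FALSE,259,169
count,genomic_instability,NGI,TRUE,156,262
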