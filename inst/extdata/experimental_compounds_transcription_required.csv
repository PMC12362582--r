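# Header-only template: transcribe the printed per-compound experimental
# values (11 compounds, series A5/A3/B) from the source publication here.
# Units: f_percent %, er unitless, papp 1e-6 cm/s, solubility ug/mL,
# clearance % hepatic blood flow, epsa/tpsa Angstrom^2, descriptor
# columns unitless (log10 capacity-factor scale).
compound_id,series,n_linker_methyls,f_percent,er,papp,solubility,clearance,epsa,tpsa,logk60_rp18,brlogd,logk80_plrps,logkw_iam,delta_logkw_iam,chamelogk
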