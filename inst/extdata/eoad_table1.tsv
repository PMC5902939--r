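gene	protein_change	external_af	called_by_default
APP	p.V717F	0	TRUE
APP	p.I716T	0	FALSE
APP	p.A673T	0.0003632	FALSE
PSEN1	p.A79V	0.00002369	TRUE
PSEN1	p.G206A	0	TRUE
PSEN1	p.H214Y	0.000008952	FALSE
PSEN1	p.P218L	0.0000179	TRUE
PSEN1	p.L262F	0	TRUE
PSEN1	p.R269H	0	TRUE
PSEN1	p.A396T	0	TRUE
PSEN2	p.A85V	0.000008955	TRUE
PSEN2	p.L238P	0.00002687	TRUE
PSEN2	p.R284G	0.000008952	FALSE
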