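# kapcg force-field defaults, version 1.
# All values are config-level substitutes for the published 1BPA
# parameter tables (which are not redistributed here); functional forms
# are fixed in the package. Units: nm, ps, kJ/mol, e, K.
temperature: 300
salt_mM: 200
epsilon_r: 80
dd_xi: 0.25
cutoff: 2.0
skin: 0.3
catpi_depth: 3.5
catpi_sigma: 0.5
ev_eps: 2.5
ev_sigma: 0.6
hp_eps: 5.0
hp_sigma: 0.55
backbone_k: 8000
backbone_r0: 0.38
elastic_k: 8000
elastic_cutoff: 1.4
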