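# scheme: mmodel2
# isoform: hERG1b
# temperature: 296.15
transition	alpha	beta
ae	1.19e-2	2.17e-2
be	1.82e-2	-3.79e-2
ain	9.29e-2	0
bin	1.09e-1	0
ai	5.11e-2	2.09e-2
bi	1.79e-2	-2.15e-2
aa	1.55e-1	9.60e-3
bb	7.82e-2	-3.54e-2
bi2	9.32e-7	1.621e-5
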