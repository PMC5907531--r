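# scheme: mmodel1
# isoform: hERG1a
# temperature: 296.15
transition	alpha	beta
ae	3.39e-2	1.04e-2
be	4.82e-2	-6.91e-2
ain	2.20e-2	0
bin	1.36e-2	0
ai	6.63e-3	-3.89e-2
bi	7.41e-2	2.80e-2
aa	4.94e-3	4.31e-2
bb	2.06e-4	-3.76e-2
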