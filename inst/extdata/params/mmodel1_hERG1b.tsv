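# scheme: mmodel1
# isoform: hERG1b
# temperature: 296.15
transition	alpha	beta
ae	4.71e-2	9.36e-3
be	7.43e-2	-5.05e-2
ain	5.01e-2	0
bin	2.95e-2	0
ai	2.80e-2	-3.06e-2
bi	7.41e-2	1.88e-2
aa	1.71e-2	3.05e-2
bb	1.61e-3	-3.44e-2
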