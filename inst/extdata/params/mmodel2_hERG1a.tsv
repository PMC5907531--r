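# scheme: mmodel2
# isoform: hERG1a
# temperature: 296.15
transition	alpha	beta
ae	3.77e-3	3.29e-2
be	2.44e-2	-6.77e-2
ain	3.59e-2	0
bin	1.65e-2	0
ai	1.74e-2	2.87e-2
bi	9.26469e-3	-2.347e-2
aa	8.80e-2	1.02e-2
bb	5.11e-3	-4.44e-2
bi2	1.02e-9	7.99e-6
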