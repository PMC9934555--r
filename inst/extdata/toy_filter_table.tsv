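variant	nonselect_freq	wt_mean	wt_sd	se	count	depth
A5G	1.0e-4	1.0e-5	1.0e-5	0.10	21	2000000
A5T	3.9e-5	1.0e-5	1.0e-5	0.30	19	2000000
A5V	4.0e-5	1.0e-5	1.0e-5	0.31	20	2000000
C7R	2.0e-5	2.0e-5	0	0.29	40	2000000
C7S	1.9e-5	2.0e-5	0	0.50	5	2000000
D9N	5.0e-4	0	0	0.05	1000	2000000
D9E	5.0e-5	1.0e-5	2.0e-5	0.20	100	2000000
E11K	2.0e-4	1.0e-5	1.0e-5	0.15	400	2000000
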