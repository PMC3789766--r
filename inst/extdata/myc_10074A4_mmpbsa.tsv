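peptide	chirality	dH	dH_sd	TdS	TdS_sd	dG	dG_sd	u_nb	u_nb_sd
c-Myc_370-409	S	−19.9	6.5	−15.4	6.7	−4.5	13.2	−38.6	3.8
c-Myc_370-409	R	−16.7	6.9	−14.3	7.8	−2.3	14.7	−34.9	4.6
c-Myc_410-437	S	−16.6	6.9	−15.5	7.4	−1.1	14.3	−35.8	3.8
c-Myc_410-437	R	−11.2	7.2	−12.8	10	1.6	17.2	−25.7	3.3
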