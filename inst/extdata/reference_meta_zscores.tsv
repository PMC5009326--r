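gene	snp	chrom	pos	A1	A2	N	z	direction	p	q
NRXN3	rs12891137	14	79157374	T	C	718	-4.178	--	2.94e-05	0.016
MAML3	rs1402669	4	140064751	A	G	719	3.832	++	1.27e-04	0.035
MAML3	rs2874372	4	140071968	T	C	718	3.606	++	3.11e-04	0.045
GDI2	rs1858446	10	5810209	T	C	715	-3.468	--	5.24e-04	0.049
CALD1	rs10488462	7	134825047	A	G	714	3.438	++	5.85e-04	0.049
NRXN3	rs766024	14	79170051	T	C	719	3.417	++	6.33e-04	0.050
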