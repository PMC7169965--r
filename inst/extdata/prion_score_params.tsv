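param	aa	value
f_prion	A	0.0465204957102002
f_prion	C	0.0017159199237368923
f_prion	D	0.019542421353670163
f_prion	E	0.0223069590085796
f_prion	F	0.03031458531935177
f_prion	G	0.08531935176358436
f_prion	H	0.013155386081982842
f_prion	I	0.022020972354623452
f_prion	K	0.02430886558627264
f_prion	L	0.04070543374642517
f_prion	M	0.01325071496663489
f_prion	N	0.2166825548141087
f_prion	P	0.04709246901811249
f_prion	Q	0.20257387988560535
f_prion	R	0.020495710200190656
f_prion	S	0.0913250714966635
f_prion	T	0.04137273593898952
f_prion	V	0.02278360343183985
f_prion	W	0.0032411820781696856
f_prion	Y	0.03527168732125834
f_background	A	0.055177928828468614
f_background	C	0.012594962015193924
f_background	D	0.0585765693722511
f_background	E	0.06547381047580968
f_background	F	0.04408236705317873
f_background	G	0.049780087964814076
f_background	H	0.021691323470611756
f_background	I	0.06547381047580968
f_background	K	0.07347061175529788
f_background	L	0.09496201519392243
f_background	M	0.02069172331067573
f_background	N	0.06147540983606557
f_background	P	0.04378248700519792
f_background	Q	0.03958416633346662
f_background	R	0.04448220711715314
f_background	S	0.08956417433026789
f_background	T	0.05917632946821272
f_background	V	0.05587764894042383
f_background	W	0.010395841663334666
f_background	Y	0.03368652538984406
log_base	NA	2.718281828459045
core_length	NA	60
prion_run_length	NA	100
background_run_length	NA	100
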