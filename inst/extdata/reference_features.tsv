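observed_mz	rt	adduct	formula	name	msi_level
136.0485	0.621	M+Na	C4H7N3O	Creatinine	3
98.98454	0.682	M+H	H3O4P	Hydrogen phosphate	3
160.1335	0.715	M+H	C8H17NO2	Pregabalin	3
229.1549	0.723	M+H	C11H20N2O3	L-isoleucyl-L-proline	1
151.0617	0.725	M+H	C6H6N4O	1-Methylhypoxanthine	3
153.0666	0.726	M+H	C7H8N2O2	N1-Methyl-2-pyridone-5-carboxamide	1
207.1111	2.982	M+Na	C9H16N2O2	N-(3-acetamidopropyl)pyrrolidin-2-one	3
307.0875	3.963	M+H	C20H15ClO	4-(2-chloro-1,2-diphenylethenyl)phenol	3
84.04482	3.963	M+H-H2O	C4H7NO2	1-Aminocyclopropanecarboxylic acid	3
91.05471	3.963	M+H-H2O	C7H8O	p-Cresol	3
335.0825	3.963	M+H-H2O	C16H17ClN2O5	N-(Carbethoxyacetyl)-4-chloro-L-tryptophan	3
364.0358	3.963	M+Na	C18H12ClNO4	7-Chloro-6-demethylcepharadione B	1
265.1192	3.963	M+H	C13H16N2O4	Acetyl-N-formyl-5-methoxykynurenamine	1
287.1013	3.964	M+H	C15H14N2O4	3',4'-Dihydrodiol	1
76.07599	0.627	M+H	C3H9NO	Trimethylamine N-oxide	3
110.0605	0.683	M+H	C6H7NO	2-Acetylpyrrole	3
77.03899	3.847	M+H-H2O	C6H6O	Phenol	3
105.0341	3.847	M+H-H2O	C7H6O2	4-Hydroxybenzaldehyde	3
250.0295	3.847	M+H-H2O	C10H9N3O4S	Nitrososulfamethoxazole	3
180.0657	3.847	M+H	C9H9NO3	Hippuric acid	3
314.2335	6.3387	M+H	C17H31NO4	3-hydroxydecanoyl carnitine	3
114.0919	3.3666	M+H	C6H11NO	Epsilon-caprolactam	1
114.0919	3.3666	M+H-H2O	C6H13NO2	L-Leucine	3
153.0665	0.990			Unknown	4
539.9853	0.733			Unknown	4
206.0394	3.847			Unknown	4
202.0476	3.848			Unknown	4
204.1244	0.7264			Unknown	4
133.0520	3.7396			Unknown	4
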