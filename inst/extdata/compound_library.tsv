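name	formula	class	standard_confirmed	msms_match
Creatinine	C4H7N3O	Alpha amino acids and derivatives	FALSE	FALSE
Hydrogen phosphate	H3O4P	Non-metal phosphates	FALSE	FALSE
Pregabalin	C8H17NO2	Gamma amino acids and derivatives	FALSE	FALSE
L-isoleucyl-L-proline	C11H20N2O3	Dipeptides	TRUE	TRUE
1-Methylhypoxanthine	C6H6N4O	Hypoxanthines	FALSE	FALSE
N1-Methyl-2-pyridone-5-carboxamide	C7H8N2O2	Nicotinamides	TRUE	TRUE
N-(3-acetamidopropyl)pyrrolidin-2-one	C9H16N2O2	N-alkylpyrrolidines	FALSE	FALSE
4-(2-chloro-1,2-diphenylethenyl)phenol	C20H15ClO	Stilbenes	FALSE	FALSE
1-Aminocyclopropanecarboxylic acid	C4H7NO2	Alpha amino acids	FALSE	FALSE
p-Cresol	C7H8O	Cresols	FALSE	FALSE
N-(Carbethoxyacetyl)-4-chloro-L-tryptophan	C16H17ClN2O5	N-acyl-alpha amino acids	FALSE	FALSE
7-Chloro-6-demethylcepharadione B	C18H12ClNO4	Oligosaccharides	TRUE	TRUE
Acetyl-N-formyl-5-methoxykynurenamine	C13H16N2O4	Alkyl-phenylketones	TRUE	TRUE
3',4'-Dihydrodiol	C15H14N2O4	Phenylhydantoins	TRUE	TRUE
Trimethylamine N-oxide	C3H9NO	Trialkyl amine oxides	FALSE	FALSE
2-Acetylpyrrole	C6H7NO	Aryl alkyl ketones	FALSE	FALSE
Phenol	C6H6O	1-hydroxy-4-unsubstituted benzenoids	FALSE	FALSE
4-Hydroxybenzaldehyde	C7H6O2	Hydroxybenzaldehydes	FALSE	FALSE
Nitrososulfamethoxazole	C10H9N3O4S	Benzenesulfonamides and derivates	FALSE	FALSE
Hippuric acid	C9H9NO3	Hippuric acids	FALSE	FALSE
3-hydroxydecanoyl carnitine	C17H31NO4	Acyl carnitines	FALSE	FALSE
Epsilon-caprolactam	C6H11NO	Caprolactams	TRUE	TRUE
L-Leucine	C6H13NO2	Amino acids and peptides	FALSE	FALSE
L-Isoleucine	C6H13NO2	Amino acids and peptides	FALSE	FALSE
Aminocaproic acid	C6H13NO2	Fatty acids and conjugates	FALSE	FALSE
2,3,4,5-Tetrahydro-2-pyridinecarboxylic acid	C6H9NO2	Alpha amino acids and derivatives	FALSE	FALSE
Benzoic acid	C7H6O2	Benzoic acids	FALSE	FALSE
Benzyl alcohol	C7H8O	Benzyl alcohols	FALSE	FALSE
9-Decenoylcarnitine	C17H33NO5	Acyl carnitines	FALSE	FALSE
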