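# edff density parameter table: s-type Gaussian expansion per element and basis mode
# weight in electrons (unit-normalized primitives), exponent in 1/bohr^2
element	mode	effective_Z	weight	exponent
H	ecp	1	0.686476457698794	0.420856363481049
H	ecp	1	0.295254555868866	1.7028613491645
H	ecp	1	0.0182689864323397	10.6640705775269
O	ecp	6	1.62767276366645	0.633529314576816
O	ecp	6	4.54204475556263	1.38710037572977
O	ecp	6	-0.169717519229078	12.3359050251664
H	full	1	0.00160701889088237	1.56076247889069e-06
H	full	1	0.76436710817952	0.259273484066672
H	full	1	-0.518528697943258	0.265671481065932
H	full	1	0.459172603366511	0.580019052753934
H	full	1	0.228217999015968	1.41721258266113
H	full	1	0.0559022569819672	3.76272647566997
H	full	1	0.00844451915705031	11.4070588281213
H	full	1	0.000783650389027507	43.1351046213386
H	full	1	3.35419623311364e-05	257.935756373799
O	full	8	-0.0646730915284916	0.00324032080635278
O	full	8	0.0804479403106454	0.0196589006096701
O	full	8	2.8025239886225	0.786271494802094
O	full	8	3.39329605182213	1.57122753436888
O	full	8	1.03114537661042	26.307033093088
O	full	8	0.617850643275594	72.5110008642291
O	full	8	0.126495362869552	227.075034672624
O	full	8	0.0124105519014251	889.290924443132
O	full	8	0.000503176116228564	5542.90222040871
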