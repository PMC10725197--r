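database	population	scheme	n_individuals	disease_allele_count
gnomAD	Total	acmg	125748	284
gnomAD	Total	clinvar	125748	205
gnomAD	Total	hgmd	125748	837
gnomAD	East Asian	acmg	9197	28
gnomAD	East Asian	clinvar	9197	3
gnomAD	East Asian	hgmd	9197	4
gnomAD	African	acmg	8128	24
gnomAD	African	clinvar	8128	22
gnomAD	African	hgmd	8128	17
gnomAD	Latino	acmg	17296	31
gnomAD	Latino	clinvar	17296	6
gnomAD	Latino	hgmd	17296	134
gnomAD	Ashkenazi Jewish	acmg	5040	1
gnomAD	Ashkenazi Jewish	clinvar	5040	0
gnomAD	Ashkenazi Jewish	hgmd	5040	14
gnomAD	European (Finnish)	acmg	10824	53
gnomAD	European (Finnish)	clinvar	10824	53
gnomAD	European (Finnish)	hgmd	10824	125
gnomAD	European (non-Finnish)	acmg	56885	118
gnomAD	European (non-Finnish)	clinvar	56885	102
gnomAD	European (non-Finnish)	hgmd	56885	498
gnomAD	South Asian	acmg	15308	26
gnomAD	South Asian	clinvar	15308	17
gnomAD	South Asian	hgmd	15308	13
gnomAD	Other	acmg	3070	3
gnomAD	Other	clinvar	3070	2
gnomAD	Other	hgmd	3070	32
gnomAD	Korean	acmg	1909	0
gnomAD	Japanese	acmg	76	0
gnomAD	Other East Asian	acmg	7212	28
KOVA	Korean (KOVA)	acmg	5305	3
KRGDB	Korean (KRGDB)	acmg	1722	1
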