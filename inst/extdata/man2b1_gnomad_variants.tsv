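hgvs_c	hgvs_p	af_total	af_east_asian	af_african	af_latino	af_ashkenazi_jewish	af_european_finnish	af_european_non_finnish	af_south_asian	af_other	qc_filters	evidence
c.12C>G	p.(Tyr4*)	3.98e-06	0	0	0	0	0	0	4.41e-05	0		PVS1;PM2
c.65G>A	p.(Trp22*)	7.95e-06	0	2.71e-04	0	0	0	0	0	0		PVS1;PM2
c.159 + 2T>A	p.?	3.98e-06	0	0	0	0	0	0	0	2.03e-04		PVS1;PM2
c.175C>T	p.(Gln59*)	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PVS1;PM2
c.222C>A	p.(Asp74Glu)	1.99e-05	0	0	0	0	0	4.39e-05	0	0		PS1;PM2
c.233T>C	p.(Leu78Pro)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PS1;PM2
c.241del	p.(Val81Trpfs*76)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.308C>T	p.(Ser103Leu)	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PS1;PM2
c.308del	p.(Ser103Trpfs*54)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.388C>T	p.(Gln130*)	3.98e-06	0	0	2.89e-05	0	0	0	0	0		PVS1;PM2
c.418C>T	p.(Arg140*)	1.59e-05	0	0	2.89e-05	0	0	1.76e-05	3.27e-05	0		PVS1;PM2
c.422del	p.(Asp141Alafs*16)	3.99e-06	0	0	0	0	0	8.82e-06	0	0		PVS1;PM2
c.437-1G>A	p.?	3.99e-06	0	6.17e-05	0	0	0	0	0	0		PVS1;PM2
c.438dup	p.(Arg147Alafs*14)	3.99e-06	0	0	0	0	0	8.83e-06	0	0		PVS1;PM2
c.458G>T	p.(Gly153Val)	3.98e-06	0	0	2.89e-05	0	0	0	0	0		PS1;PM2
c.565C>A	p.(Pro189Thr)	9.15e-05	1.25e-03	0	0	0	0	0	0	0		PS1;PM2
c.566C>A	p.(Pro189His)	3.98e-06	0	0	0	0	0	8.84e-06	0	0		PS1;PM2
c.589C>T	p.(Pro197Ser)	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PS1;PM2
c.595G>A	p.(Gly199Ser)	3.98e-06	0	0	0	0	0	8.88e-06	0	0		PS1;PM2
c.598C>A	p.(His200Asn)	7.97e-06	0	0	2.90e-05	0	0	8.89e-06	0	0		PS1;PM2
c.630 + 1G>C	p.?	3.98e-06	0	6.27e-05	0	0	0	0	0	0		PVS1;PM2
c.643G>A	p.(Gly215Ser)	3.98e-06	0	0	0	9.92e-05	0	0	0	0		PS1;PM2
c.644G>T	p.(Gly215Val)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PS1;PM2
c.680G>A	p.(Trp227*)	3.98e-06	5.44e-05	0	0	0	0	0	0	0		PVS1;PM2
c.685C>T	p.(Arg229Trp)	1.59e-05	5.44e-05	6.15e-05	0	0	4.62e-05	8.79e-06	0	0		PS1;PM2
c.788C>T	p.(Pro263Leu)	7.95e-06	0	0	2.89e-05	0	4.63e-05	0	0	0		PS1;PM2
c.807G>A	p.(Trp269*)	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PVS1;PM2
c.856G>A	p.(Glu286Lys)	1.19e-05	0	0	2.89e-05	0	0	1.76e-05	0	0		PS1;PM2
c.861C>A	p.(Tyr287*)	3.98e-06	0	0	2.89e-05	0	0	0	0	0		PVS1;PM2
c.956A>G	p.(Asp319Gly)	3.98e-06	0	0	2.89e-05	0	0	0	0	0		PS1;PM2
c.1026 + 2T>G	p.?	1.59e-05	0	0	0	0	0	3.52e-05	0	0		PVS1;PM2
c.1064C>T	p.(Thr355Ile)	3.98e-06	0	0	0	0	0	8.80e-06	0	0		PS1;PM2
c.1117A>T	p.(Lys373*)	3.98e-06	0	6.15e-05	0	0	0	0	0	0		PVS1;PM2
c.1135C>T	p.(Pro379Ser)	3.58e-05	0	0	0	0	0	0	2.94e-04	0		PS1;PM2
c.1140C>A	p.(Tyr380*)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.1169G>C	p.(Gly390Ala)	8.75e-05	0	0	6.36e-04	0	0	0	0	0		PS1;PM2
c.1321_1327del	p.(Ala441Serfs*34)	3.98e-06	7.62e-05	0	0	0	0	0	0	0		PVS1;PM2
c.1383C>A	p.(Tyr461*)	1.19e-05	0	0	0	0	0	4.38e-05	0	0		PVS1;PM2
c.1501T>A	p.(Cys501Ser)	3.98e-06	0	0	0	0	0	8.84e-06	0	0		PS1;PM2
c.1572G>A	p.(Trp524*)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.1645-1G>A	p.?	7.95e-06	0	0	0	0	0	1.77e-05	0	0		PVS1;PM2
c.1687G>T	p.(Glu563*)	3.98e-06	0	0	2.89e-05	0	0	0	0	0		PVS1;PM2
c.1830 + 1G>C	p.?	9.15e-05	0	0	0	0	3.26e-04	1.42e-04	0	0		PVS1;PM2
c.1858dup	p.(Thr620Asnfs*31)	3.98e-06	0	0	0	0	0	8.80e-06	0	0		PVS1;PM2
c.1859_1860del	p.(Thr620Argfs*30)	3.98e-06	0	6.15e-05	0	0	0	0	0	0		PVS1;PM2
c.1894C>T	p.(Gln632*)	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PVS1;PM2
c.1929-1G>T	p.?	7.95e-06	0	1.23e-04	0	0	0	0	0	0		PVS1;PM2
c.1963del	p.(Gln655Argfs*18)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.2046 + 2T>A	p.?	1.99e-05	0	3.08e-04	0	0	0	0	0	0		PVS1;PM2
c.2088G>A	p.(Trp696*)	3.98e-06	0	0	0	0	4.64e-05	0	0	0		PVS1;PM2
c.2175G>A	p.(Trp725*)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.2237_2240del	p.(Asp746Alafs*19)	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PVS1;PM2
c.2246G>A	p.(Gly749Asp)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PS1;PM2
c.2248C>T	p.(Arg750Trp)	2.35e-04	5.44e-05	1.85e-04	0	0	1.11e-03	2.64e-04	0	1.63e-04		PS1;PM2
c.2249G>A	p.(Arg750Gln)	1.19e-05	0	1.23e-04	0	0	0	8.79e-06	0	0		PS1;PM2
c.2278C>T	p.(Arg760*)	1.19e-05	0	1.25e-04	0	0	0	0	3.29e-05	0		PVS1;PM2
c.2299C>T	p.(Gln767*)	7.55e-05	0	0	0	0	8.85e-04	0	0	0		PVS1;PM2
c.2345_2348dup	p.(Ile784Leufs*14)	3.99e-06	0	6.17e-05	0	0	0	0	0	0		PVS1;PM2
c.2355G>A	p.(Thr785 = )	3.99e-06	0	0	0	0	0	8.82e-06	0	0		PS1;PM2
c.2355 + 1G>C	p.?	3.99e-06	0	0	0	0	0	8.82e-06	0	0		PVS1;PM2
c.2373del	p.(Thr792Leufs*3)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.2398G>A	p.(Gly800Arg)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PS1;PM2
c.2398G>C	p.(Gly800Arg)	7.95e-06	5.44e-05	0	0	0	0	8.79e-06	0	0		PS1;PM2
c.2398G>T	p.(Gly800Trp)	3.98e-06	0	6.15e-05	0	0	0	0	0	0		PS1;PM2
c.2401G>A	p.(Gly801Ser)	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PS1;PM2
c.2402del	p.(Gly801Alafs*4)	3.98e-06	0	0	0	0	0	8.80e-06	0	0		PVS1;PM2
c.2414_2417del	p.(Arg805Metfs*13)	3.98e-06	0	0	0	0	0	8.80e-06	0	0		PVS1;PM2
c.2426T>C	p.(Leu809Pro)	6.76e-05	0	0	0	0	0	1.50e-04	0	0		PS1;PM2
c.2436 + 1G>A	p.?	3.98e-06	0	0	0	0	0	8.82e-06	0	0		PVS1;PM2
c.2437-2A>G	p.?	3.98e-06	0	0	0	0	0	9.36e-06	0	0		PVS1;PM2
c.2581G>T	p.(Glu861*)	3.98e-06	0	7.39e-05	0	0	0	0	0	0		PVS1;PM2
c.2696C>A	p.(Ser899*)	3.98e-06	0	0	0	0	0	9.00e-06	0	0		PVS1;PM2
c.2723G>A	p.(Trp908*)	3.98e-06	0	0	0	0	0	8.92e-06	0	0		PVS1;PM2
c.2724G>A	p.(Trp908*)	4.04e-06	0	0	0	0	0	8.92e-06	0	0		PVS1;PM2
c.2747G>A	p.(Arg916His)	7.95e-06	0	0	0	0	0	8.85e-06	0	1.63e-04		PS1;PM2
c.2747G>T	p.(Arg916Leu)	3.98e-06	0	0	0	0	0	8.85e-06	0	0		PS1;PM2
c.2804_2811del	p.(Val935Glufs*?)	7.95e-06	0	0	0	0	0	1.76e-05	0	0		PVS1;PM2
c.2821-1G>A	p.?	3.98e-06	0	0	0	0	0	0	3.27e-05	0		PVS1;PM2
c.2867T>G	p.(Leu956Arg)	2.39e-05	0	0	0	0	0	0	1.96e-04	0		PS1;PM2
c.2869del	p.(Val957Trpfs*76)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
c.2821-42_2872dup	p.(Ala958Glyfs*?)	3.98e-06	0	0	0	0	0	8.79e-06	0	0		PVS1;PM2
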