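Plant_ID	HIF	Family	nFT_genotype	Visible_bud	delta_Ct
89A_CO01_P1	89A	89A_CO01	CO	FALSE	-9.10734240453897
89A_CO01_P2	89A	89A_CO01	CO	FALSE	-9.580604733223945
89A_CO02_P1	89A	89A_CO02	CO	FALSE	-10.156756908045693
89A_CO02_P2	89A	89A_CO02	CO	FALSE	-9.761969964931883
89A_CO03_P1	89A	89A_CO03	CO	FALSE	-9.933293297120512
89A_CO03_P2	89A	89A_CO03	CO	FALSE	-8.717618819180545
89A_CO04_P1	89A	89A_CO04	CO	FALSE	-9.597901823358521
89A_CO04_P2	89A	89A_CO04	CO	FALSE	-10.809783531666428
89A_CO05_P1	89A	89A_CO05	CO	FALSE	-9.06561020768482
89A_CO05_P2	89A	89A_CO05	CO	FALSE	-9.267317361435362
89A_MT01_P1	89A	89A_MT01	MT	FALSE	-8.1355624589537765
89A_MT01_P2	89A	89A_MT01	MT	FALSE	-8.042806409073187
89A_MT02_P1	89A	89A_MT02	MT	FALSE	-8.620752797135843
89A_MT02_P2	89A	89A_MT02	MT	FALSE	-8.975883156029479
89A_MT03_P1	89A	89A_MT03	MT	FALSE	-9.26297530538988
89A_MT03_P2	89A	89A_MT03	MT	FALSE	-9.342936858426544
89A_MT04_P1	89A	89A_MT04	MT	FALSE	-7.0548988346796655
89A_MT04_P2	89A	89A_MT04	MT	FALSE	-8.233628713399295
89A_MT05_P1	89A	89A_MT05	MT	TRUE	-5.854299133306993
89A_MT05_P2	89A	89A_MT05	MT	FALSE	-7.9101174211082395
98A_CO01_P1	98A	98A_CO01	CO	FALSE	-8.691506153298151
98A_CO01_P2	98A	98A_CO01	CO	FALSE	-10.450063470032964
98A_CO02_P1	98A	98A_CO02	CO	FALSE	-8.930210678813019
98A_CO02_P2	98A	98A_CO02	CO	FALSE	-8.248166696356085
98A_CO03_P1	98A	98A_CO03	CO	FALSE	-9.15428823069534
98A_CO03_P2	98A	98A_CO03	CO	FALSE	-9.716055058198016
98A_CO04_P1	98A	98A_CO04	CO	FALSE	-8.622495798046378
98A_CO04_P2	98A	98A_CO04	CO	FALSE	-9.089254898021547
98A_CO05_P1	98A	98A_CO05	CO	FALSE	-8.536829312952536
98A_CO05_P2	98A	98A_CO05	CO	FALSE	-8.35998537014515
98A_MT01_P1	98A	98A_MT01	MT	TRUE	-2.869919511645411
98A_MT01_P2	98A	98A_MT01	MT	TRUE	-3.7602923647405806
98A_MT02_P1	98A	98A_MT02	MT	TRUE	-4.152097448786028
98A_MT02_P2	98A	98A_MT02	MT	TRUE	-4.53615330910251
98A_MT03_P1	98A	98A_MT03	MT	TRUE	-3.633040833446007
98A_MT03_P2	98A	98A_MT03	MT	TRUE	-5.364324471174545
98A_MT04_P1	98A	98A_MT04	MT	TRUE	-3.3540246677180927
98A_MT04_P2	98A	98A_MT04	MT	TRUE	-4.254781930704917
98A_MT05_P1	98A	98A_MT05	MT	FALSE	-5.0047608048335395
98A_MT05_P2	98A	98A_MT05	MT	TRUE	-3.61543369742369
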