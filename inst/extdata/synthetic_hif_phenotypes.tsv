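Block	Flowering_time	Leaf_number_at_flowering	Height_at_flowering	nFT_genotype	HIF	Family
B1	156.35931237661887	44.67650800432168	28.73880120250906	CO	3A	3A_F01
B2	146.24448627527926	44.83969115296572	32.34362856045209	CO	3A	3A_F01
B3	163.28209411344298	46.25822174791949	28.275404248073563	CO	3A	3A_F01
B1	146.02520070219896	42.893571311748346	24.402875771158154	CO	3A	3A_F02
B2	144.1742410902367	41.00238845656864	26.7134537778617	CO	3A	3A_F02
B3	236.83033000009095	71.48026424137075	30.580296630043502	CO	3A	3A_F02
B1	143.11220029305085	41.2737654806772	26.127137230043182	CO	3A	3A_F03
B2	149.83372472642432	43.4825721757134	29.109259143637072	CO	3A	3A_F03
B3	158.8095052114007	49.42094651701621	26.057471794212383	CO	3A	3A_F03
B1	150.43242767602933	43.72114584031959	23.23739487670562	MT	3A	3A_F04
B2	150.79011933196614	45.75349091543608	26.851281785714455	MT	3A	3A_F04
B3	160.57935790959806	53.7147485765816	28.630771834767312	MT	3A	3A_F04
B1	158.5333072722513	42.95107012336953	28.31713732464668	MT	3A	3A_F05
B2	159.38142078880216	50.025966322930124	26.83017567035081	MT	3A	3A_F05
B3	156.90786283957547	45.59765006061049	26.091909486715384	MT	3A	3A_F05
B1	147.43353800338605	44.616625469538064	22.303377765981185	MT	3A	3A_F06
B2	151.49537112745676	43.35821860810282	24.685998436821723	MT	3A	3A_F06
B3	158.00154510831732	42.520205808629726	26.400886933256178	MT	3A	3A_F06
B1	236.6845256081646	70.63716332156334	32.63161281154561	CO	89A	89A_F01
B2	230.36890645693876	75.21947253140604	30.123288648018377	CO	89A	89A_F01
B3	247.06467220288178	70.74020592513865	31.085275123465827	CO	89A	89A_F01
B1	245.10743214749164	74.36262419664361	32.156341103178356	CO	89A	89A_F02
B2	253.97043663240802	81.15673611572747	31.45388812784541	CO	89A	89A_F02
B3	255.48228750696256	72.29363069728716	34.65839255977306	CO	89A	89A_F02
B1	249.6924901295625	75.09060675018729	32.27597224554751	CO	89A	89A_F03
B2	243.97845836310105	72.615108491384	33.97427120057685	CO	89A	89A_F03
B3	252.64614460756465	74.70731586920613	32.341094663994205	CO	89A	89A_F03
B1	157.35017662650307	46.511998138068286	22.42703763682847	MT	89A	89A_F04
B2	157.67558983331872	44.49006368504947	25.232645069435932	MT	89A	89A_F04
B3	156.25165582760147	44.921879566996445	22.849498768931177	MT	89A	89A_F04
B1	159.3342122856454	46.54346010040831	21.215434866199967	MT	89A	89A_F05
B2	154.58553605687675	44.53341234856991	22.633924472607585	MT	89A	89A_F05
B3	153.87833453961426	40.75448377328788	21.575774817803406	MT	89A	89A_F05
B1	239.31791715406686	74.95207001533508	29.684335277757686	MT	89A	89A_F06
B2	170.5501494105762	53.67961098268056	27.799569224111384	MT	89A	89A_F06
B3	162.6811733760287	49.55096644301669	29.282022996867532	MT	89A	89A_F06
B1	247.61894023354338	73.11381112004297	35.039143752054684	CO	98A	98A_F01
B2	244.08665949361705	77.58880661764528	33.8875231494366	CO	98A	98A_F01
B3	262.63916330306824	79.8403697257716	31.78140783827368	CO	98A	98A_F01
B1	251.30201240771086	77.04891159326624	28.261010311445776	CO	98A	98A_F02
B2	240.09525518886792	72.98731625049133	30.808860526554955	CO	98A	98A_F02
B3	240.51978579659342	74.40846603023185	29.3198256258544	CO	98A	98A_F02
B1	254.39966992751695	70.9583075329759	34.687970411394765	CO	98A	98A_F03
B2	253.11332146222568	79.22503762670492	36.30472810392058	CO	98A	98A_F03
B3	243.63071335178157	68.5777126924804	31.10272309300806	CO	98A	98A_F03
B1	154.03461946591702	48.29359828727112	23.619118242678788	MT	98A	98A_F04
B2	176.11881435414398	51.29290552466091	25.108832932653204	MT	98A	98A_F04
B3	167.79252718194047	51.09761512454263	21.64874330564121	MT	98A	98A_F04
B1	162.4378937362471	50.18453364947233	24.55097917495911	MT	98A	98A_F05
B2	168.31374977246028	48.5650693016616	27.829384489643843	MT	98A	98A_F05
B3	164.88184835541128	54.167865016975774	26.36308472849343	MT	98A	98A_F05
B1	158.3023263026634	46.712082376802606	26.073854652505702	MT	98A	98A_F06
B2	170.37484912664817	50.30001005583087	26.254738884225272	MT	98A	98A_F06
B3	162.71922386841175	46.83830428847698	29.29973775296242	MT	98A	98A_F06
B1	245.29719445441458	73.41466741317443	33.4631167874457	CO	105A	105A_F01
B2	243.01994441664274	78.68782347868598	32.73452649517133	CO	105A	105A_F01
B3	233.85039593104278	65.84796258950814	32.62352907207615	CO	105A	105A_F01
B1	258.6780050685751	79.08299112329749	35.756582236116046	CO	105A	105A_F02
B2	262.97054244285533	71.82334202727914	34.28314483090984	CO	105A	105A_F02
B3	238.50940220098045	70.53890312434196	29.362838242659148	CO	105A	105A_F02
B1	244.26956759232897	70.06817951780097	32.08767108873757	CO	105A	105A_F03
B2	246.6159234683166	75.85816512206372	32.32706497676503	CO	105A	105A_F03
B3	247.9938863461356	72.82241943713818	32.12615083091491	CO	105A	105A_F03
B1	239.926384228196	81.62252728178495	27.374176945270616	MT	105A	105A_F04
B2	251.15774858401733	78.06816443008748	29.58712427053338	MT	105A	105A_F04
B3	234.5232521520197	70.00803737014232	29.363017379953746	MT	105A	105A_F04
B1	250.76999271716727	73.39477524073068	31.000779560710384	MT	105A	105A_F05
B2	251.73791706354717	80.8134750056742	33.14239318738802	MT	105A	105A_F05
B3	244.00626608624333	77.1051356804409	29.199302457867663	MT	105A	105A_F05
B1	234.48142056734568	73.88012913891698	31.987346431982036	MT	105A	105A_F06
B2	258.6758891920251	82.70592838331221	34.537302622743006	MT	105A	105A_F06
B3	175.85018559507864	50.95598289213345	32.569593625097866	MT	105A	105A_F06
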