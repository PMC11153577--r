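ph,ta,temperature,salinity,pco2,dic,omega_calcite,omega_aragonite
7.4,2000.0,5.0,20.0,1847.804380,2082.004166,0.42322292,0.25221495
7.4,2000.0,5.0,27.5,1728.563160,2063.387276,0.50462456,0.31214785
7.4,2000.0,5.0,35.0,1665.260359,2047.821814,0.58214553,0.36757784
7.4,2000.0,12.5,20.0,1948.071216,2055.338986,0.57305406,0.34574394
7.4,2000.0,12.5,27.5,1816.139027,2036.440739,0.67662348,0.42362224
7.4,2000.0,12.5,35.0,1743.439639,2019.780557,0.77367113,0.49432373
7.4,2000.0,20.0,20.0,2039.765708,2031.999030,0.77348012,0.47424741
7.4,2000.0,20.0,27.5,1893.511295,2011.801717,0.90258620,0.57456067
7.4,2000.0,20.0,35.0,1809.688684,1993.192210,1.02106842,0.66361443
7.4,2200.0,5.0,20.0,2033.206651,2290.905230,0.46568764,0.27752132
7.4,2200.0,5.0,27.5,1902.325320,2270.807310,0.55535146,0.34352622
7.4,2200.0,5.0,35.0,1833.010898,2254.109804,0.64078814,0.40460591
7.4,2200.0,12.5,20.0,2143.703621,2261.743612,0.63060223,0.38046481
7.4,2200.0,12.5,27.5,1998.948861,2241.425813,0.74473138,0.46626342
7.4,2200.0,12.5,35.0,1919.393743,2223.623966,0.85175276,0.54421263
7.4,2200.0,20.0,20.0,2244.822787,2236.275328,0.85123786,0.52192337
7.4,2200.0,20.0,27.5,2084.417819,2214.634452,0.99358624,0.63248870
7.4,2200.0,20.0,35.0,1992.741030,2194.806176,1.12435081,0.73073988
7.4,2400.0,5.0,20.0,2218.608923,2499.806294,0.50815235,0.30282769
7.4,2400.0,5.0,27.5,2076.087480,2478.227345,0.60607836,0.37490458
7.4,2400.0,5.0,35.0,2000.761437,2460.397794,0.69943076,0.44163398
7.4,2400.0,12.5,20.0,2339.336026,2468.148237,0.68815041,0.41518568
7.4,2400.0,12.5,27.5,2181.758694,2446.410886,0.81283929,0.50890460
7.4,2400.0,12.5,35.0,2095.347847,2427.467374,0.92983439,0.59410153
7.4,2400.0,20.0,20.0,2449.879866,2440.551625,0.92899560,0.56959933
7.4,2400.0,20.0,27.5,2275.324344,2417.467186,1.08458627,0.69041673
7.4,2400.0,20.0,35.0,2175.793377,2396.420141,1.22763320,0.79786534
7.8,2000.0,5.0,20.0,714.201285,1984.123661,1.03212860,0.61508546
7.8,2000.0,5.0,27.5,662.565503,1961.734327,1.22042740,0.75492520
7.8,2000.0,5.0,35.0,632.654765,1939.562491,1.39545618,0.88111777
7.8,2000.0,12.5,20.0,745.929664,1959.264072,1.38448623,0.83530990
7.8,2000.0,12.5,27.5,687.980043,1932.921946,1.61723753,1.01252441
7.8,2000.0,12.5,35.0,652.954260,1906.357387,1.82823590,1.16811957
7.8,2000.0,20.0,20.0,771.903157,1932.430617,1.84685027,1.13236777
7.8,2000.0,20.0,27.5,706.835194,1901.104172,2.12588102,1.35327531
7.8,2000.0,20.0,35.0,665.875498,1869.236465,2.37052210,1.54065353
7.8,2200.0,5.0,20.0,786.207176,2184.163336,1.13618798,0.67709848
7.8,2200.0,5.0,27.5,729.664262,2160.401385,1.34402146,0.83137733
7.8,2200.0,5.0,35.0,697.045518,2136.968559,1.53748384,0.97079675
7.8,2200.0,12.5,20.0,821.286520,2157.196918,1.52435268,0.91969632
7.8,2200.0,12.5,27.5,757.867465,2129.274927,1.78152219,1.11538018
7.8,2200.0,12.5,35.0,719.695222,2101.213496,2.01510691,1.28751755
7.8,2200.0,20.0,20.0,850.074117,2128.128685,2.03388157,1.24704313
7.8,2200.0,20.0,27.5,778.902830,2094.937309,2.34263200,1.49125281
7.8,2200.0,20.0,35.0,734.283734,2061.271116,2.61405596,1.69893145
7.8,2400.0,5.0,20.0,858.213068,2384.203012,1.24024735,0.73911149
7.8,2400.0,5.0,27.5,796.763021,2359.068442,1.46761553,0.90782945
7.8,2400.0,5.0,35.0,761.436271,2334.374627,1.67951150,1.06047573
7.8,2400.0,12.5,20.0,896.643377,2355.129765,1.66421912,1.00408273
7.8,2400.0,12.5,27.5,827.754887,2325.627908,1.94580684,1.21823596
7.8,2400.0,12.5,35.0,786.436185,2296.069606,2.20197792,1.40691554
7.8,2400.0,20.0,20.0,928.245076,2323.826752,2.22091288,1.36171849
7.8,2400.0,20.0,27.5,850.970466,2288.770446,2.55938298,1.62923030
7.8,2400.0,20.0,35.0,802.691970,2253.305767,2.85758983,1.85720937
8.2,2000.0,5.0,20.0,265.049517,1883.535729,2.41679717,1.44026315
8.2,2000.0,5.0,27.5,241.341060,1843.174709,2.80488038,1.73502731
8.2,2000.0,5.0,35.0,225.988691,1801.800676,3.14511208,1.98588402
8.2,2000.0,12.5,20.0,271.078865,1844.054858,3.17458106,1.91533794
8.2,2000.0,12.5,27.5,244.251631,1795.741561,3.62272564,2.26812578
8.2,2000.0,12.5,35.0,226.272959,1746.574609,3.99744162,2.55409588
8.2,2000.0,20.0,20.0,273.431026,1798.560183,4.12778113,2.53088536
8.2,2000.0,20.0,27.5,243.311480,1741.644141,4.61725000,2.93920984
8.2,2000.0,20.0,35.0,222.574136,1684.353480,4.99948961,3.24927632
8.2,2200.0,5.0,20.0,292.057399,2075.463299,2.66306274,1.58702236
8.2,2200.0,5.0,27.5,266.180041,2032.875464,3.09356052,1.91359747
8.2,2200.0,5.0,35.0,249.507206,1989.313057,3.47242213,2.19255385
8.2,2200.0,12.5,20.0,298.819167,2032.762450,3.49944534,2.11134014
8.2,2200.0,12.5,27.5,269.550424,1981.738651,3.99795582,2.50305089
8.2,2200.0,12.5,35.0,250.025726,1929.919446,4.41706886,2.82220941
8.2,2200.0,20.0,20.0,301.554127,1983.546832,4.55233428,2.79119358
8.2,2200.0,20.0,27.5,268.701239,1923.386179,5.09906394,3.24591887
8.2,2200.0,20.0,35.0,246.174758,1862.953696,5.52960988,3.59381294
8.2,2400.0,5.0,20.0,319.065280,2267.390868,2.90932831,1.73378156
8.2,2400.0,5.0,27.5,291.019022,2222.576219,3.38224066,2.09216762
8.2,2400.0,5.0,35.0,273.025722,2176.825439,3.79973217,2.39922368
8.2,2400.0,12.5,20.0,326.559470,2221.470041,3.82430961,2.30734234
8.2,2400.0,12.5,27.5,294.849216,2167.735741,4.37318600,2.73797601
8.2,2400.0,12.5,35.0,273.778492,2113.264283,4.83669610,3.09032295
8.2,2400.0,20.0,20.0,329.677228,2168.533482,4.97688744,3.05150180
8.2,2400.0,20.0,27.5,294.090997,2105.128218,5.58087788,3.55262790
8.2,2400.0,20.0,35.0,269.775379,2041.553912,6.05973015,3.93834955
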