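x	y	planted_value
6	4	908.742924643968
11	4	1040.956963172775
8	5	142.89475612024012
4	6	3167.339866011728
6	6	3868.472581852261
7	6	851.1079777922234
8	6	464.05636181448807
9	6	258.5151671596836
10	6	976.7772042830275
12	6	788.0685268008867
6	7	280.92419500776134
7	7	1911.6668116323387
8	7	321.89040134290127
9	7	368.801859883627
10	7	502.6324524310355
12	7	746.6336534751601
3	8	733.0204194048787
5	8	361.9863537085065
6	8	333.59861267853375
7	8	2053.825609032427
8	8	1101.231312368282
9	8	564.0897825669343
10	8	2267.131339441729
11	8	723.6337720969756
5	9	1583.1177227985854
6	9	1357.7845901582132
7	9	915.887044085355
8	9	874.8548614900353
9	9	956.4223712828974
10	9	310.89520966992325
6	10	1033.4122192207951
7	10	1156.7888581490922
8	10	338.8479809831609
9	10	1432.23827004001
10	10	374.7318900950761
12	10	1021.8583634059038
6	11	3854.462830309674
7	11	448.3333458220075
8	11	2057.798735487421
10	11	557.8279240670245
12	11	564.4241463388377
6	12	645.3392574820325
9	12	5122.652260048605
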