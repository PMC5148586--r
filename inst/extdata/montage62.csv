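# units: m
name,x,y,z
E01,-0.064424784990741,0.0590183804401204,-0.0215934677419355
E02,0.00767592667650174,-0.0874632254029171,-0.0197804032258065
E03,0.0536571835698476,0.069986294308553,-0.0179673387096774
E04,-0.0871849072379194,-0.0154217824908488,-0.0161542741935484
E05,0.0749676921548054,-0.047688309237911,-0.0143412096774194
E06,-0.0231369131956251,0.0860681638388768,-0.0125281451612903
E07,-0.0411865935650555,-0.0793022796474011,-0.0107150806451613
E08,0.0841243593763474,0.0307220811202236,-0.00890201612903225
E09,-0.082932635463299,0.0342333863376306,-0.00708895161290323
E10,0.0380805401114298,-0.0813759023308736,-0.00527588709677419
E11,0.0269156028891676,0.0858111833089814,-0.00346282258064516
E12,-0.077855925296438,-0.0451191001080921,-0.00164975806451613
E13,0.0879006749210644,-0.0193247168006212,0.000163306451612905
E14,-0.0517491666741555,0.0736078644326021,0.00197637096774194
E15,-0.0115557053644104,-0.0891745807517171,0.00378943548387097
E16,0.0686849423479055,0.057887742125729,0.0056025
E17,-0.0896173825908632,0.00370596012795341,0.00741556451612903
E18,0.0634583760432021,-0.0631495599045988,0.00922862903225807
E19,-0.00412582476177122,0.0892247643517127,0.0110416935483871
E20,-0.0570726041069834,-0.0683920540380993,0.0128547580645161
E21,0.0880036991804014,0.0118407732563429,0.0146678225806452
E22,-0.0726280146956114,0.0505326809290526,0.0164808870967742
E23,0.0193409435096615,-0.085972433015129,0.0182939516129032
E24,0.0436152837221761,0.0761144856661393,0.0201070161290323
E25,-0.0831603667877263,-0.0265304251801672,0.0219200806451613
E26,0.0788093309459808,-0.03641190981808,0.0237331451612903
E27,-0.0333164029854429,0.0796078417194493,0.0255462096774194
E28,-0.0290191402517799,-0.0806806024683118,0.0273592741935484
E29,0.0753658347353529,0.0396101705228761,0.0291723387096774
E30,-0.0817069902056491,0.0215377003987924,0.0309854032258065
E31,0.0453280768106272,-0.0704955740910811,0.0327984677419355
E32,0.0140715231103874,0.0818781660279637,0.0346115322580645
E33,-0.0650680891605823,-0.050392385563971,0.0364245967741936
E34,0.0811950174957077,-0.00672684122885905,0.0382376612903226
E35,-0.0547320232958905,0.0591637134425699,0.0400507258064516
E36,0.00038865583665857,-0.0796697684599851,0.0418637903225806
E37,0.0528715669964114,0.0582831858664423,0.0436768548387097
E38,-0.0773259835356976,-0.00716655477389863,0.0454899193548387
E39,0.0609897622264167,-0.046289055082904,0.0473029838709677
E40,-0.0134982742421422,0.0741984527016587,0.0491160483870968
E41,-0.0395214362219148,-0.0628035153303348,0.0509291129032258
E42,0.0703329494328706,0.0192753455257894,0.0527421774193548
E43,-0.0636839268111716,0.0326815397934394,0.0545552419354839
E44,0.024389262792755,-0.0657858486925797,0.0563683064516129
E45,0.0258897597505341,0.0635975503645669,0.0581813709677419
E46,-0.0606235749118496,-0.0287306434992153,0.059994435483871
E47,0.0625165995046511,-0.0192745357953196,0.0618075
E48,-0.0321872367397234,0.0549218131684494,0.063620564516129
E49,-0.0129736983616428,-0.0604162506490592,0.0654336290322581
E50,0.0487643296038141,0.0346398955699912,0.0672466935483871
E51,-0.057269602182161,0.00713740022469813,0.0690597580645161
E52,0.0359546747798808,-0.0422410272238424,0.0708728225806452
E53,0.00193415753152022,0.0530379189976215,0.0726858870967742
E54,-0.0354442516142359,-0.0359668074213578,0.0744989516129032
E55,0.0476501859113286,0.00243638604045927,0.0763120161290323
E56,-0.0344452780155553,0.0284604040136142,0.0781250806451613
E57,0.00571386535414959,-0.0409541779417818,0.0799381451612903
E58,0.0213461972722662,0.0310012834942702,0.0817512096774194
E59,-0.0325706259328497,-0.00749442491775292,0.0835642741935484
E60,0.0247732489282245,-0.0140355324941108,0.0853773387096774
E61,-0.00688506858677927,0.0212233224514124,0.0871904032258065
E62,-0.0055425940783813,-0.0121516410740501,0.0890034677419355
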