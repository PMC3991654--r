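-0.73734410714095  0.67546760205377  0.00819672131148
 0.08739928859418 -0.99586981488090  0.02459016393443
 0.60792766223544  0.79293398305439  0.04098360655738
-0.98309124874120 -0.17389499957109  0.05737704918033
 0.84145626845954 -0.53526560024837  0.07377049180328
-0.25854692035417  0.96178165656461  0.09016393442623
-0.45828287593669 -0.88239579045890  0.10655737704918
 0.93219444481707  0.34043591613423  0.12295081967213
-0.91532763950569  0.37783394358155  0.13934426229508
 0.41867441468244 -0.89468290570301  0.15573770491803
 0.29481676602736  0.93992230663784  0.17213114754098
-0.84969664860833 -0.49241657592661  0.18852459016393
 0.95594987124586 -0.21016289754323  0.20491803278689
-0.56086804483816  0.79777707859485  0.22131147540984
-0.12482724110778 -0.96328320436954  0.23770491803279
 0.73955197842230  0.62329519035825  0.25409836065574
-0.96190016506561  0.03977759175449  0.27049180327869
 0.67903373822587 -0.67572926385865  0.28688524590164
-0.04401591674727  0.95188478092661  0.30327868852459
-0.60708999595973 -0.72749671158928  0.31967213114754
 0.93342741855070  0.12559133896923  0.33606557377049
-0.76818160008745  0.53448074899855  0.35245901639344
 0.20400528965027 -0.90682396597811  0.36885245901639
 0.45880544950364  0.80067668554533  0.38524590163934
-0.87247406732614 -0.27834302395415  0.40163934426230
 0.82466646033545 -0.38101682152729  0.41803278688525
-0.34772808017299  0.83087847088157  0.43442622950820
-0.30210759755706 -0.83993608251930  0.45081967213115
 0.78263557704029  0.41133132503200  0.46721311475410
-0.84637481961183  0.22310168620825  0.48360655737705
 0.46837922074334 -0.72843730380580  0.50000000000000
 0.14504553156184  0.84397843941060  0.51639344262295
-0.66906442848694 -0.51816109989405  0.53278688524590
 0.83285051040176 -0.06899996235783  0.54918032786885
-0.56003518079670  0.60538162046901  0.56557377049180
 0.00396707474614 -0.81320257327274  0.58196721311475
 0.53833246123346  0.59343296744238  0.59836065573770
-0.78535313427557 -0.07278635196461  0.61475409836066
 0.61786152808295 -0.46893487141111  0.63114754098361
-0.13639097184010  0.74972540129728  0.64754098360656
-0.39827756217912 -0.63290288443959  0.66393442622951
 0.70684361551617  0.19371653018443  0.68032786885246
-0.63820926999697  0.32751846028265  0.69672131147541
 0.24369583980616 -0.65732768475731  0.71311475409836
 0.25788664447644  0.63349212269538  0.72950819672131
-0.60188550683275 -0.28524477398934  0.74590163934426
 0.61850090117796 -0.19069043827800  0.76229508196721
-0.31723287383716  0.54130165843881  0.77868852459016
-0.12733653593577 -0.59298404028136  0.79508196721311
 0.47641942766872  0.33842604534993  0.81147540983607
-0.55661564399975  0.06936993572817  0.82786885245902
 0.34737360011217 -0.40810875884749  0.84426229508197
 0.01855642622574  0.50884905443690  0.86065573770492
-0.33719975292331 -0.34217110034991  0.87704918032787
 0.44859133270936  0.02293677642555  0.89344262295082
-0.31989877683244  0.26431629984234  0.90983606557377
 0.05208838552132 -0.37334394094379  0.92622950819672
 0.18933846267265  0.27497803392412  0.94262295081967
-0.27613489530912 -0.06353799415253  0.95901639344262
 0.19176065754132 -0.10864392263652  0.97540983606557
-0.03942842970593  0.12153869883135  0.99180327868852
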