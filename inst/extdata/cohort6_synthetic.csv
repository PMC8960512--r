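"subject_id","group","arm","lesion_load","region_001","region_002","region_003","region_004","region_005","region_006"
"S001","HC","original",0.47910448854737,0.422149082282019,0.347356313810237,0.514532176253363,0.404843767496094,0.553230140898565,0.640248039528872
"S002","HC","original",0.172667731461312,0.319616155338284,0.354742598419227,0.432393641482566,0.42982251545941,0.50824528172754,0.495263357932914
"S003","HC","original",0.433705508785465,0.327563838091148,0.392517859238168,0.47444785326076,0.541214341815253,0.496380505149523,0.548525521525494
"S004","HC","original",0.00351962000725002,0.325984157923946,0.417010229258864,0.507921564225435,0.542848973362491,0.494738747302114,0.537435108996465
"S005","HC","original",0.15554922265776,0.354224906427331,0.426386709741065,0.506120596536012,0.481546968195115,0.487175379625412,0.556643310765379
"S006","HC","original",3.45203563143553,0.39416324144402,0.391657152555523,0.416072408402887,0.435455626657318,0.555971795553228,0.526026146604096
"S007","HC","original",0.0640399298647618,0.339250392506703,0.402640002331412,0.468069120326205,0.385339286838489,0.506833501410755,0.543449517511567
"S008","HC","original",0.124452206391244,0.345324856317745,0.443040919144606,0.44166210119076,0.495516183904982,0.491718488584545,0.545492562241896
"S009","MS","original",6.46815256913928,0.377637621950251,0.38091580770259,0.403342489098112,0.444926189519337,0.551296443503526,0.600755165949774
"S010","MS","original",14.0246908144007,0.391180280307216,0.377727834926741,0.327280753475679,0.485132594084838,0.412792537329044,0.495268184666107
"S011","MS","original",12.0735461295061,0.324887864714813,0.268150237496106,0.406602354015511,0.400100100178552,0.562077307741634,0.491892498237706
"S012","MS","original",4.79030030561255,0.332823504466055,0.424881662883354,0.446257256049262,0.53303643048564,0.489815585928532,0.529971893840099
"S013","MS","original",16.6607181649254,0.390495729248434,0.49408832099308,0.448888178248935,0.454063804550622,0.51143420458886,0.508916434720687
"S014","MS","original",6.64846743238424,0.238843464541965,0.353888458462459,0.443076694317848,0.466420491981167,0.513761569586194,0.448337974364017
"S015","MS","original",4.48571237037307,0.316912886109756,0.264360312436747,0.488456059474698,0.497059463263152,0.488401443477734,0.481524167236489
"S016","MS","original",4.3337372608065,0.26221001259114,0.369909203166679,0.481504390212319,0.481309862122086,0.445885346657132,0.511540092029261
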