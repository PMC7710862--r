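"wavelength_nm","synthetic_flower_01","synthetic_flower_02","synthetic_flower_03","synthetic_flower_04","synthetic_flower_05","synthetic_flower_06"
300,0.0877827755521864,0.0855335115628688,0.0856030765282394,0.0820996128825924,0.0877402907031362,0.0908980644292784
310,0.126699824376202,0.120587176038537,0.11566564522565,0.125438088498737,0.120066464263696,0.119206833804567
320,0.159362741424379,0.174736415495155,0.163248822275923,0.168127200434603,0.167367235790389,0.168992978899762
330,0.220538149138559,0.214933517679435,0.214338786237118,0.220708400945194,0.22170921856447,0.212587964795894
340,0.264030425678175,0.259296752060896,0.249957572394556,0.254341768026861,0.251502156781727,0.249233919866761
350,0.286878282170859,0.289258579961052,0.269071822333637,0.285242230862644,0.277379963403949,0.258672078263293
360,0.296039611552908,0.296110679987031,0.265504522897039,0.293676168979062,0.283921207100686,0.26358416251453
370,0.293680132303356,0.294686160914224,0.241994799794508,0.285463896833825,0.265997907748299,0.250350585545514
380,0.290724889781903,0.293195349204445,0.226844737377519,0.280076055960134,0.25141603910653,0.237582966583132
390,0.301508856207294,0.302211384536406,0.223692632494059,0.28467109270967,0.253585868517868,0.224160395145944
400,0.321984612874177,0.327670155588043,0.236333302049082,0.318253939363307,0.275194974074018,0.238312440519686
410,0.352889754448051,0.357161112623948,0.268546730369601,0.345216852635641,0.30774118535612,0.264977815395471
420,0.38249985141297,0.37693551940773,0.30867561177417,0.380512274318059,0.348724494800168,0.313288824235149
430,0.397368151701815,0.39148412220834,0.35227726244173,0.391435712971827,0.378306290867706,0.346529394966273
440,0.38269303371763,0.377284797664949,0.37770219831121,0.385323644802202,0.390623789747849,0.385310404039636
450,0.348711781292864,0.343885192831064,0.389860425044108,0.355544178108739,0.380638438844631,0.392651502708951
460,0.298185592203367,0.297529334110702,0.374004946655843,0.31407661066838,0.346835582855675,0.372464619976427
470,0.241659210203704,0.243401347577221,0.341154262833627,0.262012850883191,0.30059900017538,0.335081095692153
480,0.198767569058094,0.192165928410481,0.285665357912262,0.20822252149834,0.236461178399085,0.280454155868212
490,0.141256386384527,0.134756484853798,0.222294876516696,0.15421893665861,0.180305989587837,0.22486651205995
500,0.101224304917049,0.107506793675493,0.171926014089825,0.107814460644024,0.140521239468561,0.175725337264909
510,0.0750524329125942,0.0707817644938417,0.121294482762154,0.0857975626512308,0.105562572612578,0.128599653781343
520,0.0617584328441093,0.0616933490980388,0.0959407187226385,0.0572194288631434,0.0740388057090534,0.0913664987067111
530,0.0472352408886065,0.0597300623872409,0.0736322062288289,0.0507559714224386,0.0568006472273227,0.0645136594929887
540,0.0388787779697262,0.0442884184255026,0.0641524417326208,0.0445570592059035,0.0417262029051749,0.0568862653160274
550,0.0443237622498498,0.0392309113700625,0.0493238403723058,0.0347827622330341,0.0498079367958854,0.0458189254393899
560,0.0367203636834616,0.0407343628834843,0.041584288167107,0.0447386219990031,0.0384349004381626,0.0493346388910816
570,0.0402441025705639,0.0473928137230924,0.0417338156316139,0.0379124077537138,0.0362159518035167,0.0349852952315483
580,0.036361971574296,0.0355438413428966,0.0385661187994893,0.0388069951114719,0.0524380456822711,0.0388892189791277
590,0.0444432906421379,0.0455028365601899,0.0369056567649158,0.0456277047581935,0.0410304207862463,0.0418883787960777
600,0.0381078383028048,0.0453276528278595,0.0407388213248923,0.0425610987687595,0.0398957838883929,0.0394605562211055
610,0.0371650792167814,0.0413484904713352,0.0364371865919897,0.0395703613726536,0.0290796599151269,0.0375965176084958
620,0.0379957010355206,0.0400282393123647,0.0406792266899189,0.0420561289109873,0.0396031868562401,0.0387872537902252
630,0.0334838019943131,0.0381782844601684,0.0414216288719427,0.0415973511196925,0.0439047272348024,0.0425198009485108
640,0.0353295621254195,0.0385339396010183,0.0397920210238678,0.0466514857948457,0.0416556181193311,0.0435811031185026
650,0.0312798495077612,0.0425931535428433,0.0392163646207249,0.0411035862859108,0.0436493200431127,0.0426409471729957
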