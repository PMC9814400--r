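id,kd_uM,kd_uM_err,kd_nd1_uM,kd_nd1_uM_err,mw,ha,clogp,std_max_pct,score_bli,le_published,lle_at_published,flag_inconsistent
TROLL2,56,46,321,67,216,11,1.39,37.7,0.83,0.52,0.47,
VIK20,147,32,192,92,245,17,1.80,18.3,0.94,0.30,0.27,
TROLL6,160,22,243,16,175,13,2.04,72.5,0.75,0.39,0.30,
TROLL7,222,83,718,57,172,11,1.18,37.3,0.91,0.45,0.42,
TROLL8,245,43,598,214,200,12,1.09,41.0,0.91,0.41,0.40,
TROLL11,323,48,290,179,223,17,2.08,43.7,0.90,0.28,0.22,
TROLL12,354,17,192,92,118,14,1.09,47.9,0.84,0.33,0.34,mw
TROLL14,409,61,290,33,244,17,2.29,67.4,0.93,0.27,0.16,lle_at
TROLL13,409,80,784,118,252,19,2.42,38.7,0.92,0.24,0.18,
TROLL18,625,89,445,223,194,13,2.78,57.4,0.89,0.33,0.27,lle_at
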