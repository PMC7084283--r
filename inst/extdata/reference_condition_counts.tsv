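condition	n_before	n_total	pct_before
degenerative disc disease	29	165	17.6
chronic obstructive pulmonary disorder	44	538	8.4
menopause	34	308	11.4
heart failure	116	896	12.9
gout	520	2052	25.34
ulcerative colitis	70	324	21.9
bladder cancer	33	302	11.3
parkinson disease	144	3613	4.01
endometrial cancer	25	110	22.7
crohn disease	146	894	16.4
angina pectoris or coronary heart disease	239	775	30.8
graves disease	112	479	23.4
esophageal cancer	29	119	24.4
lymphoma	177	849	21.0
plantar fasciitis	10	212	5.2
cellulitis	4	278	1.8
prostatitis	12	103	12.6
mastitis	10	90	12.2
bells palsy	6	168	3.6
mononucleosis	21	91	22.8
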