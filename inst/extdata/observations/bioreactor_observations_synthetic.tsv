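time_h	variable	kind	value
0	Prevotella	genus	12.3
8	Prevotella	genus	12.5
24	Prevotella	genus	12.6
40.8	Prevotella	genus	12.7
72	Prevotella	genus	12.6
96	Prevotella	genus	12.5
132	Prevotella	genus	12.5
240	Prevotella	genus	12.4
360	Prevotella	genus	12.4
480	Prevotella	genus	12.4
600	Prevotella	genus	12.3
720	Prevotella	genus	12.4
840	Prevotella	genus	12.4
0	Megasphaera	genus	11
8	Megasphaera	genus	11.1
24	Megasphaera	genus	11.2
40.8	Megasphaera	genus	11.3
72	Megasphaera	genus	11.2
96	Megasphaera	genus	11.2
132	Megasphaera	genus	11.1
240	Megasphaera	genus	11.1
360	Megasphaera	genus	11.1
480	Megasphaera	genus	11.1
600	Megasphaera	genus	11.1
720	Megasphaera	genus	11.1
840	Megasphaera	genus	11.1
0	others	genus	12.44
8	others	genus	12.48
24	others	genus	12.54
40.8	others	genus	12.59
72	others	genus	12.54
96	others	genus	12.54
132	others	genus	12.48
240	others	genus	12.48
360	others	genus	12.48
480	others	genus	12.48
600	others	genus	12.48
720	others	genus	12.48
840	others	genus	12.48
0	Succinivibrio	genus	9.7
8	Succinivibrio	genus	10
24	Succinivibrio	genus	10.3
40.8	Succinivibrio	genus	10.1
72	Succinivibrio	genus	9.9
96	Succinivibrio	genus	9.6
132	Succinivibrio	genus	9.9
240	Succinivibrio	genus	9.8
360	Succinivibrio	genus	10
480	Succinivibrio	genus	9.7
600	Succinivibrio	genus	9.9
720	Succinivibrio	genus	9.8
840	Succinivibrio	genus	9.8
0	Blautia	genus	9.78
8	Blautia	genus	9.88
24	Blautia	genus	9.98
40.8	Blautia	genus	10.08
72	Blautia	genus	9.98
96	Blautia	genus	9.98
132	Blautia	genus	9.88
240	Blautia	genus	9.88
360	Blautia	genus	9.88
480	Blautia	genus	9.88
600	Blautia	genus	9.88
720	Blautia	genus	9.88
840	Blautia	genus	9.88
0	Ruminococcus	genus	10.56
8	Ruminococcus	genus	10.76
24	Ruminococcus	genus	10.86
40.8	Ruminococcus	genus	10.96
72	Ruminococcus	genus	10.86
96	Ruminococcus	genus	10.76
132	Ruminococcus	genus	10.76
240	Ruminococcus	genus	10.66
360	Ruminococcus	genus	10.66
480	Ruminococcus	genus	10.66
600	Ruminococcus	genus	10.56
720	Ruminococcus	genus	10.66
840	Ruminococcus	genus	10.66
0	RC9	genus	11.28
8	RC9	genus	11.23
24	RC9	genus	11.13
40.8	RC9	genus	11.03
72	RC9	genus	10.84
96	RC9	genus	10.7
132	RC9	genus	10.48
240	RC9	genus	9.83
360	RC9	genus	9.1
480	RC9	genus	8.38
600	RC9	genus	7.65
720	RC9	genus	6.93
840	RC9	genus	6.2
0	Streptococcus	genus	11.41
8	Streptococcus	genus	11.36
24	Streptococcus	genus	11.25
40.8	Streptococcus	genus	11.14
72	Streptococcus	genus	10.94
96	Streptococcus	genus	10.78
132	Streptococcus	genus	10.54
240	Streptococcus	genus	9.84
360	Streptococcus	genus	9.05
480	Streptococcus	genus	8.26
600	Streptococcus	genus	7.47
720	Streptococcus	genus	6.69
840	Streptococcus	genus	5.9
0	Lactobacillus	genus	10.99
8	Lactobacillus	genus	10.94
24	Lactobacillus	genus	10.84
40.8	Lactobacillus	genus	10.73
72	Lactobacillus	genus	10.53
96	Lactobacillus	genus	10.37
132	Lactobacillus	genus	10.14
240	Lactobacillus	genus	9.45
360	Lactobacillus	genus	8.68
480	Lactobacillus	genus	7.91
600	Lactobacillus	genus	7.14
720	Lactobacillus	genus	6.37
840	Lactobacillus	genus	5.6
0	Alloprevotella	genus	11.07
8	Alloprevotella	genus	11.02
24	Alloprevotella	genus	10.93
40.8	Alloprevotella	genus	10.82
72	Alloprevotella	genus	10.64
96	Alloprevotella	genus	10.49
132	Alloprevotella	genus	10.27
240	Alloprevotella	genus	9.62
360	Alloprevotella	genus	8.9
480	Alloprevotella	genus	8.17
600	Alloprevotella	genus	7.45
720	Alloprevotella	genus	6.72
840	Alloprevotella	genus	6
0	Clostridium	genus	11.24
8	Clostridium	genus	11.19
24	Clostridium	genus	11.08
40.8	Clostridium	genus	10.98
72	Clostridium	genus	10.77
96	Clostridium	genus	10.62
132	Clostridium	genus	10.39
240	Clostridium	genus	9.69
360	Clostridium	genus	8.91
480	Clostridium	genus	8.13
600	Clostridium	genus	7.35
720	Clostridium	genus	6.58
840	Clostridium	genus	5.8
0	Treponema	genus	10.49
8	Treponema	genus	10.44
24	Treponema	genus	10.35
40.8	Treponema	genus	10.25
72	Treponema	genus	10.06
96	Treponema	genus	9.92
132	Treponema	genus	9.71
240	Treponema	genus	9.06
360	Treponema	genus	8.35
480	Treponema	genus	7.64
600	Treponema	genus	6.93
720	Treponema	genus	6.21
840	Treponema	genus	5.5
0	Faecalibacterium	genus	10.49
8	Faecalibacterium	genus	10.45
24	Faecalibacterium	genus	10.36
40.8	Faecalibacterium	genus	10.28
72	Faecalibacterium	genus	10.11
96	Faecalibacterium	genus	9.99
132	Faecalibacterium	genus	9.8
240	Faecalibacterium	genus	9.24
360	Faecalibacterium	genus	8.61
480	Faecalibacterium	genus	7.98
600	Faecalibacterium	genus	7.35
720	Faecalibacterium	genus	6.73
840	Faecalibacterium	genus	6.1
0	Phascolarctobacterium	genus	10.16
8	Phascolarctobacterium	genus	10.06
24	Phascolarctobacterium	genus	9.87
40.8	Phascolarctobacterium	genus	9.67
72	Phascolarctobacterium	genus	9.29
96	Phascolarctobacterium	genus	9
132	Phascolarctobacterium	genus	8.56
240	Phascolarctobacterium	genus	7.26
360	Phascolarctobacterium	genus	5.81
480	Phascolarctobacterium	genus	4.35
600	Phascolarctobacterium	genus	2.9
720	Phascolarctobacterium	genus	1.45
840	Phascolarctobacterium	genus	0
0	Parabacteroides	genus	9.3
8	Parabacteroides	genus	9.26
24	Parabacteroides	genus	9.18
40.8	Parabacteroides	genus	9.1
72	Parabacteroides	genus	8.95
96	Parabacteroides	genus	8.83
132	Parabacteroides	genus	8.66
240	Parabacteroides	genus	8.13
360	Parabacteroides	genus	7.54
480	Parabacteroides	genus	6.96
600	Parabacteroides	genus	6.37
720	Parabacteroides	genus	5.79
840	Parabacteroides	genus	5.2
0	Escherichia	genus	8.7
8	Escherichia	genus	8.66
24	Escherichia	genus	8.59
40.8	Escherichia	genus	8.52
72	Escherichia	genus	8.37
96	Escherichia	genus	8.27
132	Escherichia	genus	8.1
240	Escherichia	genus	7.61
360	Escherichia	genus	7.07
480	Escherichia	genus	6.53
600	Escherichia	genus	5.99
720	Escherichia	genus	5.44
840	Escherichia	genus	4.9
0	Turicibacter	genus	9.55
8	Turicibacter	genus	9.51
24	Turicibacter	genus	9.43
40.8	Turicibacter	genus	9.34
72	Turicibacter	genus	9.19
96	Turicibacter	genus	9.06
132	Turicibacter	genus	8.88
240	Turicibacter	genus	8.34
360	Turicibacter	genus	7.73
480	Turicibacter	genus	7.12
600	Turicibacter	genus	6.51
720	Turicibacter	genus	5.91
840	Turicibacter	genus	5.3
0	acetate	scfa	25.88
8	acetate	scfa	80.62
24	acetate	scfa	70.5
40.8	acetate	scfa	62.3
72	acetate	scfa	55.4
96	acetate	scfa	58.9
132	acetate	scfa	50.77
240	acetate	scfa	49.2
360	acetate	scfa	48.5
480	acetate	scfa	48.1
600	acetate	scfa	47.9
720	acetate	scfa	47.8
840	acetate	scfa	47.69
0	propionate	scfa	10.68
8	propionate	scfa	49.04
24	propionate	scfa	45.2
40.8	propionate	scfa	38.72
72	propionate	scfa	41
96	propionate	scfa	40.1
132	propionate	scfa	39.3
240	propionate	scfa	35.68
360	propionate	scfa	34.9
480	propionate	scfa	34.2
600	propionate	scfa	33.6
720	propionate	scfa	33
840	propionate	scfa	32.68
0	butyrate	scfa	6
8	butyrate	scfa	20.5
24	butyrate	scfa	21.2
40.8	butyrate	scfa	21
72	butyrate	scfa	21.3
96	butyrate	scfa	27.9
132	butyrate	scfa	26.5
240	butyrate	scfa	26
360	butyrate	scfa	26.4
480	butyrate	scfa	26.6
600	butyrate	scfa	26.8
720	butyrate	scfa	26.9
840	butyrate	scfa	26.9
0	lactate	scfa	0
8	lactate	scfa	0
24	lactate	scfa	0
40.8	lactate	scfa	0
72	lactate	scfa	0
96	lactate	scfa	0
132	lactate	scfa	0
240	lactate	scfa	0
360	lactate	scfa	0
480	lactate	scfa	0
600	lactate	scfa	0
720	lactate	scfa	0
840	lactate	scfa	0
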