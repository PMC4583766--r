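reaction	metabolite	pattern	alpha
GND	PGN	100000	0.9905
G6PDH	G6P	100000	0.9837
ALD	FBP	001000	0.9843
RPE	RU5P	01000	0.9931
RPE	RU5P	00100	0.9818
RPE	RU5P	00010	0.9852
RPE	RU5P	00001	0.998
PDH	PYR	100	0.9908
PDH	PYR	010	0.9791
PDH	PYR	001	0.9969
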