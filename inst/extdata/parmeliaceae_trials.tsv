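clade_group	group	amplified	sampled
Cetrarioid	Cetraria clade	18	18
Cetrarioid	Nephromopsis clade	6	6
Cetrarioid	Melanelia	22	24
Parmelioid	Flavoparmelia	5	5
Parmelioid	Melanelixia	4	5
Parmelioid	Melanohalea	9	11
Parmelioid	Parmotrema	2	2
Parmelioid	Xanthoparmelia	4	4
Others	Alectoria	9	9
Others	Evernia	11	11
Others	Protousnea	1	1
Others	Usnea	6	7
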