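name	role	location	orientation	sequence	tm
mrSSU1	major	533-552	F	AGCAGTGAGGAATATTGGTC	58.7
mt-SSU-581-5'	major	581-600	F	GGAGGAATGTATAGCAATAG	53.5
mt-SSU-862-5'	major	862-880	F	GAAAGCATCYCCTTATGTG	56.7
mt-SSU-1345-3'	major	1345-1324	R	CGCTTGTAAATATATCTTATTG	53.4
mrSSU3R	major	1524-1505	R	ATGTGGCACGTCTATAGCCC	64.2
mt-SSU-574-5'	alternative	574-594	F	GCAACTTGRARGAATGTATAG	56.0
mt-SSU-897-3'	alternative	897-880	R	CCCTCAACGTCAGTTATC	56.0
mt-SSU-1093-3'	alternative	1093-1073	R	TCTAATGATTTCARTTCCAA	55.3
mt-SSU-1372-3'	alternative	1372-1353	R	CGACATTAACTGAAGACAGC	58.1
mt-SSU-1492-3'	alternative	1492-1472	R	CCATGATGACTTGTCTTAGTC	56.8
mt-SSU-1548-3'	alternative	1548-1529	R	ATTTCACACCCTTTTGTAAG	56.3
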