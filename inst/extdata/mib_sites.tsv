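# Candidate metal-binding residue pairs for the 90-210 fragment, as ranked
# by a metal ion-binding site prediction/docking server (descriptive
# fixture; the server itself is out of scope).
metal	rank	site
Fe2+	1	Asp104-Glu108
Fe2+	2	Glu96-Glu100
Fe3+	1	Glu108-Glu111
Fe3+	2	Asp104-Glu108
Co2+	1	Glu100-Asp104
Co2+	2	Glu108-Asp112
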