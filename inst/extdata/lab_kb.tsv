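analyte	synonyms	specimen	unit	low	high	conversions	snomed_higher	snomed_lower	snomed_normal
leukocyte	WBC|白细胞	blood	10^9/L	4	10	/L=1e-09	414478003
glucose	血糖	blood	mmol/L	3.9	6.1		80394007	302866003
hemoglobin	Hb	blood	g/L	120	160		165397008	271737000
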