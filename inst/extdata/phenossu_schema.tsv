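attribute	subtype	values	default
assertion	phrase-based	present|absent	present
severity	phrase-based	severe|moderate|mild
temporal pattern	phrase-based	acute|chronic|recurrent|occasional|persistent
laterality	phrase-based	left|right|bilateral
spatial pattern	phrase-based	diffuse|localized
quadrant pattern	phrase-based	right-lower|right-upper|left-lower|left-upper
body location	phrase-based	abdomen|chest|head|limb
specimen	logic-based	blood|urine|serum|sputum
analyte	logic-based	leukocyte|glucose|hemoglobin
abnormality	logic-based	higher|lower|normal
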