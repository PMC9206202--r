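surface	letter	category	normalization
右下	A	quadrant pattern	right-lower
腹部	A	body location	abdomen
突发	A	temporal pattern	acute
剧烈	A	severity	severe
急性	A	temporal pattern	acute
没有出现	A	assertion	absent
无	A	assertion	absent
严重	A	severity	severe
呈持续性	A	temporal pattern	persistent
反复出现	A	temporal pattern	recurrent
疼痛	P		pain
发热	P		fever
乏力	P		fatigue
咳嗽	P		cough
腹痛	P		abdominal pain
腹泻	P		diarrhea
呼吸困难	P		dyspnea
,	C
，	C
、	C
WBC	L		leukocyte
白细胞	L		leukocyte
糖	L		glucose
血	S		blood
升高	R		higher
降低	R		lower
正常	R		normal
/L	U		/L
mmol/L	U		mmol/L
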