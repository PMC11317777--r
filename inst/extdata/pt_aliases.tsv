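alias	pt
tooth discoloration	tooth discolouration
esophagitis	oesophagitis
esophageal ulcer	oesophageal ulcer
esophageal pain	oesophageal pain
optic disc edema	optic disc oedema
hemophagocytic lymphohistiocytosis	haemophagocytic lymphohistiocytosis
diarrhea	diarrhoea
dyspnea	dyspnoea
anemia	anaemia
hypertriglyceridemia	hypertriglyceridaemia
hyperkalemia	hyperkalaemia
papilledema	papilloedema
off-label use	off label use
paresthesia	paraesthesia
hyperglycemia	hyperglycaemia
hyponatremia	hyponatraemia
edema peripheral	oedema peripheral
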