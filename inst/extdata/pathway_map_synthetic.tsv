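metabolite_id	pathway_id	pathway_name	purine_flag
IMP	pb	Purine biosynthesis	1
AMP	pb	Purine biosynthesis	1
GMP	pb	Purine biosynthesis	1
adenylosuccinate	pb	Purine biosynthesis	1
SAICAR	pb	Purine biosynthesis	1
AICAR	pb	Purine biosynthesis	1
inosine	pb	Purine biosynthesis	1
adenine	pb	Purine biosynthesis	1
hypoxanthine	purine_deg	Purine degradation	0
xanthine	purine_deg	Purine degradation	0
urate	purine_deg	Purine degradation	0
glucose	glycolysis	Glycolysis / Gluconeogenesis	0
glucose-6-phosphate	glycolysis	Glycolysis / Gluconeogenesis	0
fructose-6-phosphate	glycolysis	Glycolysis / Gluconeogenesis	0
fructose-1,6-bisphosphate	glycolysis	Glycolysis / Gluconeogenesis	0
phosphoenolpyruvate	glycolysis	Glycolysis / Gluconeogenesis	0
pyruvate	glycolysis	Glycolysis / Gluconeogenesis	0
lactate	glycolysis	Glycolysis / Gluconeogenesis	0
citrate	tca	Citrate cycle	0
isocitrate	tca	Citrate cycle	0
2-oxoglutarate	tca	Citrate cycle	0
succinate	tca	Citrate cycle	0
fumarate	tca	Citrate cycle	0
malate	tca	Citrate cycle	0
oxaloacetate	tca	Citrate cycle	0
alanine	aa	Amino acid metabolism	0
serine	aa	Amino acid metabolism	0
glycine	aa	Amino acid metabolism	0
glutamate	aa	Amino acid metabolism	0
glutamine	aa	Amino acid metabolism	0
aspartate	aa	Amino acid metabolism	0
proline	aa	Amino acid metabolism	0
leucine	aa	Amino acid metabolism	0
UMP	pyrimidine	Pyrimidine metabolism	0
CMP	pyrimidine	Pyrimidine metabolism	0
uridine	pyrimidine	Pyrimidine metabolism	0
cytidine	pyrimidine	Pyrimidine metabolism	0
uracil	pyrimidine	Pyrimidine metabolism	0
orotate	pyrimidine	Pyrimidine metabolism	0
ribose-5-phosphate	ppp	Pentose phosphate pathway	0
6-phosphogluconate	ppp	Pentose phosphate pathway	0
sedoheptulose-7-phosphate	ppp	Pentose phosphate pathway	0
erythrose-4-phosphate	ppp	Pentose phosphate pathway	0
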