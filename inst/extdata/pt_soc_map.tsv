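pt	soc
vomiting	Gastrointestinal disorders
nausea	Gastrointestinal disorders
colitis ulcerative	Gastrointestinal disorders
dysphagia	Gastrointestinal disorders
oesophageal ulcer	Gastrointestinal disorders
oesophagitis	Gastrointestinal disorders
oesophageal pain	Gastrointestinal disorders
abdominal pain upper	Gastrointestinal disorders
abdominal pain	Gastrointestinal disorders
pancreatitis	Gastrointestinal disorders
pancreatitis acute	Gastrointestinal disorders
diarrhoea	Gastrointestinal disorders
dyspepsia	Gastrointestinal disorders
gastritis	Gastrointestinal disorders
constipation	Gastrointestinal disorders
tooth discolouration	Gastrointestinal disorders
headache	Nervous system disorders
idiopathic intracranial hypertension	Nervous system disorders
intracranial pressure increased	Nervous system disorders
dizziness	Nervous system disorders
somnolence	Nervous system disorders
seizure	Nervous system disorders
paraesthesia	Nervous system disorders
depression	Psychiatric disorders
suicidal ideation	Psychiatric disorders
suicide attempt	Psychiatric disorders
anxiety	Psychiatric disorders
insomnia	Psychiatric disorders
hallucination	Psychiatric disorders
cholangitis sclerosing	Hepatobiliary disorders
drug-induced liver injury	Hepatobiliary disorders
autoimmune hepatitis	Hepatobiliary disorders
hepatotoxicity	Hepatobiliary disorders
hepatitis	Hepatobiliary disorders
jaundice	Hepatobiliary disorders
liver failure	Hepatobiliary disorders
drug reaction with eosinophilia and systemic symptoms	Skin and subcutaneous tissue disorders
neutrophilic dermatosis	Skin and subcutaneous tissue disorders
photosensitivity reaction	Skin and subcutaneous tissue disorders
urticaria	Skin and subcutaneous tissue disorders
dermatitis	Skin and subcutaneous tissue disorders
rash	Skin and subcutaneous tissue disorders
rash pruritic	Skin and subcutaneous tissue disorders
pruritus	Skin and subcutaneous tissue disorders
alopecia	Skin and subcutaneous tissue disorders
drug eruption	Skin and subcutaneous tissue disorders
erythema multiforme	Skin and subcutaneous tissue disorders
stevens-johnson syndrome	Skin and subcutaneous tissue disorders
hyperthyroidism	Endocrine disorders
hypothyroidism	Endocrine disorders
thyroiditis	Endocrine disorders
autoimmune thyroiditis	Endocrine disorders
thyroid disorder	Endocrine disorders
lymphadenopathy	Blood and lymphatic system disorders
neutropenia	Blood and lymphatic system disorders
thrombocytopenia	Blood and lymphatic system disorders
bone marrow failure	Blood and lymphatic system disorders
haemophagocytic lymphohistiocytosis	Blood and lymphatic system disorders
anaemia	Blood and lymphatic system disorders
leukopenia	Blood and lymphatic system disorders
arthralgia	Musculoskeletal and connective tissue disorders
lupus-like syndrome	Musculoskeletal and connective tissue disorders
arthropathy	Musculoskeletal and connective tissue disorders
myalgia	Musculoskeletal and connective tissue disorders
back pain	Musculoskeletal and connective tissue disorders
dyspnoea	Respiratory, thoracic and mediastinal disorders
cough	Respiratory, thoracic and mediastinal disorders
pyrexia	General disorders and administration site conditions
fatigue	General disorders and administration site conditions
multiple organ dysfunction syndrome	General disorders and administration site conditions
malaise	General disorders and administration site conditions
asthenia	General disorders and administration site conditions
chest pain	General disorders and administration site conditions
pain	General disorders and administration site conditions
oedema peripheral	General disorders and administration site conditions
death	General disorders and administration site conditions
drug ineffective	General disorders and administration site conditions
drug ineffective for unapproved indication	General disorders and administration site conditions
condition aggravated	General disorders and administration site conditions
treatment failure	General disorders and administration site conditions
intentional overdose	Injury, poisoning and procedural complications
off label use	Injury, poisoning and procedural complications
intentional product use issue	Injury, poisoning and procedural complications
product use issue	Injury, poisoning and procedural complications
alanine aminotransferase increased	Investigations
aspartate aminotransferase increased	Investigations
transaminases increased	Investigations
weight decreased	Investigations
weight increased	Investigations
blood cholesterol increased	Investigations
blood creatinine increased	Investigations
hypertriglyceridaemia	Metabolism and nutrition disorders
hyperkalaemia	Metabolism and nutrition disorders
decreased appetite	Metabolism and nutrition disorders
type 1 diabetes mellitus	Metabolism and nutrition disorders
hyperglycaemia	Metabolism and nutrition disorders
hypoglycaemia	Metabolism and nutrition disorders
hyponatraemia	Metabolism and nutrition disorders
dehydration	Metabolism and nutrition disorders
papilloedema	Eye disorders
optic disc oedema	Eye disorders
diplopia	Eye disorders
blindness	Eye disorders
vision blurred	Eye disorders
visual impairment	Eye disorders
photophobia	Eye disorders
jarisch-herxheimer reaction	Immune system disorders
anaphylactic reaction	Immune system disorders
hypersensitivity	Immune system disorders
sepsis	Infections and infestations
pneumonia	Infections and infestations
drug resistance	Infections and infestations
multiple drug resistance	Infections and infestations
cardiac arrest	Cardiac disorders
myocarditis	Cardiac disorders
acute kidney injury	Renal and urinary disorders
renal failure	Renal and urinary disorders
tinnitus	Ear and labyrinth disorders
vertigo	Ear and labyrinth disorders
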