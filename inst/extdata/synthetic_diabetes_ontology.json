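{
  "comment": "Synthetic mini-ontology fixture. Concepts and relations imitate the shape of published diabetes and study-design ontologies; content is hand-written for this package, not exported from any licensed ontology.",
  "concepts": [
    {"iri": "SDO:0001", "label": "Type2Diabetes", "definition": "Chronic metabolic disease characterized by insulin resistance and hyperglycemia.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0002", "label": "Obesity", "definition": "Excess adiposity, commonly indexed by body mass index above 30 kg/m2.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0003", "label": "Body Mass Index", "definition": "Weight in kilograms divided by the square of height in meters.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0004", "label": "Hypertension", "definition": "Persistently elevated arterial blood pressure; a cardiometabolic comorbidity.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0005", "label": "Physical activity frequency", "definition": "How often a person engages in vigorous or moderate exercise.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0006", "label": "Cigarette smoking", "definition": "Current use of combustible tobacco.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0007", "label": "Alcohol consumption", "definition": "Usual number of alcoholic drinks consumed per week.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0008", "label": "Depressive symptoms", "definition": "Self-reported frequency of depressed mood and anhedonia.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0009", "label": "Anxiety symptoms", "definition": "Self-reported frequency of worry and physiological arousal.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0010", "label": "Household income", "definition": "Total pre-tax income of the household, a socioeconomic determinant.", "source_ontology": "synthetic-study-design"},
    {"iri": "SDO:0011", "label": "Educational attainment", "definition": "Highest completed level of formal education.", "source_ontology": "synthetic-study-design"},
    {"iri": "SDO:0012", "label": "Antidiabetic medication", "definition": "Prescription drugs used to treat diabetes; a downstream marker of diagnosis.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0013", "label": "Waist circumference", "definition": "Abdominal girth, an index of central obesity.", "source_ontology": "synthetic-diabetes"},
    {"iri": "SDO:0014", "label": "Baseline demographic variable", "definition": "A study variable describing fixed participant characteristics at enrollment.", "source_ontology": "synthetic-study-design"},
    {"iri": "SDO:0015", "label": "Data collection artifact", "definition": "An administrative field produced by the survey process itself, without biomedical meaning.", "source_ontology": "synthetic-study-design"}
  ],
  "triples": [
    {"subject": "SDO:0001", "predicate": "hasRiskFactor", "object": "SDO:0002"},
    {"subject": "SDO:0001", "predicate": "hasRiskFactor", "object": "SDO:0004"},
    {"subject": "SDO:0001", "predicate": "hasRiskFactor", "object": "SDO:0006"},
    {"subject": "SDO:0002", "predicate": "isIndexedBy", "object": "SDO:0003"},
    {"subject": "SDO:0002", "predicate": "isIndexedBy", "object": "SDO:0013"},
    {"subject": "SDO:0005", "predicate": "reducesRiskOf", "object": "SDO:0001"},
    {"subject": "SDO:0008", "predicate": "isAssociatedWith", "object": "SDO:0001"},
    {"subject": "SDO:0009", "predicate": "isAssociatedWith", "object": "SDO:0001"},
    {"subject": "SDO:0010", "predicate": "modulatesAccessTo", "object": "SDO:0005"},
    {"subject": "SDO:0012", "predicate": "isDownstreamMarkerOf", "object": "SDO:0001"}
  ]
}
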