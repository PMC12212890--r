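{
  "version": "cinemort-lexicon-1.0.0",
  "comment": "Stem lexicon mapping colloquial death descriptions to the 13 NVSS leading-cause categories. Patterns are raw phrases; the loader tokenizes, removes stopwords, and stems them, yielding single-stem or stem-bigram patterns. 'other' is the fallback and carries no patterns. Tie-breaks use the NVSS table order (heart first).",
  "stopwords": ["a", "an", "the", "of", "in", "on", "at", "by", "to", "from", "with", "and", "or", "as", "is", "was", "were", "be", "been", "his", "her", "their", "its", "has", "had", "have", "after", "before", "during", "while", "into", "for"],
  "patterns": {
    "heart": ["heart attack", "heart failure", "heart disease", "cardiac arrest", "cardiac", "coronary", "myocardial infarction"],
    "cancer": ["cancer", "tumor", "tumour", "leukemia", "leukaemia", "lymphoma", "malignant neoplasm", "carcinoma"],
    "covid19": ["covid", "coronavirus"],
    "accidents": ["accident", "accidental", "accidentally", "car crash", "plane crash", "train crash", "drown", "drowns", "drowned", "drowning", "overdose", "overdoses", "electrocuted", "electrocution", "falls", "fell", "fatal fall"],
    "cerebrovascular": ["stroke", "aneurysm", "brain hemorrhage", "cerebral hemorrhage", "brain haemorrhage", "cerebrovascular"],
    "chronic_lower_respiratory": ["emphysema", "copd", "chronic bronchitis", "respiratory failure", "lung disease"],
    "alzheimer": ["alzheimer", "alzheimers", "dementia"],
    "diabetes": ["diabetes", "diabetic", "insulin shock"],
    "chronic_liver": ["cirrhosis", "liver failure", "liver disease"],
    "nephritis": ["nephritis", "kidney failure", "renal failure", "kidney disease"],
    "suicide": ["suicide", "suicidal", "kills himself", "kills herself", "hangs himself", "hangs herself", "shoots himself", "shoots herself", "poisons himself", "poisons herself"],
    "hypertension": ["hypertension", "hypertensive", "blood pressure"],
    "other": []
  }
}
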