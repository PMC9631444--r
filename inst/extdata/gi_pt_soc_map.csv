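pt,soc,primary_soc
Nausea,Gastrointestinal disorders,TRUE
Vomiting,Gastrointestinal disorders,TRUE
Diarrhea,Gastrointestinal disorders,TRUE
Constipation,Gastrointestinal disorders,TRUE
Abdominal pain upper,Gastrointestinal disorders,TRUE
Abdominal pain,Gastrointestinal disorders,TRUE
Pancreatitis,Gastrointestinal disorders,TRUE
Abdominal discomfort,Gastrointestinal disorders,TRUE
Abdominal distension,Gastrointestinal disorders,TRUE
Eructation,Gastrointestinal disorders,TRUE
Flatulence,Gastrointestinal disorders,TRUE
Dyspepsia,Gastrointestinal disorders,TRUE
Gastrooesophageal reflux disease,Gastrointestinal disorders,TRUE
Gastrointestinal disorder,Gastrointestinal disorders,TRUE
Dysgeusia,Gastrointestinal disorders,TRUE
Taste disorder,Gastrointestinal disorders,TRUE
Dry mouth,Gastrointestinal disorders,TRUE
Retching,Gastrointestinal disorders,TRUE
Hypophagia,Gastrointestinal disorders,TRUE
Pancreatitis acute,Gastrointestinal disorders,TRUE
Pancreatic carcinoma,"Neoplasms benign, malignant and unspecified",TRUE
Pancreatic carcinoma,Gastrointestinal disorders,FALSE
Impaired gastric emptying,Gastrointestinal disorders,TRUE
Hiccups,Gastrointestinal disorders,TRUE
Gastric disorder,Gastrointestinal disorders,TRUE
Ageusia,Gastrointestinal disorders,TRUE
Gastritis,Gastrointestinal disorders,TRUE
Gastrointestinal sounds abnormal,Gastrointestinal disorders,TRUE
Vomiting projectile,Gastrointestinal disorders,TRUE
Gastroenteritis viral,Infections and infestations,TRUE
Gastroenteritis viral,Gastrointestinal disorders,FALSE
Bowel movement irregularity,Gastrointestinal disorders,TRUE
Gastroenteritis,Infections and infestations,TRUE
Gastroenteritis,Gastrointestinal disorders,FALSE
Gastrointestinal pain,Gastrointestinal disorders,TRUE
Feces discolored,Gastrointestinal disorders,TRUE
Obstructive pancreatitis,Gastrointestinal disorders,TRUE
Paraesthesia oral,Gastrointestinal disorders,TRUE
Abnormal feces,Gastrointestinal disorders,TRUE
Pancreatic carcinoma metastatic,"Neoplasms benign, malignant and unspecified",TRUE
Pancreatic carcinoma metastatic,Gastrointestinal disorders,FALSE
Regurgitation,Gastrointestinal disorders,TRUE
Hypoaesthesia oral,Gastrointestinal disorders,TRUE
Appendicitis,Infections and infestations,TRUE
Appendicitis,Gastrointestinal disorders,FALSE
Epigastric discomfort,Gastrointestinal disorders,TRUE
Oropharyngeal discomfort,Gastrointestinal disorders,TRUE
Early satiety,Gastrointestinal disorders,TRUE
Feces soft,Gastrointestinal disorders,TRUE
Dry throat,Gastrointestinal disorders,TRUE
Diarrhoea,Gastrointestinal disorders,TRUE
Headache,Nervous system disorders,TRUE
Fatigue,General disorders and administration site conditions,TRUE
Dizziness,Nervous system disorders,TRUE
Rash,Skin and subcutaneous tissue disorders,TRUE
Arthralgia,Musculoskeletal and connective tissue disorders,TRUE
Insomnia,Psychiatric disorders,TRUE
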