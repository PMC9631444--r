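pt,serious_n,nonserious_n,test,statistic,p_printed
Nausea,545,1824,pearson-chi2,178.202,NA
Vomiting,470,868,pearson-chi2,4.862,0.027
Diarrhea,364,831,pearson-chi2,3.405,0.065
Pancreatitis,333,56,pearson-chi2,533.618,NA
Constipation,170,493,pearson-chi2,16.966,NA
Abdominal pain,163,235,pearson-chi2,13.393,NA
Abdominal pain upper,140,350,pearson-chi2,4.116,0.042
Eructation,75,245,pearson-chi2,13.180,NA
Flatulence,67,205,pearson-chi2,8.412,0.004
Abdominal distension,65,267,pearson-chi2,27.556,NA
Abdominal discomfort,57,283,pearson-chi2,41.717,NA
Pancreatitis acute,54,7,pearson-chi2,87.487,NA
Dyspepsia,49,188,pearson-chi2,16.212,NA
Gastrooesophageal reflux disease,47,120,pearson-chi2,1.606,0.205
Pancreatic carcinoma,46,3,pearson-chi2,84.205,NA
Gastrointestinal disorder,33,121,pearson-chi2,9.108,0.003
Hypophagia,29,35,pearson-chi2,4.704,0.03
Impaired gastric emptying,26,22,pearson-chi2,10.172,0.001
Gastritis,25,12,pearson-chi2,20.622,NA
Gastroenteritis,18,2,pearson-chi2,29.991,NA
Taste disorder,17,66,pearson-chi2,5.694,0.017
Dry mouth,17,57,pearson-chi2,3.208,0.073
Retching,15,51,pearson-chi2,3.004,0.083
Obstructive pancreatitis,15,1,pearson-chi2,27.215,NA
Dysgeusia,15,76,pearson-chi2,11.025,0.001
Pancreatic carcinoma metastatic,12,0,fisher-exact,NA,NA
Appendicitis,10,2,fisher-exact,NA,NA
Hiccups,9,38,pearson-chi2,3.941,0.047
Gastric disorder,9,33,pearson-chi2,2.432,0.119
Ageusia,9,32,pearson-chi2,2.158,0.142
Vomiting projectile,8,16,pearson-chi2,0.005,0.945
Gastroenteritis viral,7,16,pearson-chi2,0.053,0.819
Gastrointestinal pain,6,12,pearson-chi2,0.004,0.952
Feces discolored,6,11,pearson-chi2,0.053,0.817
Bowel movement irregularity,5,16,pearson-chi2,0.753,0.386
Epigastric discomfort,4,7,fisher-exact,NA,0.757
Gastrointestinal sounds abnormal,3,29,pearson-chi2,7.942,0.005
Dry throat,3,7,fisher-exact,NA,1.000
Abnormal feces,3,11,fisher-exact,NA,0.569
Feces soft,2,8,fisher-exact,NA,0.514
Early satiety,2,8,fisher-exact,NA,0.514
Regurgitation,1,11,fisher-exact,NA,0.119
Paraesthesia oral,1,13,fisher-exact,NA,0.046
Hypoaesthesia oral,1,11,fisher-exact,NA,0.119
Oropharyngeal discomfort,0,11,fisher-exact,NA,0.020
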