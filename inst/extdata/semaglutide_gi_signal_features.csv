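pt,n_reports,ror025,deaths,dme_ime,evidence,score,band
Nausea,2369,7.20,0,none,++,6,moderate
Vomiting,1338,6.33,3,none,++,6,moderate
Diarrhea,1195,3.50,0,none,++,5,moderate
Constipation,663,5.75,0,none,++,6,moderate
Abdominal pain upper,490,4.53,2,none,++,5,moderate
Abdominal pain,398,3.28,1,none,++,5,moderate
Pancreatitis,389,18.29,2,DME,++,8,strong
Abdominal discomfort,340,3.24,0,none,++,5,moderate
Abdominal distension,332,6.14,1,none,++,6,moderate
Eructation,320,42.03,0,none,++,6,moderate
Flatulence,272,9.28,0,none,++,6,moderate
Dyspepsia,237,4.76,0,none,++,5,moderate
Gastrooesophageal reflux disease,167,3.65,0,none,++,5,moderate
Gastrointestinal disorder,154,3.03,1,none,++,5,moderate
Dysgeusia,91,2.84,0,IME,++,6,moderate
Taste disorder,83,5.02,0,IME,++,7,moderate
Dry mouth,74,1.63,0,none,-,2,weak
Retching,66,5.42,0,none,++,6,moderate
Hypophagia,64,3.93,0,none,-,3,weak
Pancreatitis acute,61,4.52,1,DME,++,7,moderate
Pancreatic carcinoma,49,1.31,7,none,++,3,weak
Impaired gastric emptying,48,8.88,0,IME,+,5,moderate
Hiccups,47,9.83,0,none,++,5,moderate
Gastric disorder,42,1.26,0,none,++,3,weak
Ageusia,41,2.45,0,IME,+,4,weak
Gastritis,37,2.21,0,IME,++,5,moderate
Gastrointestinal sounds abnormal,32,9.99,0,none,-,3,weak
Vomiting projectile,24,13.29,0,none,+,4,weak
Gastroenteritis viral,23,1.74,0,IME,+,3,weak
Bowel movement irregularity,21,3.14,0,none,-,2,weak
Gastroenteritis,20,1.77,0,IME,+,3,weak
Gastrointestinal pain,18,1.97,0,none,+,2,weak
Feces discolored,17,1.03,0,none,-,1,weak
Obstructive pancreatitis,16,18.81,0,IME,+,5,moderate
Paraesthesia oral,14,1.20,0,IME,-,2,weak
Abnormal feces,14,1.85,0,none,-,1,weak
Pancreatic carcinoma metastatic,12,5.62,3,IME,-,5,moderate
Regurgitation,12,5.03,0,none,+,4,weak
Hypoaesthesia oral,12,1.01,0,IME,-,2,weak
Appendicitis,12,1.46,0,none,-,1,weak
Epigastric discomfort,11,2.78,0,none,+,3,weak
Oropharyngeal discomfort,11,1.12,0,none,-,1,weak
Early satiety,10,8.23,0,none,-,3,weak
Feces soft,10,1.25,0,none,-,1,weak
Dry throat,10,1.08,0,none,-,1,weak
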