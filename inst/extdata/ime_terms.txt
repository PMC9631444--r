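# important medical events (toy excerpt)
Dysgeusia
Taste disorder
Impaired gastric emptying
Ageusia
Gastritis
Gastroenteritis viral
Gastroenteritis
Obstructive pancreatitis
Paraesthesia oral
Pancreatic carcinoma metastatic
Hypoaesthesia oral
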