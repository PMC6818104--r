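cause_label,broad_group
HIV/AIDS related death,infections
Pulmonary tuberculosis,infections
Acute respiratory infection incl. pneumonia,infections
Diarrhoeal diseases,infections
Malaria,infections
Meningitis and encephalitis,infections
Digestive neoplasms,cancer
Respiratory neoplasms,cancer
Breast neoplasms,cancer
Reproductive neoplasms MF,cancer
Other and unspecified neoplasms,cancer
Acute cardiac disease,cardiovascular
Stroke,cardiovascular
Other and unspecified cardiac disease,cardiovascular
Diabetes mellitus,other_ncd
Chronic obstructive pulmonary disease,other_ncd
Renal failure,other_ncd
Liver cirrhosis,other_ncd
Epilepsy,other_ncd
Road traffic accident,injuries
Assault,injuries
Accidental drowning and submersion,injuries
Accidental fall,injuries
Intentional self-harm,injuries
Obstetric haemorrhage,pregnancy_neonatal
Pregnancy-induced hypertension,pregnancy_neonatal
Neonatal sepsis,pregnancy_neonatal
Prematurity,pregnancy_neonatal
Birth asphyxia,pregnancy_neonatal
Indeterminate,indeterminate
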