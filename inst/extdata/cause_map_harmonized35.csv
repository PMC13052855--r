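detailed,harmonized35,who15,broad6
Acute respiratory infection incl pneumonia,Acute respiratory infection incl pneumonia,Infectious and parasitic diseases,Other communicable
Sepsis (non-obstetric),Sepsis (non-obstetric),Infectious and parasitic diseases,Other communicable
Diarrhoeal diseases,Diarrhoeal diseases,Infectious and parasitic diseases,Other communicable
Malaria,Malaria,Infectious and parasitic diseases,Other communicable
Meningitis and encephalitis,Meningitis and encephalitis,Infectious and parasitic diseases,Other communicable
Other and unspecified infectious diseases,Other and unspecified infectious diseases,Infectious and parasitic diseases,Other communicable
HIV/AIDS related death,HIV/AIDS related death,HIV/TB-related,HIV/TB-related
Pulmonary tuberculosis,Pulmonary tuberculosis,HIV/TB-related,HIV/TB-related
Oral neoplasms,Oral neoplasms,Neoplasms,Non-communicable
Digestive neoplasms,Digestive neoplasms,Neoplasms,Non-communicable
Respiratory neoplasms,Respiratory neoplasms,Neoplasms,Non-communicable
Breast neoplasms,Breast neoplasms,Neoplasms,Non-communicable
Reproductive neoplasms,Reproductive neoplasms,Neoplasms,Non-communicable
Other and unspecified neoplasms,Other and unspecified neoplasms,Neoplasms,Non-communicable
Severe malnutrition,Severe malnutrition,Nutritional and endocrine disorders,Non-communicable
Diabetes mellitus,Diabetes mellitus,Nutritional and endocrine disorders,Non-communicable
Acute cardiac disease,Acute cardiac disease,Circulatory system diseases,Non-communicable
Stroke,Stroke,Circulatory system diseases,Non-communicable
Other and unspecified cardiac disease,Other and unspecified cardiac disease,Circulatory system diseases,Non-communicable
Chronic obstructive pulmonary disease,Chronic obstructive pulmonary disease,Respiratory disorders,Non-communicable
Asthma,Asthma,Respiratory disorders,Non-communicable
Acute abdomen,Acute abdomen,Gastrointestinal disorders,Non-communicable
Liver cirrhosis,Liver cirrhosis,Gastrointestinal disorders,Non-communicable
Renal failure,Renal failure,Renal disorders,Non-communicable
Epilepsy,Epilepsy,Nervous system disorders,Non-communicable
Other and unspecified NCD,Other and unspecified NCD,Other and unspecified NCD,Non-communicable
Abortion-related death,Abortion-related death,Pregnancy and childbirth,Maternal
Pregnancy-induced hypertension,Pregnancy-induced hypertension,Pregnancy and childbirth,Maternal
Obstetric haemorrhage,Obstetric haemorrhage,Pregnancy and childbirth,Maternal
Pregnancy-related sepsis,Pregnancy-related sepsis,Pregnancy and childbirth,Maternal
Road traffic accident,Road traffic accident,Transport accidents,External
Accidental fall,Accidental fall,Other external causes,External
Assault,Assault,Intentional injuries,External
Intentional self-harm,Intentional self-harm,Intentional injuries,External
undetermined,undetermined,undetermined,undetermined
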