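code,short_title
038.9,Unspecified septicemia
518.81,Acute respiratory failure
785.52,Septic shock
584.9,Acute kidney failure unspecified
995.92,Severe sepsis
995.91,Sepsis
427.31,Atrial fibrillation
428.0,Congestive heart failure unspecified
486,Pneumonia organism unspecified
599.0,Urinary tract infection site not specified
401.9,Unspecified essential hypertension
276.2,Acidosis
250.0,Diabetes mellitus without mention of complication
414.01,Coronary atherosclerosis of native coronary artery
410.71,Subendocardial infarction initial episode
493.90,Asthma unspecified
511.9,Unspecified pleural effusion
585.9,Chronic kidney disease unspecified
593.9,Unspecified disorder of kidney and ureter
285.9,Anemia unspecified
305.1,Tobacco use disorder
311,Depressive disorder not elsewhere classified
530.81,Esophageal reflux
715.90,Osteoarthrosis unspecified site
780.60,Fever unspecified
550.12,Unilateral inguinal hernia with obstruction recurrent
550.13,Bilateral inguinal hernia with obstruction
541,Appendicitis unqualified
V58.61,Long-term (current) use of anticoagulants
E878.8,Other specified surgical operations as cause of abnormal reaction
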