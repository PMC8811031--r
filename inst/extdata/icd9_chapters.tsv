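start	end	label
001	139	Infectious and parasitic diseases
140	239	Neoplasms
240	279	Endocrine, nutritional and metabolic diseases, and immunity disorders
280	289	Diseases of the blood and blood-forming organs
290	319	Mental disorders
320	389	Diseases of the nervous system and sense organs
390	459	Diseases of the circulatory system
460	519	Diseases of the respiratory system
520	579	Diseases of the digestive system
580	629	Diseases of the genitourinary system
630	679	Complications of pregnancy, childbirth, and the puerperium
680	709	Diseases of the skin and subcutaneous tissue
710	739	Diseases of the musculoskeletal system and connective tissue
740	759	Congenital anomalies
760	779	Certain conditions originating in the perinatal period
780	799	Symptoms, signs, and ill-defined conditions
800	999	Injury and poisoning
V01	V91	Supplementary classification of factors influencing health status and contact with health services
E000	E999	Supplementary classification of external causes of injury and poisoning
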