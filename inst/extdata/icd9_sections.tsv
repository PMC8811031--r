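start	end	label
001	009	Intestinal infectious diseases
010	019	Tuberculosis
020	029	Zoonotic bacterial diseases
030	041	Other bacterial diseases
042	044	Human immunodeficiency virus (HIV) infection
045	049	Poliomyelitis and other non-arthropod-borne viral diseases of central nervous system
050	059	Viral diseases accompanied by exanthem
060	069	Arthropod-borne viral diseases
070	079	Other diseases due to viruses and Chlamydiae
080	089	Rickettsioses and other arthropod-borne diseases
090	099	Syphilis and other venereal diseases
100	109	Other spirochetal diseases
110	119	Mycoses
120	129	Helminthiases
130	136	Other infectious and parasitic diseases
137	139	Late effects of infectious and parasitic diseases
140	149	Malignant neoplasm of lip, oral cavity, and pharynx
150	159	Malignant neoplasm of digestive organs and peritoneum
160	169	Malignant neoplasm of respiratory and intrathoracic organs
170	176	Malignant neoplasm of bone, connective tissue, skin, and breast
177	189	Malignant neoplasm of genitourinary organs
190	199	Malignant neoplasm of other and unspecified sites
200	208	Malignant neoplasm of lymphatic and hematopoietic tissue
209	209	Neuroendocrine tumors
210	229	Benign neoplasms
230	234	Carcinoma in situ
235	238	Neoplasms of uncertain behavior
239	239	Neoplasms of unspecified nature
240	246	Disorders of thyroid gland
247	259	Diseases of other endocrine glands
260	269	Nutritional deficiencies
270	279	Other metabolic and immunity disorders
280	289	Diseases of the blood and blood-forming organs
290	294	Organic psychotic conditions
295	299	Other psychoses
300	316	Neurotic disorders, personality disorders, and other nonpsychotic mental disorders
317	319	Intellectual disabilities
320	327	Inflammatory and other diseases of the central nervous system
328	337	Hereditary and degenerative diseases of the central nervous system
338	338	Pain
339	339	Other headache syndromes
340	349	Other disorders of the central nervous system
350	359	Disorders of the peripheral nervous system
360	379	Disorders of the eye and adnexa
380	389	Diseases of the ear and mastoid process
390	392	Acute rheumatic fever
393	398	Chronic rheumatic heart disease
399	405	Hypertensive disease
406	414	Ischemic heart disease
415	417	Diseases of pulmonary circulation
418	429	Other forms of heart disease
430	438	Cerebrovascular disease
439	449	Diseases of arteries, arterioles, and capillaries
450	459	Diseases of veins and lymphatics, and other diseases of circulatory system
460	469	Acute respiratory infections
470	478	Other diseases of the upper respiratory tract
479	488	Pneumonia and influenza
489	496	Chronic obstructive pulmonary disease and allied conditions
497	508	Pneumoconioses and other lung diseases due to external agents
509	519	Other diseases of respiratory system
520	529	Diseases of oral cavity, salivary glands, and jaws
530	539	Diseases of esophagus, stomach, and duodenum
540	543	Appendicitis
544	553	Hernia of abdominal cavity
554	558	Noninfectious enteritis and colitis
559	569	Other diseases of intestines and peritoneum
570	579	Other diseases of digestive system
580	589	Nephritis, nephrotic syndrome, and nephrosis
590	599	Other diseases of urinary system
600	608	Diseases of male genital organs
609	612	Disorders of breast
613	616	Inflammatory disease of female pelvic organs
617	629	Other disorders of female genital tract
630	639	Ectopic and molar pregnancy and pregnancy with abortive outcome
640	649	Complications mainly related to pregnancy
650	659	Normal delivery, and other indications for care in pregnancy, labor, and delivery
660	669	Complications occurring mainly in the course of labor and delivery
670	677	Complications of the puerperium
678	679	Other maternal and fetal complications
680	686	Infections of skin and subcutaneous tissue
687	698	Other inflammatory conditions of skin and subcutaneous tissue
699	709	Other diseases of skin and subcutaneous tissue
710	719	Arthropathies and related disorders
720	724	Dorsopathies
725	729	Rheumatism, excluding the back
730	739	Osteopathies, chondropathies, and acquired musculoskeletal deformities
740	759	Congenital anomalies
760	763	Maternal causes of perinatal morbidity and mortality
764	779	Other conditions originating in the perinatal period
780	789	Symptoms
790	796	Nonspecific abnormal findings
797	799	Ill-defined and unknown causes of morbidity and mortality
800	804	Fracture of skull
805	809	Fracture of neck and trunk
810	819	Fracture of upper limb
820	829	Fracture of lower limb
830	839	Dislocation
840	848	Sprains and strains of joints and adjacent muscles
849	854	Intracranial injury, excluding those with skull fracture
855	869	Internal injury of thorax, abdomen, and pelvis
870	879	Open wound of head, neck, and trunk
880	887	Open wound of upper limb
888	897	Open wound of lower limb
898	904	Injury to blood vessels
905	909	Late effects of injuries, poisonings, toxic effects, and other external causes
910	919	Superficial injury
920	924	Contusion with intact skin surface
925	929	Crushing injury
930	939	Effects of foreign body entering through orifice
940	949	Burns
950	957	Injury to nerves and spinal cord
958	959	Certain traumatic complications and unspecified injuries
960	979	Poisoning by drugs, medicinal and biological substances
980	989	Toxic effects of substances chiefly nonmedicinal as to source
990	995	Other and unspecified effects of external causes
996	999	Complications of surgical and medical care, not elsewhere classified
V01	V09	Persons with potential health hazards related to communicable diseases
V10	V19	Persons with potential health hazards related to personal and family history
V20	V29	Persons encountering health services in circumstances related to reproduction and development
V30	V39	Liveborn infants according to type of birth
V40	V49	Persons with a condition influencing their health status
V50	V59	Persons encountering health services for specific procedures and aftercare
V60	V69	Persons encountering health services in other circumstances
V70	V82	Persons without reported diagnosis encountered during examination and investigation
V83	V84	Genetics
V85	V85	Body mass index
V86	V86	Estrogen receptor status
V87	V88	Other specified personal exposures, and acquired absence of organ
V89	V89	Other suspected conditions not found
V90	V90	Retained foreign body
V91	V91	Multiple gestation placenta status
E000	E000	External cause status
E001	E030	Activity
E031	E799	Other and unspecified transport and environmental circumstances
E800	E807	Railway accidents
E808	E819	Motor vehicle traffic accidents
E820	E825	Motor vehicle nontraffic accidents
E826	E829	Other road vehicle accidents
E830	E838	Water transport accidents
E839	E845	Air and space transport accidents
E846	E849	Vehicle accidents not elsewhere classifiable
E850	E858	Accidental poisoning by drugs, medicinal substances, and biologicals
E859	E869	Accidental poisoning by other solid and liquid substances, gases, and vapors
E870	E876	Misadventures to patients during surgical and medical care
E877	E879	Surgical and medical procedures as the cause of abnormal reaction of patient
E880	E888	Accidental falls
E889	E899	Accidents caused by fire and flames
E900	E909	Accidents due to natural and environmental factors
E910	E915	Accidents caused by submersion, suffocation, and foreign bodies
E916	E928	Other accidents
E929	E929	Late effects of accidental injury
E930	E949	Drugs, medicinal and biological substances causing adverse effects in therapeutic use
E950	E959	Suicide and self-inflicted injury
E960	E969	Homicide and injury purposely inflicted by other persons
E970	E979	Legal intervention
E980	E989	Injury undetermined whether accidentally or purposely inflicted
E990	E999	Injury resulting from operations of war
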