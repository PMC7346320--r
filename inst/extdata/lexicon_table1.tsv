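# Clinician-curated evidence-phrase lexicon for cardiogenic stroke
# columns: surface<TAB>etype<TAB>provenance
# seed: phrases summarized by ultrasound clinicians (27 phrases, 20 evidence classes)
# harvested: additional surface forms matched by regex expansion of the seeds
# manual: potential-evidence phrases, the compound aortic+mitral phrase, and abbreviations
左心房附壁血栓	mural_thrombus	seed
左心室附壁血栓	mural_thrombus	seed
心肌梗死	myocardial_infarction	seed
节段性室壁运动异常	myocardial_infarction	seed
室壁瘤	ventricular_aneurysm	seed
扩张型心肌病	dilated_cardiomyopathy	seed
植入术	prosthetic_valve	seed
置换术	prosthetic_valve	seed
感染性心内膜炎	valvular_endocarditis	seed
肿物	intracardiac_mass	seed
团块	intracardiac_mass	seed
回声团	intracardiac_mass	seed
粘液瘤	myxoma	seed
纤维瘤	papillary_fibroelastoma	seed
射血分数低	low_ejection_fraction	seed
心尖运动减弱	apex_dyskinesia	seed
自显影	spontaneous_echo_contrast	seed
二尖瓣狭窄	mitral_stenosis	seed
二尖瓣脱垂	mitral_prolapse	seed
二尖瓣钙化	mitral_calcification	seed
二尖瓣退行性改变	mitral_calcification	seed
主动脉瓣钙化	aortic_calcification	seed
主动脉瓣退行性改变	aortic_calcification	seed
巨大Lambl's赘生物	lambl_excrescence	seed
房间隔瘤	atrial_septal_aneurysm	seed
房间隔缺损	atrial_septal_defect	seed
充血性心力衰竭	congestive_heart_failure	seed
心梗	myocardial_infarction	harvested
节段性左室壁运动异常	myocardial_infarction	harvested
扩张性心肌病	dilated_cardiomyopathy	harvested
置入术	prosthetic_valve	harvested
置换	prosthetic_valve	harvested
心尖运动略减弱	apex_dyskinesia	harvested
二尖瓣轻度狭窄	mitral_stenosis	harvested
二尖瓣中度狭窄	mitral_stenosis	harvested
二尖瓣重度狭窄	mitral_stenosis	harvested
二尖瓣轻度脱垂	mitral_prolapse	harvested
二尖瓣前叶脱垂	mitral_prolapse	harvested
二尖瓣后叶脱垂	mitral_prolapse	harvested
二尖瓣退行性变	mitral_calcification	harvested
主动脉瓣退行性变	aortic_calcification	harvested
心脏增大	cardiac_enlargement	manual
室壁运动减弱	wall_hypokinesis	manual
心脏收缩功能减弱	systolic_dysfunction	manual
主动脉瓣、二尖瓣钙化	aortic_mitral_calcification	manual
主动脉瓣,二尖瓣钙化	aortic_mitral_calcification	manual
左室附壁血栓	mural_thrombus	manual
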