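# Regex harvest patterns: pattern<TAB>etype
# [\u4e00-\u9fa5] is the CJK-character wildcard class
二尖瓣[\u4e00-\u9fa5]*狭窄	mitral_stenosis
二尖瓣[\u4e00-\u9fa5]*脱垂	mitral_prolapse
二尖瓣退行性[\u4e00-\u9fa5]*变	mitral_calcification
主动脉瓣[\u4e00-\u9fa5]*钙化	aortic_calcification
心尖运动[\u4e00-\u9fa5]*减弱	apex_dyskinesia
节段性[\u4e00-\u9fa5]*运动异常	myocardial_infarction
扩张[\u4e00-\u9fa5]*心肌病	dilated_cardiomyopathy
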