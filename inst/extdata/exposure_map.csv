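field,organ
supra_diaphragmatic,breast
supra_diaphragmatic,heart
supra_diaphragmatic,lung
supra_diaphragmatic,thyroid
supra_diaphragmatic,esophagus
cervical,thyroid
cervical,salivary_glands
cervical,carotid
cervical,esophagus
cranial,brain
cranial,pituitary
cranial,lens
cranial,eye
cranial,ear
cranial,skin
abdominal,kidney
abdominal,liver
abdominal,bowel
abdominal,stomach
abdominal,pancreas
abdominal,spleen
abdominal,ovary
abdominal,uterus
pelvic,bladder
pelvic,bowel
pelvic,ovary
pelvic,uterus
pelvic,testis
pelvic,bone
spinal,bone
spinal,soft_tissue
spinal,esophagus
TBI,*
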