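code,system,label
breast,reproductive,Breast / mammary gland
heart,cardiovascular,Heart
lung,respiratory,Lung
thyroid,endocrine,Thyroid gland
salivary_glands,digestive,Salivary glands
carotid,cardiovascular,Carotid arteries
brain,nervous,Brain
pituitary,endocrine,Pituitary gland
lens,eye,Ocular lens
eye,eye,Eye
ear,auditory,Inner / middle ear
kidney,urinary,Kidney
bladder,urinary,Bladder
liver,digestive,Liver
bowel,digestive,Bowel
stomach,digestive,Stomach
esophagus,digestive,Esophagus
pancreas,endocrine,Pancreas
spleen,immune,Spleen
ovary,reproductive,Ovary
uterus,reproductive,Uterus
testis,reproductive,Testis
bone,musculoskeletal,Bone
soft_tissue,musculoskeletal,Soft tissue
skin,skin,Skin
bone_marrow,hematologic,Bone marrow
oral_mucosa,digestive,Oral mucosa
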