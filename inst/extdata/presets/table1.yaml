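# Cohort preset calibrated to the registered-cohort profile (n = 2558).
# Probabilities are count-derived at full precision where counts exist.
name: table1
n: 2558
seed: 20240125
disease_probs:
  leukemia: 0.283033620015637
  cerebral_tumor: 0.197810789679437
  lymphoma:  0.1704456606724
  sarcoma: 0.125879593432369
  kidney_tumor: 0.0609851446442533
  neuroblastoma: 0.0598123534010946
  other: 0.0437842064112588
  rare_tumor: 0.0414386239249414
  extra_cerebral_germ_cell_tumor: 0.0168100078186083
sex_prob_male: 0.544175136825645
age_mean: 8.34
age_range: [0.0, 23.2]
age_shape: 1.6
p_surgery:  0.4147771696638
p_medical_treatment: 0.870992963252541
p_radiotherapy: 0.204456606724003
p_rt_and_medical: 0.186
p_surgery_only: 0.161
p_autotransplant: 0.0355746677091478
p_allograft: 0.0383111806098514
p_simple_monitoring: 0.0379202501954652
p_tumor_bank: 0.6654
p_recurrence:  0.1278342455043
p_second_cancer: 0.0156372165754496
p_third_cancer_given_second: 0.1
p_predisposition: 0.1
p_allograft_second_line: 0.143730886850153
p_dosimetry: 0.5
p_retrospective_era: 0.0461297888975762
recurrence_disease_weights:
  leukemia:            0.238
  cerebral_tumor:            0.333
  lymphoma: 0.117017892644135
  sarcoma:            0.159
  kidney_tumor: 0.041868787276342
  neuroblastoma: 0.0410636182902585
  other: 0.0300596421471173
  rare_tumor: 0.0284493041749503
  extra_cerebral_germ_cell_tumor: 0.0115407554671968
second_cancer_type_weights:
  sarcoma: 0.275
  cerebral_tumor: 0.25
  leukemia: 0.15
  lymphoma: 0.125
  other: 0.125
  rare_tumor: 0.075
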