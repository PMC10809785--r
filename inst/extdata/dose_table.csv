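protocol,arm,agent,cumulative_dose,units
ALL01,standard,daunorubicin,100,mg/m2
ALL01,standard,vincristine,12,mg/m2
ALL01,standard,cyclophosphamide,2000,mg/m2
ALL01,standard,methotrexate,25000,mg/m2
ALL01,standard,cytarabine,900,mg/m2
ALL01,high_risk,daunorubicin,240,mg/m2
ALL01,high_risk,vincristine,18,mg/m2
ALL01,high_risk,cyclophosphamide,4000,mg/m2
ALL01,high_risk,methotrexate,33000,mg/m2
ALL01,high_risk,cytarabine,12000,mg/m2
ALL01,high_risk,etoposide,900,mg/m2
LYMPH02,standard,doxorubicin,200,mg/m2
LYMPH02,standard,bleomycin,60,mg/m2
LYMPH02,standard,vinblastine,36,mg/m2
LYMPH02,standard,dacarbazine,1500,mg/m2
LYMPH02,intensified,doxorubicin,300,mg/m2
LYMPH02,intensified,cyclophosphamide,4800,mg/m2
LYMPH02,intensified,etoposide,1200,mg/m2
LYMPH02,intensified,procarbazine,4200,mg/m2
SARC03,vdc_ie,doxorubicin,375,mg/m2
SARC03,vdc_ie,cyclophosphamide,8400,mg/m2
SARC03,vdc_ie,ifosfamide,54000,mg/m2
SARC03,vdc_ie,etoposide,2500,mg/m2
SARC03,vdc_ie,vincristine,14,mg/m2
OSTEO04,map,cisplatin,480,mg/m2
OSTEO04,map,doxorubicin,450,mg/m2
OSTEO04,map,methotrexate,72000,mg/m2
NEURO05,induction,cisplatin,320,mg/m2
NEURO05,induction,carboplatin,1500,mg/m2
NEURO05,induction,cyclophosphamide,4200,mg/m2
NEURO05,induction,etoposide,1200,mg/m2
NEURO05,induction,vincristine,9,mg/m2
WILMS06,avd,vincristine,22,mg/m2
WILMS06,avd,dactinomycin,6.75,mg/m2
WILMS06,avd,doxorubicin,150,mg/m2
GERM07,bep,cisplatin,400,mg/m2
GERM07,bep,etoposide,1500,mg/m2
GERM07,bep,bleomycin,270,mg/m2
BRAIN08,pcv_like,carboplatin,1750,mg/m2
BRAIN08,pcv_like,vincristine,9,mg/m2
BRAIN08,pcv_like,lomustine,440,mg/m2
HDC09,busmel,busulfan,12.8,mg/kg
HDC09,busmel,melphalan,140,mg/m2
RARE10,platinum_based,cisplatin,300,mg/m2
RARE10,platinum_based,etoposide,900,mg/m2
RARE10,platinum_based,ifosfamide,27000,mg/m2
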