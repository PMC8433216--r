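patient_id,age,gleason,psa_ng_ml,group,blood_ml,epcam,psa,psma
P1,65,6 (3+3),<10,localized,3,5,6,5
P2,66,6 (3+3),4.8,localized,3,9,2,5
P3,61,6 (3+3),7.0,localized,3,9,2,6
P4,64,7 (3+4),0.1,localized,1,1,,
P5,64,7 (3+4),>50,metastatic,1,10,,
P6,72,10 (5+5),>100,metastatic,1,15,,
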