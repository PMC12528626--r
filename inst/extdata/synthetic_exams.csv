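exam_id,patient_id,age,psa,facility,biopsy_status,pirads,confirmed,cspca,dominant_zone,exam_iq,iq_source
E00001,P00001,59.3,4.2,III,prev_benign,1,FALSE,FALSE,none,optimal,model
E00002,P00002,56.9,8.9,III,prev_benign,3,TRUE,FALSE,PZ,moderate,radiologist
E00003,P00003,66.5,5.3,I,unknown,1,FALSE,FALSE,none,mild,model
E00004,P00004,61.5,5.8,I,naive,1,TRUE,FALSE,none,moderate,model
E00005,P00005,62.1,3.1,III,prev_benign,2,FALSE,FALSE,none,optimal,model
E00006,P00006,59.4,,I,naive,3,TRUE,FALSE,PZ,optimal,model
E00007,P00007,63.6,6.5,I,unknown,1,FALSE,FALSE,none,moderate,radiologist
E00008,P00008,63.6,16.4,II,prev_benign,4,TRUE,TRUE,PZ,mild,model
E00009,P00009,44.1,15,I,unknown,4,TRUE,TRUE,TZ,mild,model
E00010,P00010,76.8,6.5,III,prev_benign,3,TRUE,TRUE,TZ,optimal,model
E00011,P00011,70.7,8.7,I,prev_benign,1,TRUE,FALSE,none,optimal,model
E00012,P00012,67.3,14.9,III,prev_benign,2,FALSE,FALSE,none,optimal,model
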