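target_kind,name
concentration,Climatic variables
concentration,Animal activity
concentration,Diet
concentration,Climatic variables and animal activity
concentration,Climatic variables and diet
concentration,Diet and animal activity
concentration,"Climatic variables, animal activity and diet"
emission,Concentrations
emission,Climatic variables
emission,Animal activity
emission,Diet
emission,Concentrations and climatic variables
emission,Concentrations and animal activity
emission,Concentrations and diet
emission,Climatic variables and animal activity
emission,Climatic variables and diet
emission,Animal activity and diet
emission,"Concentrations, climatic variables and animal activity"
emission,"Concentrations, climatic variables and diet"
emission,"Concentrations, animal activity and diet"
emission,"Climatic variables, animal activity and diet"
emission,"Concentrations, climatic variables, animal activity and diet"
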