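"unit_id","event_label","n_events","responsive","direction","supra_bins","peak_z","peak_latency_s","excluded","reason"
"demo_u001","CS_ON",6,TRUE,"excited","1,2,3,4,5",9.75807358037435,0,FALSE,NA
"demo_u001","FREEZE_ON",8,FALSE,"none","",1.81838437606861,0.4,FALSE,NA
"demo_u001","FREEZE_OFF",7,TRUE,"inhibited","1,5",4.74341649025257,0.1,FALSE,NA
"demo_u002","CS_ON",6,TRUE,"excited","1,2,3,4,5",9.86076139984207,0,FALSE,NA
"demo_u002","FREEZE_ON",12,TRUE,"excited","3,4",2.62247182836461,0.3,FALSE,NA
"demo_u002","FREEZE_OFF",11,FALSE,"none","",-1.36310840219296,0.4,FALSE,NA
"demo_u003","CS_ON",6,TRUE,"excited","3,5",-2.44948974278318,0,FALSE,NA
"demo_u003","FREEZE_ON",8,FALSE,"none","",1.54348726628258,0.4,FALSE,NA
"demo_u003","FREEZE_OFF",8,FALSE,"none","",-1.75406504612757,0.1,FALSE,NA
"demo_u004","CS_ON",6,FALSE,"none","",-1.52127765851133,0,FALSE,NA
"demo_u004","FREEZE_ON",11,FALSE,"none","",-1.56337444359079,0.4,FALSE,NA
"demo_u004","FREEZE_OFF",10,TRUE,"excited","1,2,3,4,5",12.2454377736632,0.2,FALSE,NA
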