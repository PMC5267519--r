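compound,cmax_ub_um,observed_auc_pct,substrate_class,in_calibration_set,category
Rifampicin,NA,97,midazolam,TRUE,strong
Phenytoin,NA,94,midazolam,TRUE,strong
Carbamazepine,NA,94,midazolam,TRUE,strong
Phenobarbital,NA,61,nonmidazolam,FALSE,moderate_weak
Pioglitazone,NA,26,midazolam,TRUE,moderate_weak
Terbinafine,NA,25,midazolam,TRUE,moderate_weak
Sulfinpyrazone,NA,22,nonmidazolam,FALSE,moderate_weak
Probenecid,28,20,nonmidazolam,FALSE,moderate_weak
Dexamethasone,NA,19,nonmidazolam,FALSE,noninducer
Nifedipine,NA,4,midazolam,TRUE,noninducer
Omeprazole,NA,-25,nonmidazolam,FALSE,noninducer
Rosiglitazone,NA,12,nonmidazolam,FALSE,noninducer
Clotrimazole,NA,9.7,nonmidazolam,FALSE,noninducer
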