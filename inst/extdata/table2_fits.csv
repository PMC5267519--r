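compound,conc_low_um,conc_high_um,lot,status,r_squared,e_max,ec50_um,max_fold_induction
Rifampicin,0.01,50,2B,fit,0.98,22,0.36,NA
Rifampicin,0.01,50,3A,fit,0.96,28,0.27,NA
Rifampicin,0.01,50,3B,fit,0.98,26,0.52,NA
Phenytoin,0.6,120,2B,fit,1.00,23,15,NA
Phenytoin,0.6,120,3A,fit,1.00,38,16,NA
Phenytoin,0.6,120,3B,fit,0.99,35,23,NA
Carbamazepine,0.23,500,2B,fit,1.00,16,108,NA
Carbamazepine,0.23,500,3A,fit,1.00,10,65,NA
Carbamazepine,0.23,500,3B,fit,0.98,14,53,NA
Phenobarbital,0.91,2000,2B,fit,1.00,110,558,NA
Phenobarbital,0.91,2000,3A,fit,1.00,135,728,NA
Phenobarbital,0.91,2000,3B,fit,1.00,73,775,NA
Terbinafine,0.05,100,2B,fit,1.00,20,3.6,NA
Terbinafine,0.05,100,3A,fit,1.00,24,2.2,NA
Terbinafine,0.05,100,3B,fit,0.99,21,2.7,NA
Sulfinpyrazone,0.09,200,2B,fit,1.00,31,23,NA
Sulfinpyrazone,0.09,200,3A,fit,0.98,53,28,NA
Sulfinpyrazone,0.09,200,3B,fit,0.98,38,32,NA
Probenecid,0.13,300,2B,fit,1.00,25,187,NA
Probenecid,0.13,300,3A,fit,1.00,26,176,NA
Probenecid,0.13,300,3B,fit,1.00,22,195,NA
Pioglitazone,0.006,12.5,2B,fit,0.99,33,3.3,NA
Pioglitazone,0.006,12.5,3A,fit,0.99,31,2.3,NA
Pioglitazone,0.006,12.5,3B,fit,0.98,15,2.0,NA
Dexamethasone,0.11,250,2B,fit,1.00,32,139,NA
Dexamethasone,0.11,250,3A,fit,1.00,53,117,NA
Dexamethasone,0.11,250,3B,fit,1.00,29,134,NA
Rosiglitazone,0.05,100,2B,fit,0.99,49,3.8,NA
Rosiglitazone,0.05,100,3A,fit,1.00,85,4.3,NA
Rosiglitazone,0.05,100,3B,fit,1.00,95,4,NA
Omeprazole,0.05,100,2B,fit,1.00,24,13,NA
Omeprazole,0.05,100,3A,fit,1.00,45,23,NA
Omeprazole,0.05,100,3B,fit,1.00,27,13,NA
Clotrimazole,0.005,10,2B,fit,1.00,16,0.58,NA
Clotrimazole,0.005,10,3A,fit,0.99,18,0.35,NA
Clotrimazole,0.005,10,3B,fit,1.00,17,0.33,NA
Nifedipine,0.05,100,2B,fit,1.00,28,5.6,NA
Nifedipine,0.05,100,3A,fit,0.99,40,6.6,NA
Nifedipine,0.05,100,3B,fit,0.99,27,3.5,NA
Quinidine,0.11,250,2B,NA,NA,NA,NA,1.0
Quinidine,0.11,250,3A,NA,NA,NA,NA,2.0
Quinidine,0.11,250,3B,NI,NA,NA,NA,1.12
Flumazenil,0.023,50,2B,NI,NA,NA,NA,NA
Flumazenil,0.023,50,3A,NI,NA,NA,NA,NA
Flumazenil,0.023,50,3B,NI,NA,NA,NA,NA
Primaquine,0.05,40,2B,NI,NA,NA,NA,NA
Primaquine,0.05,40,3A,NI,NA,NA,NA,NA
Primaquine,0.05,40,3B,NI,NA,NA,NA,NA
Methotrexate,0.009,20,2B,NI,NA,NA,NA,NA
Methotrexate,0.009,20,3A,NI,NA,NA,NA,NA
Methotrexate,0.009,20,3B,NI,NA,NA,NA,NA
Digoxin,0.0002,0.2,2B,NI,NA,NA,NA,NA
Digoxin,0.0002,0.2,3A,NI,NA,NA,NA,NA
Digoxin,0.0002,0.2,3B,NI,NA,NA,NA,NA
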