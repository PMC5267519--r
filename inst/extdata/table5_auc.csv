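compound,observed_auc_pct,endpoint,lot,predicted_auc_pct
Rifampicin,97,mRNA,2B,98
Rifampicin,97,mRNA,3A,98
Rifampicin,97,mRNA,3B,95
Rifampicin,97,activity,2B,96
Rifampicin,97,activity,3A,96
Rifampicin,97,activity,3B,99
Phenytoin,94,mRNA,2B,98
Phenytoin,94,mRNA,3A,98
Phenytoin,94,mRNA,3B,95
Phenytoin,94,activity,2B,96
Phenytoin,94,activity,3A,96
Phenytoin,94,activity,3B,97
Carbamazepine,94,mRNA,2B,86
Carbamazepine,94,mRNA,3A,87
Carbamazepine,94,mRNA,3B,95
Carbamazepine,94,activity,2B,92
Carbamazepine,94,activity,3A,92
Carbamazepine,94,activity,3B,87
Phenobarbital,61,mRNA,2B,98
Phenobarbital,61,mRNA,3A,98
Phenobarbital,61,mRNA,3B,95
Phenobarbital,61,activity,2B,96
Phenobarbital,61,activity,3A,96
Phenobarbital,61,activity,3B,98
Pioglitazone,26,mRNA,2B,36
Pioglitazone,26,mRNA,3A,35
Pioglitazone,26,mRNA,3B,29
Pioglitazone,26,activity,2B,17
Pioglitazone,26,activity,3A,23
Pioglitazone,26,activity,3B,34
Terbinafine,25,mRNA,2B,8.1
Terbinafine,25,mRNA,3A,13
Terbinafine,25,mRNA,3B,19
Terbinafine,25,activity,2B,29
Terbinafine,25,activity,3A,29
Terbinafine,25,activity,3B,15
Sulfinpyrazone,22,mRNA,2B,94
Sulfinpyrazone,22,mRNA,3A,97
Sulfinpyrazone,22,mRNA,3B,95
Sulfinpyrazone,22,activity,2B,96
Sulfinpyrazone,22,activity,3A,95
Sulfinpyrazone,22,activity,3B,92
Probenecid,20,mRNA,2B,98
Probenecid,20,mRNA,3A,98
Probenecid,20,mRNA,3B,95
Probenecid,20,activity,2B,96
Probenecid,20,activity,3A,94
Probenecid,20,activity,3B,83
Dexamethasone,19,mRNA,2B,0.00
Dexamethasone,19,mRNA,3A,0.00
Dexamethasone,19,mRNA,3B,0.00
Dexamethasone,19,activity,2B,0.0
Dexamethasone,19,activity,3A,0.0
Dexamethasone,19,activity,3B,0.0
Nifedipine,4,mRNA,2B,4.4
Nifedipine,4,mRNA,3A,0.89
Nifedipine,4,mRNA,3B,8.3
Nifedipine,4,activity,2B,8.9
Nifedipine,4,activity,3A,2.1
Nifedipine,4,activity,3B,0.63
Omeprazole,-25,mRNA,2B,1.7
Omeprazole,-25,mRNA,3A,0.14
Omeprazole,-25,mRNA,3B,0.35
Omeprazole,-25,activity,2B,0.11
Omeprazole,-25,activity,3A,0.002
Omeprazole,-25,activity,3B,0.017
Rosiglitazone,12,mRNA,2B,0.53
Rosiglitazone,12,mRNA,3A,0.10
Rosiglitazone,12,mRNA,3B,0.20
Rosiglitazone,12,activity,2B,0.21
Rosiglitazone,12,activity,3A,0.077
Rosiglitazone,12,activity,3B,0.22
Clotrimazole,9.7,mRNA,2B,0.00
Clotrimazole,9.7,mRNA,3A,0.00
Clotrimazole,9.7,mRNA,3B,0.00
Clotrimazole,9.7,activity,2B,0
Clotrimazole,9.7,activity,3A,0
Clotrimazole,9.7,activity,3B,0
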