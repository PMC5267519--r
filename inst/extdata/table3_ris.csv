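compound,endpoint,lot,ris
Rifampicin,mRNA,2B,19.1
Rifampicin,mRNA,3A,24.8
Rifampicin,mRNA,3B,21.5
Phenytoin,mRNA,2B,7.5
Phenytoin,mRNA,3A,12.1
Phenytoin,mRNA,3B,8.5
Carbamazepine,mRNA,2B,0.76
Carbamazepine,mRNA,3A,0.77
Carbamazepine,mRNA,3B,1.3
Phenobarbital,mRNA,2B,5.2
Phenobarbital,mRNA,3A,5.0
Phenobarbital,mRNA,3B,2.5
Terbinafine,mRNA,2B,0.13
Terbinafine,mRNA,3A,0.26
Terbinafine,mRNA,3B,0.19
Pioglitazone,mRNA,2B,0.28
Pioglitazone,mRNA,3A,0.37
Pioglitazone,mRNA,3B,0.21
Sulfinpyrazone,mRNA,2B,1.2
Sulfinpyrazone,mRNA,3A,1.8
Sulfinpyrazone,mRNA,3B,1.1
Probenecid,mRNA,2B,2.8
Probenecid,mRNA,3A,3.2
Probenecid,mRNA,3B,2.4
Dexamethasone,mRNA,2B,0.0013
Dexamethasone,mRNA,3A,0.0024
Dexamethasone,mRNA,3B,0.0012
Nifedipine,mRNA,2B,0.10
Nifedipine,mRNA,3A,0.12
Nifedipine,mRNA,3B,0.16
Rosiglitazone,mRNA,2B,0.043
Rosiglitazone,mRNA,3A,0.065
Rosiglitazone,mRNA,3B,0.070
Omeprazole,mRNA,2B,0.069
Omeprazole,mRNA,3A,0.073
Omeprazole,mRNA,3B,0.079
Clotrimazole,mRNA,2B,0.0028
Clotrimazole,mRNA,3A,0.0051
Clotrimazole,mRNA,3B,0.0052
Rifampicin,activity,2B,23.8
Rifampicin,activity,3A,23.0
Rifampicin,activity,3B,18.3
Phenytoin,activity,2B,1.8
Phenytoin,activity,3A,2.3
Phenytoin,activity,3B,2.4
Carbamazepine,activity,2B,0.67
Carbamazepine,activity,3A,0.8
Carbamazepine,activity,3B,0.9
Phenobarbital,activity,2B,2.9
Phenobarbital,activity,3A,4.2
Phenobarbital,activity,3B,4.0
Terbinafine,activity,2B,0.15
Terbinafine,activity,3A,0.23
Terbinafine,activity,3B,0.17
Pioglitazone,activity,2B,0.12
Pioglitazone,activity,3A,0.20
Pioglitazone,activity,3B,0.28
Sulfinpyrazone,activity,2B,1.5
Sulfinpyrazone,activity,3A,1.4
Sulfinpyrazone,activity,3B,1.2
Probenecid,activity,2B,1.5
Probenecid,activity,3A,1.0
Probenecid,activity,3B,0.8
Dexamethasone,activity,2B,0.00054
Dexamethasone,activity,3A,0.00041
Dexamethasone,activity,3B,0.00043
Nifedipine,activity,2B,0.09
Nifedipine,activity,3A,0.09
Nifedipine,activity,3B,0.04
Rosiglitazone,activity,2B,0.019
Rosiglitazone,activity,3A,0.028
Rosiglitazone,activity,3B,0.024
Omeprazole,activity,2B,0.015
Omeprazole,activity,3A,0.009
Omeprazole,activity,3B,0.007
Clotrimazole,activity,2B,NA
Clotrimazole,activity,3A,NA
Clotrimazole,activity,3B,NA
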