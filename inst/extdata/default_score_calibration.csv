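group,variable,p0,p1,p2,mean,sd
CA_APP,no_flow_fraction,9.4,12.5,78.1,13.28,4.09
CA_APP,avg_depth,53.8,0.0,46.2,4.6,1.0
CA_APP,avg_rate,50.0,0.0,50.0,121,7
CA_APP,t_first_rhythm,6.3,0.0,93.7,74,30
CA_APP,t_first_shock,18.8,9.3,71.9,111,67
CA_APP,n_compressor_changes,12.5,46.9,40.6,NA,NA
CA_APP,dev_compressor_change,31.3,18.7,50.0,29,28
CA_APP,n_adrenaline,3.1,15.6,81.3,NA,NA
CA_APP,dev_adrenaline,59.4,0.0,40.6,17,23
CA_APP,n_rhythm_checks,0.0,3.1,96.9,NA,NA
CA_APP,dev_rhythm,6.3,12.5,81.3,12,11
CA_APP,amiodarone_class,18.8,0.0,81.3,NA,NA
NO_APP,no_flow_fraction,9.7,25.8,64.5,14.06,4.40
NO_APP,avg_depth,72.7,0.0,27.3,4.0,1.0
NO_APP,avg_rate,31.8,0.0,68.2,119,12
NO_APP,t_first_rhythm,16.1,3.3,80.6,98,53
NO_APP,t_first_shock,25.8,9.7,64.5,135,82
NO_APP,n_compressor_changes,38.7,41.9,19.4,NA,NA
NO_APP,dev_compressor_change,54.8,22.6,22.6,59,68
NO_APP,n_adrenaline,3.2,9.7,87.1,NA,NA
NO_APP,dev_adrenaline,74.2,0.0,25.8,51,70
NO_APP,n_rhythm_checks,9.7,9.7,80.6,NA,NA
NO_APP,dev_rhythm,19.4,45.2,35.5,31,31
NO_APP,amiodarone_class,25.8,0.0,74.2,NA,NA
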