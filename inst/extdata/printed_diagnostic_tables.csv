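table,stratum,model,n,TP,TN,FP,FN,sens,sens_lo,sens_hi,spec,spec_lo,spec_hi,acc,acc_lo,acc_hi
diagnostic,region_training,RadSignature,330,22,267,40,1,95.7,78.1,99.9,87.0,82.7,90.5,87.6,83.5,90.9
diagnostic,region_training,RadScore,330,22,248,59,1,95.7,78.1,99.9,80.8,75.9,85.0,81.8,77.2,85.8
diagnostic,region_training,ADC,330,21,91,216,2,91.3,72.0,98.9,29.6,24.6,35.1,33.9,28.8,39.3
diagnostic,region_training,SA,330,16,213,94,7,69.6,47.1,86.8,69.4,63.9,74.5,69.4,64.1,74.3
diagnostic,region_testing,RadSignature,142,8,114,18,2,80.0,44.4,97.5,86.4,79.3,91.7,85.9,79.1,91.2
diagnostic,region_testing,RadScore,142,8,106,26,2,80.0,44.4,97.5,80.3,72.5,86.7,80.3,72.8,86.5
diagnostic,region_testing,ADC,142,7,32,100,3,70.0,34.8,93.3,24.2,17.2,32.5,27.5,20.3,35.6
diagnostic,region_testing,SA,142,7,85,47,3,70.0,34.8,93.3,64.4,55.6,72.5,64.8,56.3,72.6
diagnostic,patient_training,RadSignature,165,15,119,30,1,93.8,69.8,99.8,79.9,72.5,86.0,81.2,74.4,86.9
diagnostic,patient_training,RadScore,165,15,105,44,1,93.8,69.8,99.8,70.5,62.5,77.7,72.7,65.3,79.4
diagnostic,patient_training,ADC,165,15,25,124,1,93.8,69.8,99.8,16.8,11.2,23.8,24.2,17.9,31.5
diagnostic,patient_training,SA,165,12,80,69,4,75.0,47.6,92.7,53.7,45.3,61.9,55.8,47.8,63.5
diagnostic,patient_testing,RadSignature,71,6,50,14,1,85.7,42.1,99.6,78.1,66.0,87.5,78.9,67.6,87.7
diagnostic,patient_testing,RadScore,71,6,44,20,1,85.7,42.1,99.6,68.8,55.9,79.8,70.4,58.4,80.7
diagnostic,patient_testing,ADC,71,6,9,55,1,85.7,42.1,99.6,14.1,6.6,25.0,21.1,12.3,32.4
diagnostic,patient_testing,SA,71,5,28,36,2,71.4,29.0,96.3,43.8,31.4,56.7,46.5,34.5,58.7
subgroup,low_risk,RadSignature,165,4,135,25,1,80.0,28.4,99.5,84.4,77.8,89.6,84.2,77.8,89.4
subgroup,low_risk,RadScore,165,4,116,44,1,80.0,28.4,99.5,72.5,64.9,79.3,72.7,65.3,79.4
subgroup,low_risk,ADC,165,5,26,134,0,100.0,47.8,100.0,16.3,10.9,22.9,18.8,13.1,25.6
subgroup,low_risk,SA,165,1,86,74,4,20.0,0.5,71.6,53.8,45.7,61.7,52.7,44.8,60.5
subgroup,intermediate_risk,RadSignature,36,3,20,12,1,75.0,19.4,99.4,62.5,43.7,78.9,63.9,46.2,79.2
subgroup,intermediate_risk,RadScore,36,3,19,13,1,75.0,19.4,99.4,59.4,40.6,76.3,61.1,43.5,76.9
subgroup,intermediate_risk,ADC,36,4,4,28,0,100.0,39.8,100.0,12.5,3.5,29.0,22.2,10.1,39.2
subgroup,intermediate_risk,SA,36,2,14,18,2,50.0,6.8,93.2,43.8,26.4,62.3,44.4,27.9,61.9
subgroup,high_risk,RadSignature,35,14,14,7,0,100.0,76.8,100.0,66.7,43.0,85.4,80.0,63.1,91.6
subgroup,high_risk,RadScore,35,14,14,7,0,100.0,76.8,100.0,66.7,43.0,85.4,80.0,63.1,91.6
subgroup,high_risk,ADC,35,12,4,17,2,85.7,57.2,98.2,19.0,5.4,41.9,45.7,28.8,63.4
subgroup,high_risk,SA,35,14,8,13,0,100.0,76.8,100.0,38.1,18.1,61.6,62.9,44.9,78.5
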