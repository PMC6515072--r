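pH,copigment,family,parameter,cp,sd,r2
3.1,epicatechin,reference,A520,0.12,0.00,0.9997
3.1,epicatechin,reference,L,-1.68,0.00,0.9881
3.1,epicatechin,reference,Cab,2.40,0.02,0.9978
3.1,epicatechin,reference,hab,-5.50,0.00,0.9985
3.1,epicatechin,reference,a,2.19,0.02,0.9976
3.1,epicatechin,reference,b,-1.53,0.02,0.9828
3.1,grape-seed,PC/PD,A520,0.11,0.00,0.9908
3.1,grape-seed,PC/PD,L,-1.55,0.01,0.9993
3.1,grape-seed,PC/PD,Cab,1.95,0.01,0.9925
3.1,grape-seed,PC/PD,hab,-6.95,0.00,0.9987
3.1,grape-seed,PC/PD,a,1.70,0.01,0.9925
3.1,grape-seed,PC/PD,b,-1.70,0.04,0.9842
3.1,grape-skin,PC/PD,A520,0.25,0.01,0.9768
3.1,grape-skin,PC/PD,L,-3.07,0.00,0.9856
3.1,grape-skin,PC/PD,Cab,3.97,0.00,0.9807
3.1,grape-skin,PC/PD,hab,-4.96,0.00,0.9750
3.1,grape-skin,PC/PD,a,3.71,0.00,0.9779
3.1,grape-skin,PC/PD,b,-2.07,0.02,0.9989
3.1,quebracho,PF/PR,A520,0.02,0.00,0.8904
3.1,quebracho,PF/PR,L,-0.92,0.00,0.9758
3.1,quebracho,PF/PR,Cab,0.13,0.04,0.7953
3.1,quebracho,PF/PR,hab,-7.87,0.00,0.9946
3.1,quebracho,PF/PR,a,-0.16,0.03,0.8585
3.1,quebracho,PF/PR,b,-1.61,0.04,0.9933
3.1,gallotannin,GT,A520,0.22,0.00,0.8446
3.1,gallotannin,GT,L,-3.02,0.00,0.8318
3.1,gallotannin,GT,Cab,4.49,0.03,0.8377
3.1,gallotannin,GT,hab,-5.36,0.00,0.9173
3.1,gallotannin,GT,a,3.98,0.02,0.8384
3.1,gallotannin,GT,b,-3.18,0.04,0.9953
3.1,ellagitannin,ET,A520,0.13,0.00,0.8334
3.1,ellagitannin,ET,L,-2.71,0.00,0.8824
3.1,ellagitannin,ET,Cab,2.52,0.01,0.8371
3.1,ellagitannin,ET,hab,-13.05,0.00,0.9955
3.1,ellagitannin,ET,a,2.00,0.01,0.8233
3.1,ellagitannin,ET,b,-3.09,0.02,0.9952
3.5,epicatechin,reference,A520,0.06,0.00,0.8940
3.5,epicatechin,reference,L,-0.92,0.00,0.9231
3.5,epicatechin,reference,Cab,1.20,0.03,0.8937
3.5,epicatechin,reference,hab,-4.06,0.00,0.9763
3.5,epicatechin,reference,a,1.12,0.03,0.8744
3.5,epicatechin,reference,b,-0.62,0.03,1.0000
3.5,grape-seed,PC/PD,A520,0.07,0.00,0.9681
3.5,grape-seed,PC/PD,L,-1.00,0.00,1.0000
3.5,grape-seed,PC/PD,Cab,1.28,0.02,0.9619
3.5,grape-seed,PC/PD,hab,-3.01,0.01,0.9776
3.5,grape-seed,PC/PD,a,1.23,0.02,0.9702
3.5,grape-seed,PC/PD,b,-0.52,0.04,0.8378
3.5,grape-skin,PC/PD,A520,0.12,0.00,0.9581
3.5,grape-skin,PC/PD,L,-1.91,0.00,0.9791
3.5,grape-skin,PC/PD,Cab,2.01,0.06,0.9660
3.5,grape-skin,PC/PD,hab,-7.74,0.01,0.9617
3.5,grape-skin,PC/PD,a,1.83,0.05,0.9610
3.5,grape-skin,PC/PD,b,-1.22,0.06,0.8009
3.5,quebracho,PF/PR,A520,0.17,0.00,0.9251
3.5,quebracho,PF/PR,L,-2.33,0.00,0.9018
3.5,quebracho,PF/PR,Cab,2.50,0.06,0.9525
3.5,quebracho,PF/PR,hab,-8.74,0.01,0.9995
3.5,quebracho,PF/PR,a,2.38,0.06,0.9562
3.5,quebracho,PF/PR,b,-1.15,0.08,0.7987
3.5,gallotannin,GT,A520,0.31,0.00,0.9885
3.5,gallotannin,GT,L,-4.14,0.00,0.9832
3.5,gallotannin,GT,Cab,6.23,0.03,0.9897
3.5,gallotannin,GT,hab,-16.75,0.01,0.9516
3.5,gallotannin,GT,a,5.62,0.02,0.0885
3.5,gallotannin,GT,b,-3.41,0.05,0.9986
3.5,ellagitannin,ET,A520,0.15,0.00,0.9964
3.5,ellagitannin,ET,L,-2.48,0.00,0.9976
3.5,ellagitannin,ET,Cab,2.52,0.02,0.9959
3.5,ellagitannin,ET,hab,-12.74,0.00,0.9828
3.5,ellagitannin,ET,a,2.19,0.01,0.9930
3.5,ellagitannin,ET,b,-1.90,0.01,0.9998
3.9,epicatechin,reference,A520,0.08,0.00,1.0000
3.9,epicatechin,reference,L,-1.08,0.00,0.9826
3.9,epicatechin,reference,Cab,1.26,0.01,0.9922
3.9,epicatechin,reference,hab,-3.79,0.00,0.9932
3.9,epicatechin,reference,a,1.20,0.01,0.9908
3.9,epicatechin,reference,b,-0.45,0.02,0.9967
3.9,grape-seed,PC/PD,A520,0.05,0.00,0.9873
3.9,grape-seed,PC/PD,L,-0.79,0.00,0.9973
3.9,grape-seed,PC/PD,Cab,0.71,0.01,0.9304
3.9,grape-seed,PC/PD,hab,-7.63,0.07,1.0000
3.9,grape-seed,PC/PD,a,0.61,0.02,0.9131
3.9,grape-seed,PC/PD,b,-0.62,0.07,0.8536
3.9,grape-skin,PC/PD,A520,0.06,0.01,0.9873
3.9,grape-skin,PC/PD,L,-0.92,0.00,0.8811
3.9,grape-skin,PC/PD,Cab,0.85,0.02,0.9996
3.9,grape-skin,PC/PD,hab,-11.63,0.01,0.9001
3.9,grape-skin,PC/PD,a,0.70,0.01,0.7340
3.9,grape-skin,PC/PD,b,-0.15,0.13,0.9251
3.9,quebracho,PF/PR,A520,0.05,0.00,0.9434
3.9,quebracho,PF/PR,L,-1.75,0.00,0.9643
3.9,quebracho,PF/PR,Cab,0.98,0.03,0.8275
3.9,quebracho,PF/PR,hab,-11.92,0.01,0.9826
3.9,quebracho,PF/PR,a,0.80,0.03,0.9943
3.9,quebracho,PF/PR,b,-3.07,0.05,0.9588
3.9,gallotannin,GT,A520,0.15,0.00,0.9920
3.9,gallotannin,GT,L,-2.08,0.00,0.9952
3.9,gallotannin,GT,Cab,3.04,0.03,0.9954
3.9,gallotannin,GT,hab,-16.14,0.02,0.9924
3.9,gallotannin,GT,a,2.74,0.02,0.9922
3.9,gallotannin,GT,b,-1.75,0.05,0.9969
3.9,ellagitannin,ET,A520,0.10,0.00,0.9510
3.9,ellagitannin,ET,L,-1.65,0.00,0.9443
3.9,ellagitannin,ET,Cab,1.62,0.01,0.9615
3.9,ellagitannin,ET,hab,-18.34,0.02,0.9968
3.9,ellagitannin,ET,a,1.33,0.01,0.9692
3.9,ellagitannin,ET,b,-1.51,0.07,0.9898
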