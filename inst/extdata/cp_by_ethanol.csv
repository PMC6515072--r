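ethanol_pct,copigment,family,parameter,cp,sd,r2
10,epicatechin,reference,A520,0.15,0.00,0.9999
10,epicatechin,reference,L,-1.75,0.00,0.9993
10,epicatechin,reference,Cab,2.77,0.02,0.9989
10,epicatechin,reference,hab,-7.02,0.01,0.9717
10,epicatechin,reference,a,2.62,0.02,0.9980
10,epicatechin,reference,b,-1.19,0.04,0.9828
10,grape-seed,PC/PD,A520,0.12,0.00,0.9991
10,grape-seed,PC/PD,L,-1.46,0.00,0.9909
10,grape-seed,PC/PD,Cab,1.83,0.03,0.9983
10,grape-seed,PC/PD,hab,-6.27,0.01,0.9777
10,grape-seed,PC/PD,a,1.71,0.02,0.9984
10,grape-seed,PC/PD,b,-0.94,0.04,0.9842
10,grape-skin,PC/PD,A520,0.14,0.00,0.9849
10,grape-skin,PC/PD,L,-2.11,0.00,0.9861
10,grape-skin,PC/PD,Cab,1.97,0.01,0.9827
10,grape-skin,PC/PD,hab,-8.50,0.01,0.9967
10,grape-skin,PC/PD,a,2.15,0.01,0.9857
10,grape-skin,PC/PD,b,-1.27,0.04,0.9989
10,quebracho,PF/PR,A520,0.12,0.01,0.9775
10,quebracho,PF/PR,L,-2.03,0.00,0.9798
10,quebracho,PF/PR,Cab,1.09,0.05,0.8761
10,quebracho,PF/PR,hab,-14.97,0.02,0.9875
10,quebracho,PF/PR,a,1.53,0.05,0.9521
10,quebracho,PF/PR,b,-1.94,0.13,0.9933
10,gallotannin,GT,A520,0.47,0.00,0.9983
10,gallotannin,GT,L,-6.30,0.00,0.9979
10,gallotannin,GT,Cab,8.33,0.02,0.9979
10,gallotannin,GT,hab,-25.68,0.01,0.9424
10,gallotannin,GT,a,9.39,0.02,0.9983
10,gallotannin,GT,b,-5.49,0.07,0.9953
10,ellagitannin,ET,A520,0.23,0.00,0.9983
10,ellagitannin,ET,L,-3.48,0.00,0.9996
10,ellagitannin,ET,Cab,4.43,0.02,0.9858
10,ellagitannin,ET,hab,-20.82,0.00,0.9993
10,ellagitannin,ET,a,3.82,0.01,0.9871
10,ellagitannin,ET,b,-3.31,0.02,0.9952
12,epicatechin,reference,A520,0.10,0.00,0.9845
12,epicatechin,reference,L,-1.42,0.00,0.9935
12,epicatechin,reference,Cab,1.78,0.16,0.9267
12,epicatechin,reference,hab,-3.55,0.01,0.9705
12,epicatechin,reference,a,1.93,0.11,0.9778
12,epicatechin,reference,b,-0.73,0.12,1.0000
12,grape-seed,PC/PD,A520,0.07,0.00,0.9902
12,grape-seed,PC/PD,L,-0.56,0.00,0.3213
12,grape-seed,PC/PD,Cab,0.49,0.09,0.5663
12,grape-seed,PC/PD,hab,-5.53,0.02,0.8155
12,grape-seed,PC/PD,a,0.30,0.06,0.4808
12,grape-seed,PC/PD,b,0.64,0.17,0.8378
12,grape-skin,PC/PD,A520,0.08,0.00,0.8542
12,grape-skin,PC/PD,L,-1.59,0.00,0.9498
12,grape-skin,PC/PD,Cab,0.87,0.05,0.7500
12,grape-skin,PC/PD,hab,-5.26,0.04,0.7940
12,grape-skin,PC/PD,a,1.35,0.05,0.9959
12,grape-skin,PC/PD,b,-0.63,0.07,0.8009
12,quebracho,PF/PR,A520,0.22,0.00,0.9554
12,quebracho,PF/PR,L,-3.24,0.00,0.9672
12,quebracho,PF/PR,Cab,0.98,0.27,0.9600
12,quebracho,PF/PR,hab,-9.77,0.02,0.7591
12,quebracho,PF/PR,a,1.10,0.19,0.9568
12,quebracho,PF/PR,b,6.46,0.12,0.7987
12,gallotannin,GT,A520,0.38,0.00,0.9999
12,gallotannin,GT,L,-5.22,0.00,0.9994
12,gallotannin,GT,Cab,6.88,0.04,0.9945
12,gallotannin,GT,hab,-19.07,0.02,0.9829
12,gallotannin,GT,a,6.39,0.08,0.9990
12,gallotannin,GT,b,-4.09,0.09,0.9986
12,ellagitannin,ET,A520,0.16,0.00,0.9893
12,ellagitannin,ET,L,-2.72,0.00,0.9840
12,ellagitannin,ET,Cab,2.80,0.14,0.9932
12,ellagitannin,ET,hab,-16.45,0.07,1.0000
12,ellagitannin,ET,a,2.05,0.10,0.9590
12,ellagitannin,ET,b,-2.25,0.46,0.9998
14,epicatechin,reference,A520,0.09,0.00,0.9980
14,epicatechin,reference,L,-1.17,0.00,0.9937
14,epicatechin,reference,Cab,1.75,0.02,0.9977
14,epicatechin,reference,hab,-6.97,0.00,0.9963
14,epicatechin,reference,a,1.60,0.02,0.9972
14,epicatechin,reference,b,-1.08,0.02,0.9967
14,grape-seed,PC/PD,A520,0.06,0.00,0.9954
14,grape-seed,PC/PD,L,-0.83,0.00,0.9868
14,grape-seed,PC/PD,Cab,1.52,0.02,0.9834
14,grape-seed,PC/PD,hab,-35.41,0.00,0.8453
14,grape-seed,PC/PD,a,1.02,0.02,0.9999
14,grape-seed,PC/PD,b,-4.28,0.03,0.8536
14,grape-skin,PC/PD,A520,0.09,0.00,0.9133
14,grape-skin,PC/PD,L,-1.44,0.00,0.9651
14,grape-skin,PC/PD,Cab,1.32,0.01,0.8271
14,grape-skin,PC/PD,hab,-5.70,0.02,0.9218
14,grape-skin,PC/PD,a,1.20,0.01,0.8127
14,grape-skin,PC/PD,b,-0.87,0.06,0.9251
14,quebracho,PF/PR,A520,0.06,0.00,0.7889
14,quebracho,PF/PR,L,-1.35,0.00,0.7311
14,quebracho,PF/PR,Cab,1.07,0.03,0.9791
14,quebracho,PF/PR,hab,-9.21,0.01,0.9875
14,quebracho,PF/PR,a,0.87,0.02,0.9530
14,quebracho,PF/PR,b,-1.14,0.04,0.9588
14,gallotannin,GT,A520,0.34,0.00,0.9982
14,gallotannin,GT,L,-4.52,0.00,0.9993
14,gallotannin,GT,Cab,6.91,0.03,0.9981
14,gallotannin,GT,hab,-20.86,0.02,0.9644
14,gallotannin,GT,a,6.11,0.03,0.9974
14,gallotannin,GT,b,-4.23,0.08,0.9969
14,ellagitannin,ET,A520,0.14,0.00,0.9328
14,ellagitannin,ET,L,-2.23,0.00,0.9516
14,ellagitannin,ET,Cab,2.89,0.01,0.9764
14,ellagitannin,ET,hab,-16.15,0.03,0.9745
14,ellagitannin,ET,a,2.44,0.00,0.9680
14,ellagitannin,ET,b,-2.47,0.10,0.9898
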