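name,C1,C2,C3,C4,C5,C6,lambda_star,K
TV_CT,3.00e+07,0e+00,7.00e+03,8.00e+01,5.441e+08,-5.8409121548145676e+08,1.0860000000000001e+00,1.464e+08
TV_LL,1.95e+04,0e+00,1.00e+05,1.35e+01,4.800e+07,-5.7158395826442599e+07,1.2800000000000000e+00,1.464e+08
TV_PM,3.00e+03,0e+00,5.00e+01,2.85e+01,1.024e+05,-1.1421599303451704e+05,1.1499999999999999e+00,1.464e+08
MV_CT,3.37e+06,0e+00,8.82e+03,6.00e+01,9.210e+07,-9.8493289501562923e+07,1.0860000000000001e+00,1.464e+08
MV_LL,3.00e+05,0e+00,9.00e+04,4.00e+01,5.380e+06,-5.3895357772122854e+06,1.0100000000000000e+00,1.464e+08
MV_PM,1.05e+04,0e+00,5.00e+02,2.45e+01,1.111e+05,-1.1706387421607180e+05,1.0900000000000001e+00,1.464e+08
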