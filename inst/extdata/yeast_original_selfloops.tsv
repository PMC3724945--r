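# source	target	sign
Cln3	MBF	+
Cln3	SBF	+
SBF	Cln1_2	+
MBF	Clb5_6	+
Clb5_6	Mcm1_SFF	+
Clb5_6	Clb1_2	+
Clb1_2	Mcm1_SFF	+
Clb1_2	Cdc20	+
Mcm1_SFF	Clb1_2	+
Mcm1_SFF	Cdc20	+
Mcm1_SFF	Swi5	+
Cdc20	Swi5	+
Cdc20	Sic1	+
Cdc20	Cdh1	+
Swi5	Sic1	+
Cln1_2	Sic1	-
Cln1_2	Cdh1	-
Clb5_6	Sic1	-
Clb5_6	Cdh1	-
Clb1_2	Sic1	-
Clb1_2	Cdh1	-
Clb1_2	Swi5	-
Clb1_2	MBF	-
Clb1_2	SBF	-
Sic1	Clb5_6	-
Sic1	Clb1_2	-
Cdh1	Clb1_2	-
Cdc20	Clb5_6	-
Cdc20	Clb1_2	-
Cln3	Cln3	-	self_degradation
Cln1_2	Cln1_2	-	self_degradation
Swi5	Swi5	-	self_degradation
Cdc20	Cdc20	-	self_degradation
Mcm1_SFF	Mcm1_SFF	-	self_degradation
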