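id,class,approval_year,dose_frequency,hba1c_reduction,weight_change,mortality_or
glp1_weekly,GLP-1 analogs,2017,0.142857142857143,1.1,6.2,0.87
glp1_daily,GLP-1 analogs,2010,1,0.9,1.4,0.88
sglt2_a,SGLT2 inhibitors,2014,1,0.65,2.6,0.85
sglt2_b,SGLT2 inhibitors,2013,1,0.6,1.9,0.86
dpp4_a,DPP-4 inhibitors,2006,1,0.66,0,1.0
dpp4_b,DPP-4 inhibitors,2009,1,0.6,0,1.01
biguanide,Biguanides,1995,2,1.5,0.3,0.95
sulfonylurea,Sulfonylureas,1994,1,1.7,0,1.08
glinide,Glinides,1997,3,0.45,-2.8,1.02
tzd,Thiazolidinediones,1999,1,0.8,-2.2,1.05
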