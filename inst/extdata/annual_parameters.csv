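name,baseline,low,high,dist_family,shape_a,shape_b,units,role,source,calibration
p_low_pce,0.41,0.205,0.615,beta,8.66,12.46,proportion,probability,literature,printed
p_mod_pce,0.363,0.181,0.544,beta,9.45,16.58,proportion,probability,literature,printed
p_high_pce,0.227,0.114,0.341,beta,11.61,39.53,proportion,probability,literature,printed
enrollment,0.52,0.26,0.78,beta,6.86,6.33,proportion,probability,literature,printed
risk_cad_high_pce,0.022,0.017,0.027,beta,76.39,3380.45,probability/yr,probability,literature,printed
risk_cad_mod_pce,0.013,0.005,0.022,beta,9.33,697.44,probability/yr,probability,literature,printed
or_cad_high_prs,1.9,1.8,2,lognormal,0.64,0.05,ratio,relative_effect,literature,printed
hr_cad_diabetes,2,1.83,2.19,lognormal,0.57,0.22,ratio,relative_effect,literature,printed
risk_cad_after_istroke,0.017,0.014,0.019,beta,174.59,10095.92,probability/yr,probability,literature,printed
risk_ischemic_stroke,0.004,0.003,0.005,beta,95.65,23817.31,probability/yr,probability,literature,printed
risk_istroke_after_cad,0.015,,,beta,60.529,3974.712,probability/yr,probability,literature,derived_pm25
hr_istroke_diabetes,2.27,1.95,2.65,lognormal,0.37,0.26,ratio,relative_effect,literature,printed
risk_istroke_post_hstroke,0.057,0.048,0.068,beta,117.64,1946.26,probability/yr,probability,literature,printed
risk_recurrent_cad,0.2,0.1,0.3,beta,48.972,195.89,probability/yr,probability,assumption,derived_pm25
risk_recurrent_istroke,0.1,0.05,0.15,beta,55.219,496.971,probability/yr,probability,assumption,derived_pm25
hr_statin_cad,0.56,0.4,0.78,lognormal,-0.58,0.09,ratio,relative_effect,literature,printed
hr_statin_istroke,0.77,0.63,0.94,lognormal,-0.26,0.08,ratio,relative_effect,literature,printed
adherence,0.5,0.4,0.6,beta,47.52,47.52,proportion,probability,assumption,printed
risk_myopathy,1e-04,1e-04,2e-04,beta,2397.88,23976402.12,probability/yr,probability,literature,recalibrated_b
risk_statin_diabetes,0.0015,0.001,0.002,beta,847.59,564212.41,probability/yr,probability,literature,recalibrated_b
risk_statin_hstroke,2e-04,1e-04,2e-04,beta,862.67,4312487.33,probability/yr,probability,literature,recalibrated_b
mort_acute_cad,0.228,0.182,0.274,beta,73.91,250.27,probability,probability,literature,printed
mort_chronic_cad,0.07,0.067,0.072,beta,14100.39,187333.752857,probability/yr,probability,literature,recalibrated_b
hr_mort_cad_diabetes,1.81,1.44,2.28,lognormal,0.69,0.09,ratio,relative_effect,literature,printed
mort_stroke_cad,0.075,0.05,0.1,beta,88.72,1094.73,probability/yr,probability,assumption,printed
mort_acute_istroke,0.1,0.08,0.12,beta,86.34,777.02,probability,probability,literature,printed
mort_chronic_stroke,0.069,0.055,0.082,beta,89.39,1215.65,probability/yr,probability,literature,printed
rr_mort_istroke_diabetes,1.67,1.58,1.76,lognormal,0.8,0.18,ratio,relative_effect,literature,printed
mort_acute_hstroke,0.39,0.33,0.45,beta,98.62,154.25,probability,probability,literature,printed
hr_mort_diabetes,1.68,1.52,1.87,lognormal,0.51,0.09,ratio,relative_effect,literature,printed
u_cad,0.79,0.73,0.86,beta,118.38,31.46,utility weight,utility,literature,printed
u_myopathy,0.917,0.896,0.938,beta,697.06,54.95,utility weight,utility,literature,printed
u_diabetes,0.8,0.62,0.98,beta,14.38,3.59,utility weight,utility,literature,printed
u_stroke,0.63,0.44,0.78,beta,18.89,11.09,utility weight,utility,literature,printed
du_acute_cad,0.041,0.021,0.062,beta,14.69,343.73,utility decrement,disutility,literature,printed
du_acute_stroke,0.22,0.18,0.26,beta,90.42,320.59,utility decrement,disutility,literature,printed
du_age,0.004,0.002,0.006,beta,15.3,3809.93,utility decrement/yr,disutility,literature,printed
cost_prs_test,145,116,174,gamma,96.04,0.66,USD,cost,vendor,printed
cost_standard_whp,58,46,70,gamma,96.04,1.66,USD/yr,cost,literature,printed
cost_mobile_app,6,5,7,gamma,96.04,16.01,USD/yr,cost,vendor,printed
cost_primary_care_visit,114,91,137,gamma,96.04,0.84,USD,cost,literature,printed
cost_statin,132,106,158,gamma,96.04,0.73,USD/yr,cost,literature,printed
cost_background,4941,3953,5930,gamma,96.04,0.019437,USD/yr,cost,literature,recalibrated_b
cost_acute_cad_nonfatal,65442,43818,100531,gamma,20.46,0.000313,USD,cost,literature,recalibrated_b
cost_acute_cad_fatal,18246,14597,21896,gamma,96.04,0.0053,USD,cost,literature,printed
cost_acute_istroke_nonfatal,40225,11539,100184,gamma,3.16,7.9e-05,USD,cost,literature,recalibrated_b
cost_acute_istroke_fatal,11256,9005,13507,gamma,96.04,0.0085,USD,cost,literature,printed
cost_acute_hstroke_nonfatal,38246,30596,45895,gamma,96.04,0.0025,USD,cost,literature,printed
cost_acute_hstroke_fatal,18246,14597,21896,gamma,96.04,0.0053,USD,cost,literature,printed
cost_fu_cad,11815,7865,16186,gamma,30.99,0.002623,USD/yr,cost,literature,recalibrated_b
cost_fu_stroke,20005,16004,24006,gamma,96.04,0.0048,USD/yr,cost,literature,printed
cost_fu_myopathy,20438,16351,24536,gamma,96.04,0.0047,USD/yr,cost,literature,printed
cost_fu_diabetes,10026,8021,12031,gamma,96.04,0.0096,USD/yr,cost,literature,printed
cost_prod_first_year,73492,58794,88191,gamma,96.04,0.001307,USD,cost,literature,recalibrated_b
cost_prod_followup,9056,7245,10868,gamma,96.04,0.010605,USD/yr,cost,literature,recalibrated_b
cost_prod_diabetes,9242,7393,11090,gamma,97.04,0.0105,USD/yr,cost,literature,recalibrated_b
cost_prod_myopathy,9056,7245,10868,gamma,96.04,0.010605,USD/yr,cost,literature,recalibrated_b
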