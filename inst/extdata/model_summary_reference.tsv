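stratum	algorithm	cv_capture_mean	cv_capture_sd	final_capture	cv_tp_flag_mean	cv_tp_flag_sd	final_tp_flag
snv-het	gradientboosting	99.76	0.18	99.58	12.78	2.26	12.20
snv-hom	easyensemble	99.94	0.14	99.75	17.25	2.07	17.40
snv-complexhet	NA	NA	NA	NA	NA	NA	NA
indel-het	gradientboosting	99.62	0.26	99.68	43.11	3.35	43.41
indel-hom	gradientboosting	99.78	0.27	99.50	55.65	4.16	55.16
indel-complexhet	gradientboosting	99.86	0.14	99.60	53.45	5.65	54.22
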