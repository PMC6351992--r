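condition_name	n_downloaded	n_intensional	n_derived	disc_only_in_downloaded	disc_only_in_derived	ext_minutes_measured	int_minutes	n_terms_downloaded	n_terms_intensional	exclude_from_summary
CKD-5 and ESRD	5	3	27	0	22	17	3	485	586	FALSE
Hypertension	12	3	233	1	222	NA	3	131	5473	FALSE
Kidney transplant	8	8	36	6	34	NA	15	49	708	FALSE
Pregnancy, narrow	35	6	156	0	121	NA	4	23429	24043	FALSE
Pregnancy, broad	35	20	1262	0	1227	NA	12	23429	47812	TRUE
Bipolar disorder	99	2	109	0	10	NA	5	1640	1744	FALSE
Depression and dysthymia	72	2	151	0	79	NA	5	978	1946	FALSE
Personality disorders	26	2	48	0	22	NA	5	401	724	FALSE
Diabetes	89	6	441	3	355	NA	6	11997	33707	FALSE
Prostate cancer	12	3	19	2	9	10	7	NA	NA	FALSE
Pain related to prostate cancer	17	14	20	0	3	12	7	149	149	FALSE
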