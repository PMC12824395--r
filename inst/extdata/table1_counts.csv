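section,row,group,n,denominator,percent_printed
A_initiation,yes,swedish_born,18640,20361,91.5
A_initiation,yes,second_gen,1633,1867,87.5
A_initiation,yes,non_refugee,1302,1462,89.1
A_initiation,yes,refugee,769,888,86.6
A_initiation,no,swedish_born,1721,20361,8.5
A_initiation,no,second_gen,234,1867,12.5
A_initiation,no,non_refugee,160,1462,10.9
A_initiation,no,refugee,119,888,13.4
A_time_to_initiation,early_0_3m,swedish_born,16634,18640,89.2
A_time_to_initiation,early_0_3m,second_gen,1431,1633,87.6
A_time_to_initiation,early_0_3m,non_refugee,1117,1302,85.8
A_time_to_initiation,early_0_3m,refugee,641,769,83.4
A_time_to_initiation,delayed_4_12m,swedish_born,1357,18640,7.3
A_time_to_initiation,delayed_4_12m,second_gen,136,1633,8.3
A_time_to_initiation,delayed_4_12m,non_refugee,124,1302,9.5
A_time_to_initiation,delayed_4_12m,refugee,84,769,10.9
A_time_to_initiation,delayed_ge12m,swedish_born,649,18640,3.5
A_time_to_initiation,delayed_ge12m,second_gen,66,1633,4.0
A_time_to_initiation,delayed_ge12m,non_refugee,61,1302,4.7
A_time_to_initiation,delayed_ge12m,refugee,44,769,5.7
A_discontinuation,no,swedish_born,9937,17991,55.2
A_discontinuation,no,second_gen,724,1567,46.2
A_discontinuation,no,non_refugee,562,1241,45.3
A_discontinuation,no,refugee,290,725,40.0
A_discontinuation,yes,swedish_born,8054,17991,44.8
A_discontinuation,yes,second_gen,843,1567,53.8
A_discontinuation,yes,non_refugee,679,1241,54.7
A_discontinuation,yes,refugee,435,725,60.0
A_time_to_discontinuation,within_6m,swedish_born,2963,8054,36.8
A_time_to_discontinuation,within_6m,second_gen,355,843,42.1
A_time_to_discontinuation,within_6m,non_refugee,288,679,42.4
A_time_to_discontinuation,within_6m,refugee,199,435,45.7
A_time_to_discontinuation,within_1y,swedish_born,1727,8054,21.4
A_time_to_discontinuation,within_1y,second_gen,156,843,18.5
A_time_to_discontinuation,within_1y,non_refugee,150,679,22.1
A_time_to_discontinuation,within_1y,refugee,99,435,22.8
A_time_to_discontinuation,within_2y,swedish_born,2320,8054,28.8
A_time_to_discontinuation,within_2y,second_gen,229,843,27.2
A_time_to_discontinuation,within_2y,non_refugee,169,679,24.9
A_time_to_discontinuation,within_2y,refugee,109,435,25.1
A_time_to_discontinuation,after_2y,swedish_born,1044,8054,13.0
A_time_to_discontinuation,after_2y,second_gen,103,843,12.2
A_time_to_discontinuation,after_2y,non_refugee,72,679,10.6
A_time_to_discontinuation,after_2y,refugee,28,435,6.4
B_trajectory,early_no_disc,swedish_born,9399,20361,46.2
B_trajectory,early_no_disc,second_gen,683,1867,36.6
B_trajectory,early_no_disc,non_refugee,521,1462,35.6
B_trajectory,early_no_disc,refugee,272,888,30.6
B_trajectory,early_disc,swedish_born,7235,20361,35.5
B_trajectory,early_disc,second_gen,748,1867,40.1
B_trajectory,early_disc,non_refugee,596,1462,40.8
B_trajectory,early_disc,refugee,369,888,41.6
B_trajectory,delayed_no_disc,swedish_born,851,20361,4.2
B_trajectory,delayed_no_disc,second_gen,68,1867,3.6
B_trajectory,delayed_no_disc,non_refugee,65,1462,4.4
B_trajectory,delayed_no_disc,refugee,34,888,3.8
B_trajectory,delayed_disc,swedish_born,1155,20361,5.7
B_trajectory,delayed_disc,second_gen,134,1867,7.2
B_trajectory,delayed_disc,non_refugee,120,1462,8.2
B_trajectory,delayed_disc,refugee,94,888,10.6
B_trajectory,continuous_lack,swedish_born,1721,20361,8.5
B_trajectory,continuous_lack,second_gen,234,1867,12.5
B_trajectory,continuous_lack,non_refugee,160,1462,10.9
B_trajectory,continuous_lack,refugee,119,888,13.4
C_typology,treatment failure,swedish_born,6586,20361,32.3
C_typology,treatment failure,second_gen,762,1867,40.8
C_typology,treatment failure,non_refugee,605,1462,41.4
C_typology,treatment failure,refugee,429,888,48.3
C_typology,persistent antidepressant-monotherapy,swedish_born,3851,20361,18.9
C_typology,persistent antidepressant-monotherapy,second_gen,309,1867,16.6
C_typology,persistent antidepressant-monotherapy,non_refugee,275,1462,18.8
C_typology,persistent antidepressant-monotherapy,refugee,166,888,18.7
C_typology,persistent mood-stabilizers,swedish_born,4256,20361,20.9
C_typology,persistent mood-stabilizers,second_gen,306,1867,16.4
C_typology,persistent mood-stabilizers,non_refugee,205,1462,14.0
C_typology,persistent mood-stabilizers,refugee,80,888,9.0
C_typology,persistent antipsychotics,swedish_born,1838,20361,9.0
C_typology,persistent antipsychotics,second_gen,147,1867,7.9
C_typology,persistent antipsychotics,non_refugee,131,1462,9.0
C_typology,persistent antipsychotics,refugee,81,888,9.1
C_typology,persistent lithium,swedish_born,1725,20361,8.5
C_typology,persistent lithium,second_gen,149,1867,8.0
C_typology,persistent lithium,non_refugee,116,1462,7.9
C_typology,persistent lithium,refugee,50,888,5.6
C_typology,persistent augmentation,swedish_born,1053,20361,5.2
C_typology,persistent augmentation,second_gen,92,1867,4.9
C_typology,persistent augmentation,non_refugee,60,1462,4.1
C_typology,persistent augmentation,refugee,33,888,3.7
C_typology,persistent lithium with augmentation,swedish_born,1052,20361,5.2
C_typology,persistent lithium with augmentation,second_gen,102,1867,5.5
C_typology,persistent lithium with augmentation,non_refugee,70,1462,4.8
C_typology,persistent lithium with augmentation,refugee,49,888,5.5
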