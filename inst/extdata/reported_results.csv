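outcome,disease,value
pain_management,knee_oa,108000000
pain_management,hip_oa,64545447
pain_management,fibromyalgia,125700000
pain_management,shoulder_pain,80030000
pain_management,low_back_pain,187908323
pain_management,five_mskd,566170000
pain_management,rest_of_mskd,119430000
pain_management,total_mskd,685598439
depression,knee_oa,329000
depression,hip_oa,192000
depression,fibromyalgia,9270000
depression,shoulder_pain,648000
depression,low_back_pain,812000
depression,five_mskd,11260000
depression,rest_of_mskd,59600000
depression,total_mskd,70860000
anxiety,knee_oa,671000
anxiety,hip_oa,459000
anxiety,fibromyalgia,732000
anxiety,shoulder_pain,548000
anxiety,low_back_pain,1340000
anxiety,five_mskd,3750000
anxiety,rest_of_mskd,718000
anxiety,total_mskd,4471935
absenteeism,knee_oa,8756456
absenteeism,hip_oa,5200000
absenteeism,fibromyalgia,3120000
absenteeism,shoulder_pain,4410000
absenteeism,low_back_pain,50018592
absenteeism,five_mskd,71500000
productivity_losses,knee_oa,11960000
productivity_losses,hip_oa,6430000
productivity_losses,fibromyalgia,4890000
productivity_losses,shoulder_pain,6840000
productivity_losses,low_back_pain,80869957
productivity_losses,five_mskd,110990000
total_cost,knee_oa,129710868
total_cost,hip_oa,76827711
total_cost,fibromyalgia,143710082
total_cost,shoulder_pain,92465614
total_cost,low_back_pain,320952132
total_cost,total_mskd,943413490
lhsu,knee_oa,21720
lhsu,hip_oa,10810
lhsu,fibromyalgia,54172
lhsu,shoulder_pain,1023
lhsu,low_back_pain,31523
lhsu,five_mskd,119249
lhsu,rest_of_mskd,35787
lhsu,total_mskd,155036
depression_episodes,knee_oa,12892
depression_episodes,hip_oa,7483
depression_episodes,fibromyalgia,357469
depression_episodes,shoulder_pain,24252
depression_episodes,low_back_pain,30832
depression_episodes,five_mskd,432927
depression_episodes,rest_of_mskd,2257030
depression_episodes,total_mskd,2689958
anxiety_episodes,knee_oa,45804
anxiety_episodes,hip_oa,31420
anxiety_episodes,fibromyalgia,50921
anxiety_episodes,shoulder_pain,37330
anxiety_episodes,low_back_pain,93427
anxiety_episodes,five_mskd,258903
anxiety_episodes,rest_of_mskd,45095
anxiety_episodes,total_mskd,303997
sick_leave_days,knee_oa,387961
sick_leave_days,hip_oa,221281
sick_leave_days,fibromyalgia,182945
sick_leave_days,shoulder_pain,205647
sick_leave_days,low_back_pain,2677424
sick_leave_days,five_mskd,3147509
n_leaves,low_back_pain,273297
paid_sick_leave_days,low_back_pain,2324466
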