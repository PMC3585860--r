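stu	population_id	male_ratio	repro_isolation	ovotestis
T_baeticus	lit	>45
T_cancriformis	lit	0-53	yes	yes
T_cf_australiensis_sp_1	lit
T_cf_australiensis_sp_2	lit
T_cf_australiensis_sp_3	lit
T_cf_australiensis_sp_A	lit	>45		no
T_cf_australiensis_sp_B	lit	<30		yes
T_emeritensis	lit	>45
T_gadensis	lit	36
T_cf_granarius_Japan	lit	>45	no
T_cf_granarius_Namibia	lit	even	no
T_cf_granarius_Tunisia	lit	even	no
T_cf_granarius_Russia	lit
T_cf_longicaudatus_sp_1	lit	>45
T_cf_longicaudatus_sp_2	lit	0-68		yes
T_cf_mauritanicus_E_Spain	lit
T_mauritanicus	lit
T_newberryi	lit	<30	yes
T_simplex	lit	>45
T_vicentinus	lit	>45
L_apus	lit	<45		yes
L_arcticus	lit	<45		yes
L_bilobatus	lit	35
L_cf_couesii_Apulia	lit
L_cf_couesii_Sardinia	lit	>45
L_couesii_Canada	lit	>45
L_cryptus	lit
L_lemmoni	lit	>45
L_lubbocki	lit	>45		no
L_packardi	lit	>45
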