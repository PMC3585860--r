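(((T_cancriformis:3,(T_mauritanicus:2,T_cf_mauritanicus_E_Spain:2,T_baeticus:2,T_emeritensis:2,T_gadensis:2,T_vicentinus:2,T_simplex:2):1):2,((T_cf_granarius_Japan:2,T_cf_granarius_Namibia:2,T_cf_granarius_Tunisia:2,T_cf_granarius_Russia:2):2,((T_cf_australiensis_sp_1:2,T_cf_australiensis_sp_2:2,T_cf_australiensis_sp_3:2,T_cf_australiensis_sp_A:2,T_cf_australiensis_sp_B:2):1,((T_newberryi:1,T_cf_longicaudatus_sp_2:1):1,T_cf_longicaudatus_sp_1:2):1):1):1):2,(L_lubbocki:4,(L_apus:3,((L_packardi:1,L_cryptus:1,L_bilobatus:1,L_lemmoni:1):1,(L_arcticus:2,(L_couesii_Canada:1,L_cf_couesii_Apulia:1,L_cf_couesii_Sardinia:1):1):1):1):1):3);
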