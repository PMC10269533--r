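dna_binding:
- HTH_1
- HTH_3
- HTH_8
- HTH_11
- HTH_AraC
- Crp
- GerE
- LytTR
- Trans_reg_C
- MerR
- PadR
- TetR_N
- ArsR
- MarR
- DeoR
- GntR
- LacI
- Rrf2
- HxlR
- RpiR
- Fe_dep_repress
- ROS_MUCR
- PucR
- FUR
tcs_core:
- Response_reg
- HATPase_c
- HisKA
st_membership:
- MCPsignal
- GGDEF
- EAL
- HD
- PilZ
- HisKA
- HATPase_c
- Response_reg
- PAS
- GAF
- Cache_1
- dCache_1
- CHASE
- sCache_2
- MASE1
- HAMP
- Y_Y_Y
- Peripla_BP_6
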