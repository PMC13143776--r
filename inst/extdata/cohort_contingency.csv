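table,row,col,count
grade_by_subtype,grade_low,ER+,24
grade_by_subtype,grade_low,HER2+,8
grade_by_subtype,grade_low,TNBC,6
grade_by_subtype,grade_high,ER+,7
grade_by_subtype,grade_high,HER2+,10
grade_by_subtype,grade_high,TNBC,17
yap_by_grade,grade_low,YAP_high,24
yap_by_grade,grade_low,YAP_low,13
yap_by_grade,grade_high,YAP_high,14
yap_by_grade,grade_high,YAP_low,20
yap_by_node,node_negative,YAP_high,8
yap_by_node,node_negative,YAP_low,14
yap_by_node,node_positive,YAP_high,29
yap_by_node,node_positive,YAP_low,20
yap_by_subtype,ER+,YAP_high,18
yap_by_subtype,ER+,YAP_low,13
yap_by_subtype,HER2+,YAP_high,11
yap_by_subtype,HER2+,YAP_low,9
yap_by_subtype,TNBC,YAP_high,11
yap_by_subtype,TNBC,YAP_low,12
nelfa_by_menopause,premenopausal,NELFA_high,8
nelfa_by_menopause,premenopausal,NELFA_low,7
nelfa_by_menopause,postmenopausal,NELFA_high,23
nelfa_by_menopause,postmenopausal,NELFA_low,26
joint_by_subtype,HighYAP_HighNELFA,ER+,9
joint_by_subtype,HighYAP_HighNELFA,HER2+,8
joint_by_subtype,HighYAP_HighNELFA,TNBC,5
joint_by_subtype,HighYAP_LowNELFA,ER+,9
joint_by_subtype,HighYAP_LowNELFA,HER2+,3
joint_by_subtype,HighYAP_LowNELFA,TNBC,6
joint_by_subtype,LowYAP_HighNELFA,ER+,7
joint_by_subtype,LowYAP_HighNELFA,HER2+,3
joint_by_subtype,LowYAP_HighNELFA,TNBC,5
joint_by_subtype,LowYAP_LowNELFA,ER+,6
joint_by_subtype,LowYAP_LowNELFA,HER2+,6
joint_by_subtype,LowYAP_LowNELFA,TNBC,8
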