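# Frontal data channels (1-4) from the same published comparison: channel
# MNI coordinates by registration method, the anatomical regions detected by
# 10-mm-ball Monte-Carlo sampling against a gyrus atlas (semicolon-joined),
# and the printed per-axis absolute differences between the two methods.
group,channel,method,x,y,z,regions,dx,dy,dz
adult,CH1,MRI,-56,50,-17,Inferior frontal gyrus,1,3,0
adult,CH1,POR,-57,47,-17,Inferior frontal gyrus,1,3,0
adult,CH2,MRI,-53,49,-1,Middle frontal gyrus;Inferior frontal gyrus,2,5,1
adult,CH2,POR,-55,44,-2,Inferior frontal gyrus;Middle frontal gyrus,2,5,1
adult,CH3,MRI,-62,29,-14,Precentral gyrus;Superior temporal gyrus;Inferior frontal gyrus,0,2,0
adult,CH3,POR,-62,27,-14,Precentral gyrus;Superior temporal gyrus;Inferior frontal gyrus,0,2,0
adult,CH4,MRI,-59,33,5,Inferior frontal gyrus,2,8,2
adult,CH4,POR,-61,25,3,Inferior frontal gyrus;Precentral gyrus,2,8,2
child,CH1,MRI,-56,50,-20,Inferior frontal gyrus,1,4,0
child,CH1,POR,-55,54,-20,Inferior frontal gyrus;Middle frontal gyrus,1,4,0
child,CH2,MRI,-53,48,-2,Middle frontal gyrus;Inferior frontal gyrus,1,2,2
child,CH2,POR,-54,50,-4,Inferior frontal gyrus;Middle frontal gyrus,1,2,2
child,CH3,MRI,-61,29,-18,Precentral gyrus;Superior temporal gyrus;Inferior frontal gyrus,0,4,1
child,CH3,POR,-61,33,-17,Precentral gyrus;Superior temporal gyrus;Inferior frontal gyrus,0,4,1
child,CH4,MRI,-59,32,2,Inferior frontal gyrus;Precentral gyrus,1,1,0
child,CH4,POR,-60,31,2,Inferior frontal gyrus;Precentral gyrus,1,1,0
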