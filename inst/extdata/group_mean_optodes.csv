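# Group-averaged optode MNI coordinates (mm) from a published
# photogrammetry-vs-MRI fNIRS registration comparison: POR columns are the
# photo-based registration (pre/post-MRI sessions averaged), MRI columns the
# MRI-based registration; dx,dy,dz,d are the printed per-axis absolute
# differences and Euclidean distance.
group,optode,por_x,por_y,por_z,mri_x,mri_y,mri_z,dx,dy,dz,d
adult,1,-61,34,-7,-59,39,-5,2,5,2,5.7
adult,2,-67,1,-1,-66,6,1,1,5,2,5.5
adult,3,-62,-32,5,-65,-25,7,3,7,2,7.9
adult,4,-46,-58,6,-51,-51,9,5,7,3,9.1
adult,5,-65,-31,-29,-64,-31,-32,1,0,3,3.2
adult,6,-48,-61,-23,-49,-59,-28,1,2,5,5.5
adult,7,-53,60,-27,-53,60,-29,0,0,2,2.0
adult,8,-48,54,4,-47,59,4,1,5,0,5.1
adult,9,-63,19,-21,-64,18,-23,1,1,2,2.4
adult,10,-61,16,13,-58,27,14,3,11,1,11.4
adult,11,-68,-15,-17,-69,-13,-19,1,2,2,3.0
adult,12,-62,-19,19,-62,-7,21,0,12,2,12.2
adult,13,-58,-45,-12,-61,-40,-13,3,5,1,5.9
adult,14,-51,-45,20,-55,-34,24,4,11,4,12.4
adult,15,-37,-70,-8,-41,-66,-7,4,4,1,5.7
adult,16,-33,-63,18,-38,-55,20,5,8,2,9.6
adult,17,-56,-46,-39,-52,-49,-47,4,3,8,9.4
adult,18,-37,-71,-34,-38,-69,-39,1,2,5,5.5
child,1,-59,41,-9,-59,39,-9,0,2,0,2.0
child,2,-66,4,-2,-66,6,-5,0,2,3,3.6
child,3,-63,-31,3,-65,-27,-4,2,4,7,8.3
child,4,-47,-58,4,-50,-55,-6,3,3,10,10.9
child,5,-65,-28,-32,-62,-30,-41,3,2,9,9.7
child,6,-49,-60,-28,-46,-58,-44,3,2,16,16.4
child,7,-50,66,-30,-52,61,-30,2,5,0,5.4
child,8,-48,59,2,-47,57,6,1,2,4,4.6
child,9,-62,24,-24,-63,19,-27,1,5,3,5.9
child,10,-60,21,12,-59,24,13,1,3,1,3.3
child,11,-68,-12,-21,-68,-12,-25,0,0,4,4.0
child,12,-63,-17,18,-64,-10,16,1,7,2,7.3
child,13,-56,-45,-15,-59,-42,-24,3,3,9,9.9
child,14,-52,-46,18,-55,-40,14,3,6,4,7.8
child,15,-38,-70,-12,-39,-69,-22,1,1,10,10.1
child,16,-34,-64,15,-36,-63,12,2,1,3,3.7
child,17,-56,-43,-45,-51,-47,-57,5,4,12,13.6
child,18,-37,-69,-40,-35,-67,-52,2,2,12,12.3
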