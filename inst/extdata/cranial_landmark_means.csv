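name,frame,x,y,z
bregma,acpc,-0.1,-7.0,10.0
inion,acpc,0.1,-23.0,-3.0
rhinion,acpc,-0.1,19.6,-3.2
zygion_L,acpc,-15.1,-0.2,-10.0
zygion_R,acpc,14.9,-0.1,-10.0
bregma,stereotactic,-0.3,6.0,20.4
inion,stereotactic,-0.2,-12.0,10.5
rhinion,stereotactic,0.1,29.9,2.9
zygion_L,stereotactic,-15.1,9.4,-0.4
zygion_R,stereotactic,14.9,9.2,-0.3
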