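patient_id,ls_right_percent,xa_manual_right_percent,xa_right_percent,right_start_frame,left_start_frame,elapsed_right_s,elapsed_left_s,fps
A,81,82,82,22,22,0.73,0.73,30
B,59,61,62,26,26,0.86,0.86,30
C,69,67,84,16,16,0.53,0.53,30
D,43,30,40,24,21,0.79,0.69,30
E,45,34,38,23,23,0.76,0.76,30
F,55,64,50,15,14,0.50,0.46,30
G,46,52,49,16,15,0.53,0.50,30
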