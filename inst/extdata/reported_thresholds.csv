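species,scenario,loss_lower_pct,loss_upper_pct,occupancy_decrease_pct
Emberiza calandra,A2,0,10,35.38
Emberiza calandra,R1,20,30,43.41
Emberiza calandra,R2,20,30,30.32
Emberiza calandra,S,0,10,62.18
Passer montanus,R1,10,20,34.28
Passer montanus,R2,10,20,34.05
Emberiza citrinella,R1,10,20,52.45
Emberiza citrinella,R2,10,20,51.79
Garrulus glandarius,A2,50,60,47.01
Garrulus glandarius,R1,80,90,99.99
Garrulus glandarius,R2,70,80,100.00
Garrulus glandarius,C,40,50,38.20
Garrulus glandarius,S,30,40,47.61
Poecile palustris,A1,0,10,97.78
Poecile palustris,A2,10,20,94.74
Poecile palustris,R1,80,90,100.00
Poecile palustris,R2,70,80,95.31
Poecile palustris,C,0,10,73.76
Poecile palustris,S,0,10,76.38
Rana temporaria,R1,50,60,31.71
Bufo bufo,A1,0,10,43.29
Bufo bufo,A2,10,20,53.57
Bufo bufo,R1,80,90,76.98
Bufo bufo,R2,70,80,68.32
Bufo bufo,C,0,10,58.12
Bufo bufo,S,0,10,47.09
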