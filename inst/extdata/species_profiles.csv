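species,common_name,group,dispersal_km,classes,min_area_ha
Turdus merula,Blackbird,generalist,3.3,1;2;3;4;5;6;7;8,0.02
Prunella modularis,Dunnock,generalist,2.1,1;2;3;4;5;6;7;8,0.02
Carduelis chloris,Greenfinch,generalist,4.2,1;2;3,0.25
Emberiza calandra,Corn bunting,farmland,4.0,3;4;5;6;8,2.50
Passer montanus,Tree sparrow,farmland,8.0,1;2;3,0.12
Emberiza citrinella,Yellowhammer,farmland,8.4,3;5;10;11,0.03
Garrulus glandarius,Jay,woodland,3.5,1;2,0.32
Poecile palustris,Marsh tit,woodland,0.885,1,2.10
Rana temporaria,Common frog,amphibian,1.0,1;2;3;4;5;6;8;9;16,0.02
Bufo bufo,Common toad,amphibian,0.7,1;2;5;6;8;9;16,0.02
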